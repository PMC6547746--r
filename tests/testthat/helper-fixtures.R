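# Shared fixture builders. Everything is generated in code; no binary data.

# minimal twin sheet: n_sets pairs (optionally one triplet), one collection,
# one sample per collection unless replicate counts given
tiny_sheet <- function(n_sets = 2, n_collections = 1, n_replicates = 1,
                       triplet_first = FALSE, sexes = NULL) {
  rows <- list()
  for (s in seq_len(n_sets)) {
    n_ind <- if (triplet_first && s == 1) 3 else 2
    sex <- if (is.null(sexes)) "F" else sexes[s]
    for (i in seq_len(n_ind)) {
      status <- if (i == 1) "affected" else "unaffected"
      for (ci in seq_len(n_collections)) {
        for (r in seq_len(n_replicates)) {
          sid <- sprintf("s%d_%d_c%d_r%d", s, i, ci, r)
          rows[[sid]] <- data.frame(
            sample_id = sid,
            individual_id = sprintf("set%d_ind%d", s, i),
            twin_set_id = paste0("set", s),
            disease_status = status, sex = sex,
            age_at_collection = 40 + s + ci, collection_index = ci,
            replicate_group = sprintf("set%d_ind%d_c%d", s, i, ci),
            cohort = "twin", stringsAsFactors = FALSE)
        }
      }
    }
  }
  sample_sheet(do.call(rbind, rows))
}

# build a collapsed_cohort object directly from a per-set delta-beta matrix;
# unaffected baseline defaults to 0.4 so beta stays in range
fake_collapsed <- function(delta_beta, baseline = 0.4,
                           is_control = NULL) {
  un <- matrix(baseline, nrow(delta_beta), ncol(delta_beta),
               dimnames = dimnames(delta_beta))
  aff <- un + delta_beta
  if (is.null(is_control)) {
    is_control <- stats::setNames(rep(FALSE, ncol(delta_beta)),
                                  colnames(delta_beta))
  }
  structure(list(
    affected_beta = aff, unaffected_beta = un,
    affected_m = beta_to_m(aff), unaffected_m = beta_to_m(un),
    delta_beta = aff - un, delta_m = beta_to_m(aff) - beta_to_m(un),
    set_ids = colnames(delta_beta), is_control = is_control
  ), class = "collapsed_cohort")
}

# annotation with a single HIL class and optional gene strings
flat_annotation <- function(probe_ids, hil = "HC", genes = "") {
  probe_annotation(data.frame(
    probe_id = probe_ids, chromosome = "chr1",
    position = seq_along(probe_ids), genes = genes,
    distance_to_tss = 0L, hil_category = hil,
    cross_hybridising = FALSE, sex_chromosome = FALSE, snp_overlap = FALSE,
    stringsAsFactors = FALSE))
}

# the hand-enumerated 5-sample x 6-unit amplicon plate:
#  - S5 entirely missing (step-1 sample failure)
#  - U6 missing for S1..S4, so 100% missing once S5 is gone (step-1 unit)
#  - S4 additionally missing U1: 1/5 = 20% >= 15% of remaining units (step 2)
#  - final retained: S1..S3 x U1..U5
epityper_fixture <- function() {
  v <- matrix(50, 6, 5,
              dimnames = list(paste0("U", 1:6), paste0("S", 1:5)))
  v[, "S5"] <- NA
  v["U6", ] <- NA
  v["U1", "S4"] <- NA
  epityper_plate(v)
}

# simulated mixed-model cohort: 20 twin pairs, 2 collections x 2 technical
# replicates, gaussian response with set/individual intercepts; optional
# disease main effect or disease-by-age slope
mixed_model_cohort <- function(n_sets = 20, seed = 1, disease_effect = 0,
                               interaction_slope = 0) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_sets)) {
    age <- stats::runif(1, 25, 65)
    sex <- sample(c("F", "M"), 1)
    set_int <- stats::rnorm(1, 0, 2)
    for (i in 1:2) {
      ind_int <- stats::rnorm(1, 0, 2)
      status <- if (i == 1) "affected" else "unaffected"
      aff <- as.numeric(i == 1)
      for (ci in 1:2) {
        a <- age + (ci - 1) * 1.5
        coll_val <- 50 + 0.3 * a + set_int + ind_int +
          aff * disease_effect + aff * interaction_slope * (a - 45) +
          stats::rnorm(1, 0, 1)
        for (r in 1:2) {
          sid <- sprintf("s%d_%d_%d_%d", s, i, ci, r)
          rows[[sid]] <- data.frame(
            sample_id = sid, individual_id = sprintf("i%d_%d", s, i),
            twin_set_id = paste0("set", s), disease_status = status,
            sex = sex, age_at_collection = a, collection_index = ci,
            replicate_group = sprintf("i%d_%d_%d", s, i, ci),
            cohort = "twin",
            y = coll_val + stats::rnorm(1, 0, 0.8),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
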