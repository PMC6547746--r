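# Synthetic twin cohorts, case-control cohorts, amplicon plates, clocks and
# count matrices with known planted truth. These generators are the testing
# substrate for every downstream stage: cohort data of this design are
# typically not shareable, so planted-truth simulation is the only portable
# acceptance oracle.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# bimodal methylome baseline: most CpGs near fully un/methylated
rbeta_bimodal <- function(n) {
  lo <- stats::rbeta(n, 0.5, 8)
  hi <- stats::rbeta(n, 8, 0.5)
  pick <- stats::runif(n) < 0.5
  ifelse(pick, lo, hi)
}

#' Configuration for the twin-cohort methylome simulator
#'
#' Defaults emulate a small discordant-MZ cohort: four twin sets of which one
#' is a triplet, longitudinal collections with technical replicates, a
#' bimodal background methylome and planted disease effects of a fixed
#' delta-beta at designated probes (shared probes keep one sign across all
#' sets; private probes are planted per set).
#'
#' @param n_twin_sets number of discordant twin/triplet sets.
#' @param triplet_sets indices of sets that are triplets (one affected, two
#'   unaffected).
#' @param n_probes number of array probes simulated.
#' @param n_planted_dmps_shared shared-direction disease probes (planted in
#'   high-density-island probes so the cross-set ranking stage can be tested).
#' @param n_planted_dmps_private per-set private disease probes.
#' @param delta_beta planted effect size on the beta scale, in (0,1).
#' @param n_collections longitudinal collections per individual.
#' @param n_replicates technical replicates per collection.
#' @param replicate_sd technical noise sd on the beta scale.
#' @param biological_sd individual/set deviation sd on the beta scale.
#' @param hil_fractions proportions of probes per CpG-density class
#'   (HC, IC, ICshore, LC); must sum to 1.
#' @param detection_fail_rate fraction of detection p-values drawn above the
#'   usual detection threshold.
#' @param age_range range from which each set's collection-1 age is drawn.
#' @param clock optional synthetic clock model (see [make_synthetic_clock()]);
#'   when supplied, its clock CpGs are appended to the matrix with the
#'   age-encoding embedding so epigenetic age is recoverable.
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return a list of class `twin_sim_config`.
#' @export
twin_sim_config <- function(n_twin_sets = 4, triplet_sets = 1L,
                            n_probes = 5000, n_planted_dmps_shared = 20,
                            n_planted_dmps_private = 10, delta_beta = 0.3,
                            n_collections = 2, n_replicates = 2,
                            replicate_sd = 0.02, biological_sd = 0.02,
                            hil_fractions = c(HC = 0.3, IC = 0.2,
                                              ICshore = 0.2, LC = 0.3),
                            detection_fail_rate = 0.002,
                            age_range = c(25, 65), clock = NULL, seed = 1L) {
  stopifnot(n_twin_sets >= 1, n_probes >= 1,
            n_planted_dmps_shared >= 0, n_planted_dmps_private >= 0,
            n_collections >= 1, n_replicates >= 1)
  if (!(delta_beta > 0 && delta_beta < 1)) {
    stop("delta_beta must be in (0,1)", call. = FALSE)
  }
  if (abs(sum(hil_fractions) - 1) > 1e-8 ||
      !setequal(names(hil_fractions), HIL_LEVELS)) {
    stop("hil_fractions must be named over HC/IC/ICshore/LC and sum to 1",
         call. = FALSE)
  }
  if (length(triplet_sets) && any(triplet_sets > n_twin_sets)) {
    stop("triplet_sets index exceeds n_twin_sets", call. = FALSE)
  }
  structure(list(
    n_twin_sets = n_twin_sets, triplet_sets = as.integer(triplet_sets),
    n_probes = n_probes, n_planted_dmps_shared = n_planted_dmps_shared,
    n_planted_dmps_private = n_planted_dmps_private, delta_beta = delta_beta,
    n_collections = n_collections, n_replicates = n_replicates,
    replicate_sd = replicate_sd, biological_sd = biological_sd,
    hil_fractions = hil_fractions[HIL_LEVELS],
    detection_fail_rate = detection_fail_rate, age_range = age_range,
    clock = clock, seed = as.integer(seed)
  ), class = "twin_sim_config")
}

#' Simulate a discordant-twin methylome cohort with planted truth
#'
#' Each twin set shares a set-level baseline methylome (cohort-wide bimodal
#' baseline plus a set deviation); individuals add a biological deviation;
#' affected individuals are shifted by the planted delta-beta at planted
#' probes (sign fixed per probe for shared probes, so direction is consistent
#' across sets); each technical replicate adds measurement noise; everything
#' is clipped to \[0,1\].
#'
#' @param config a [twin_sim_config()].
#' @return list with elements `beta` (probes x samples), `detp` (matching
#'   detection p-values), `sheet` (sample sheet), `annotation`
#'   (probe annotation) and `truth` (planted effects; see details).
#' @export
simulate_twin_methylomes <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  cfg <- config
  n_planted_total <- cfg$n_planted_dmps_shared +
    cfg$n_planted_dmps_private * cfg$n_twin_sets
  if (n_planted_total > cfg$n_probes) {
    stop("planted probes exceed n_probes", call. = FALSE)
  }
  with_seed(cfg$seed, {
    probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
    hil <- sample(HIL_LEVELS, cfg$n_probes, replace = TRUE,
                  prob = cfg$hil_fractions)
    # gene pool: ~1 gene per 4 probes, 0-2 genes per probe
    gene_pool <- sprintf("GENE%04d", seq_len(max(2, cfg$n_probes %/% 4)))
    n_genes_per_probe <- sample(0:2, cfg$n_probes, replace = TRUE,
                                prob = c(0.3, 0.55, 0.15))
    genes <- vapply(n_genes_per_probe, function(k) {
      paste(sample(gene_pool, k), collapse = ";")
    }, character(1))
    annotation <- probe_annotation(data.frame(
      probe_id = probe_ids,
      chromosome = sample(paste0("chr", 1:22), cfg$n_probes, replace = TRUE),
      position = sample.int(1e8, cfg$n_probes, replace = TRUE),
      genes = genes,
      distance_to_tss = sample(-2000:2000, cfg$n_probes, replace = TRUE),
      hil_category = hil,
      cross_hybridising = FALSE, sex_chromosome = FALSE, snp_overlap = FALSE,
      stringsAsFactors = FALSE
    ))

    hc_probes <- probe_ids[hil == "HC"]
    if (length(hc_probes) < cfg$n_planted_dmps_shared) {
      stop("not enough HC probes to plant shared DMPs", call. = FALSE)
    }
    shared <- sample(hc_probes, cfg$n_planted_dmps_shared)
    remaining <- setdiff(probe_ids, shared)
    private <- list()
    for (s in seq_len(cfg$n_twin_sets)) {
      pick <- sample(remaining, cfg$n_planted_dmps_private)
      remaining <- setdiff(remaining, pick)
      private[[paste0("set", s)]] <- pick
    }

    # cohort baseline + per-set deviation
    base <- rbeta_bimodal(cfg$n_probes)
    names(base) <- probe_ids
    # planted effects point away from the nearer beta boundary (a CpG near 0
    # can only gain methylation; one near 1 can only lose it), so the full
    # configured delta survives clipping
    shared_sign <- ifelse(base[shared] < 0.5, 1, -1)
    names(shared_sign) <- shared

    sheet_rows <- list()
    cols <- list()
    true_age <- c()
    sexes <- sample(SEX_LEVELS, cfg$n_twin_sets, replace = TRUE)
    for (s in seq_len(cfg$n_twin_sets)) {
      set_id <- paste0("set", s)
      n_ind <- if (s %in% cfg$triplet_sets) 3L else 2L
      set_dev <- stats::rnorm(cfg$n_probes, 0, cfg$biological_sd)
      set_base <- pmin(pmax(base + set_dev, 0), 1)
      base_age <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
      for (i in seq_len(n_ind)) {
        ind_id <- paste0(set_id, "_ind", i)
        status <- if (i == 1L) "affected" else "unaffected"
        ind_val <- set_base + stats::rnorm(cfg$n_probes, 0, cfg$biological_sd)
        if (status == "affected") {
          ind_val[shared] <- ind_val[shared] + shared_sign * cfg$delta_beta
          priv <- private[[set_id]]
          ind_val[priv] <- ind_val[priv] +
            ifelse(base[priv] < 0.5, 1, -1) * cfg$delta_beta
        }
        ind_val <- pmin(pmax(ind_val, 0), 1)
        for (ci in seq_len(cfg$n_collections)) {
          age <- base_age + (ci - 1) * 1.5
          rep_grp <- paste0(ind_id, "_c", ci)
          for (r in seq_len(cfg$n_replicates)) {
            sid <- paste0(rep_grp, "_r", r)
            val <- pmin(pmax(
              ind_val + stats::rnorm(cfg$n_probes, 0, cfg$replicate_sd), 0), 1)
            cols[[sid]] <- val
            true_age[sid] <- age
            sheet_rows[[sid]] <- data.frame(
              sample_id = sid, individual_id = ind_id, twin_set_id = set_id,
              disease_status = status, sex = sexes[s],
              age_at_collection = age, collection_index = ci,
              replicate_group = rep_grp, cohort = "twin",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    beta <- do.call(cbind, cols)
    rownames(beta) <- probe_ids
    sheet <- sample_sheet(do.call(rbind, sheet_rows))

    # optional clock-CpG rows encoding age
    clock <- cfg$clock
    if (!is.null(clock)) {
      emb <- clock_embedding_betas(clock, true_age)
      emb <- pmin(pmax(emb + matrix(
        stats::rnorm(length(emb), 0, cfg$replicate_sd), nrow(emb)), 0), 1)
      beta <- rbind(beta, emb)
      annotation <- probe_annotation(rbind(
        as.data.frame(annotation),
        data.frame(probe_id = rownames(emb), chromosome = "chr0",
                   position = seq_len(nrow(emb)), genes = "",
                   distance_to_tss = 0L, hil_category = "LC",
                   cross_hybridising = FALSE, sex_chromosome = FALSE,
                   snp_overlap = FALSE, stringsAsFactors = FALSE)))
    }

    detp <- matrix(stats::rbeta(length(beta), 1, 200),
                   nrow = nrow(beta), dimnames = dimnames(beta))
    fail <- stats::runif(length(detp)) < cfg$detection_fail_rate
    detp[fail] <- stats::runif(sum(fail), 0.06, 0.8)

    shared_delta <- matrix(rep(shared_sign * cfg$delta_beta,
                               cfg$n_twin_sets),
                           ncol = cfg$n_twin_sets,
                           dimnames = list(shared,
                                           paste0("set",
                                                  seq_len(cfg$n_twin_sets))))
    truth <- list(
      planted_shared_dmps = data.frame(probe_id = shared,
                                       sign = unname(shared_sign),
                                       delta_beta = rep(cfg$delta_beta,
                                                        length(shared)),
                                       stringsAsFactors = FALSE),
      planted_shared_delta = shared_delta,
      planted_private_dmps = private,
      true_ages = true_age,
      clock = clock
    )
    list(beta = beta, detp = detp, sheet = sheet, annotation = annotation,
         truth = truth)
  })
}

#' Simulate a case-control methylation cohort
#'
#' Case columns are shifted by the listed per-probe delta-beta effects; ages
#' are drawn per group and sex assigned with the configured imbalance.
#'
#' @param n_cases,n_controls group sizes (each at least 2).
#' @param probe_effects named numeric vector: probe id -> delta-beta
#'   (case minus control).
#' @param n_probes total probes (effect probes plus null filler).
#' @param age_range range of collection ages.
#' @param sex_imbalance fraction of males among cases (controls are balanced).
#' @param noise_sd individual-level noise sd on the beta scale.
#' @param seed integer seed.
#' @return list with `beta`, `sheet`, `truth`.
#' @export
simulate_case_control <- function(n_cases, n_controls,
                                  probe_effects = numeric(0),
                                  n_probes = 100, age_range = c(40, 80),
                                  sex_imbalance = 0.5, noise_sd = 0.05,
                                  seed = 1L) {
  stopifnot(n_cases >= 2, n_controls >= 2)
  with_seed(seed, {
    effect_ids <- names(probe_effects)
    n_fill <- max(0, n_probes - length(effect_ids))
    probe_ids <- unique(c(effect_ids, sprintf("ccg%05d", seq_len(n_fill))))
    n <- n_cases + n_controls
    base <- rbeta_bimodal(length(probe_ids))
    # keep planted probes mid-range so the shift is not eaten by clipping
    base[match(effect_ids, probe_ids)] <- stats::runif(length(effect_ids),
                                                       0.35, 0.65)
    names(base) <- probe_ids
    sids <- sprintf("cc_s%04d", seq_len(n))
    beta <- matrix(base, nrow = length(probe_ids), ncol = n,
                   dimnames = list(probe_ids, sids)) +
      matrix(stats::rnorm(length(probe_ids) * n, 0, noise_sd),
             nrow = length(probe_ids))
    status <- rep(c("affected", "control"), c(n_cases, n_controls))
    beta[effect_ids, status == "affected"] <-
      beta[effect_ids, status == "affected"] + probe_effects
    clipped <- beta < 0 | beta > 1
    if (any(clipped[effect_ids, ])) {
      warning("planted probe effects clipped at [0,1] for some samples",
              call. = FALSE)
    }
    beta <- pmin(pmax(beta, 0), 1)
    sex <- c(ifelse(stats::runif(n_cases) < sex_imbalance, "M", "F"),
             ifelse(stats::runif(n_controls) < 0.5, "M", "F"))
    sheet <- sample_sheet(data.frame(
      sample_id = sids, individual_id = sids, twin_set_id = "none",
      disease_status = status, sex = sex,
      age_at_collection = stats::runif(n, age_range[1], age_range[2]),
      collection_index = 1L, replicate_group = sids,
      cohort = "case_control", stringsAsFactors = FALSE))
    # single-sample "sets" are permitted only in case-control cohorts
    truth <- list(probe_effects = probe_effects)
    list(beta = beta, sheet = sheet, truth = truth)
  })
}

#' Simulate an EpiTYPER-like amplicon plate
#'
#' Values are percent methylation per CpG unit. Designated failed samples and
#' units receive at least 90 percent missing entries; all other cells are
#' missing independently at `missing_rate`.
#'
#' @param n_units,n_samples plate dimensions.
#' @param missing_rate background missingness fraction.
#' @param failed_samples,failed_units number of planted failures.
#' @param seed integer seed.
#' @return list with `plate` (an [epityper_plate()]) and `truth` (planted
#'   failed ids).
#' @export
simulate_epityper <- function(n_units, n_samples, missing_rate = 0.05,
                              failed_samples = 0, failed_units = 0,
                              seed = 1L) {
  stopifnot(failed_samples <= n_samples, failed_units <= n_units)
  with_seed(seed, {
    unit_ids <- sprintf("unit%03d", seq_len(n_units))
    sample_ids <- sprintf("ep_s%03d", seq_len(n_samples))
    base <- 100 * rbeta_bimodal(n_units)
    vals <- matrix(base, n_units, n_samples) +
      matrix(stats::rnorm(n_units * n_samples, 0, 5), n_units)
    vals <- pmin(pmax(vals, 0), 100)
    dimnames(vals) <- list(unit_ids, sample_ids)
    if (missing_rate > 0) {
      vals[stats::runif(length(vals)) < missing_rate] <- NA_real_
    }
    fs <- if (failed_samples > 0) sample(sample_ids, failed_samples) else character(0)
    fu <- if (failed_units > 0) sample(setdiff(unit_ids, character(0)),
                                       failed_units) else character(0)
    for (s in fs) {
      miss <- sample.int(n_units, ceiling(0.95 * n_units))
      vals[miss, s] <- NA_real_
    }
    for (u in fu) {
      miss <- sample.int(n_samples, ceiling(0.95 * n_samples))
      vals[u, miss] <- NA_real_
    }
    plate <- epityper_plate(vals,
                            n_sites = sample(1:3, n_units, replace = TRUE),
                            plate_id = "simplate1")
    list(plate = plate,
         truth = list(failed_samples = fs, failed_units = fu))
  })
}

#' Inject replicate-discordance artifacts at selected probes
#'
#' Emulates the artifact class the replicate-variance probe filter targets
#' (e.g. probes overlapping SNPs or cross-hybridising, where technical
#' replicates of the same DNA can straddle genotype-like methylation
#' states): at each injected probe, `n_bad_pairs` randomly chosen replicate
#' pairs have one member displaced by a large discrete shift (direction
#' away from the nearer beta boundary) plus jitter, while all other pairs
#' stay concordant.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet defining replicate groups.
#' @param probes probe ids to corrupt.
#' @param n_bad_pairs discordant pairs per probe, default 2.
#' @param shift discordance magnitude on the beta scale, default 0.5.
#' @param jitter_sd sd of the jitter added to the shift.
#' @param seed integer seed.
#' @return the modified beta matrix.
#' @export
inject_replicate_discordance <- function(beta, sheet, probes,
                                         n_bad_pairs = 2, shift = 0.5,
                                         jitter_sd = 0.02, seed = 1L) {
  with_seed(seed, {
    groups <- split(sheet$sample_id, sheet$replicate_group)
    groups <- groups[vapply(groups, length, 1L) >= 2]
    for (p in probes) {
      bad <- sample(length(groups), n_bad_pairs)
      for (g in bad) {
        ids <- groups[[g]]
        victim <- ids[2]
        v <- beta[p, victim]
        dir <- if (v < 0.5) 1 else -1
        beta[p, victim] <- min(max(
          v + dir * (shift + stats::rnorm(1, 0, jitter_sd)), 0), 1)
      }
    }
    beta
  })
}

#' Build a synthetic epigenetic clock with an invertible age embedding
#'
#' Returns a clock (intercept + per-CpG weights + output transform) together
#' with an embedding rule that maps a chronological age to clock-CpG beta
#' values. Each clock CpG carries the age signal linearly on the transformed
#' age scale, beta_j = a_j + b_j * f(age), with slopes scaled so values stay
#' inside \[0.05, 0.95\] over ages 0-100; weights are solved so the clock's
#' linear predictor equals f(age) exactly, making noiseless recovery exact.
#'
#' @param n_clock_cpgs number of clock CpGs (>= 1).
#' @param transform `"identity"` (predictor is the age) or `"horvath"`
#'   (log-linear age transform around `adult_age`).
#' @param adult_age transition age of the horvath transform.
#' @param seed integer seed.
#' @return a `clock_model` (see [clock_model()]) with an `embedding`
#'   data.frame attached.
#' @export
make_synthetic_clock <- function(n_clock_cpgs = 20,
                                 transform = c("identity", "horvath"),
                                 adult_age = 20, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(n_clock_cpgs >= 1)
  with_seed(seed, {
    cpgs <- sprintf("clockcg%04d", seq_len(n_clock_cpgs))
    tmax <- max(abs(age_transform(c(0, 100), transform, adult_age)))
    b <- stats::runif(n_clock_cpgs, 0.05, 0.15) *
      sample(c(-1, 1), n_clock_cpgs, replace = TRUE) * (0.4 / tmax)
    a <- stats::runif(n_clock_cpgs, 0.45, 0.55)
    w <- b / sum(b^2)
    model <- clock_model(intercept = -sum(w * a),
                         coefficients = stats::setNames(w, cpgs),
                         transform = transform, adult_age = adult_age)
    model$embedding <- data.frame(cpg = cpgs, a = a, b = b,
                                  stringsAsFactors = FALSE)
    model
  })
}

#' Clock-CpG beta values encoding a vector of ages
#'
#' Applies a synthetic clock's embedding rule: for each age, clock CpG j gets
#' beta = a_j + b_j * f(age). By construction [dnam_age()] on the result
#' returns the input ages exactly.
#'
#' @param clock a synthetic clock from [make_synthetic_clock()].
#' @param ages named numeric vector of ages (names become column names).
#' @return matrix of clock-CpG betas (clock CpGs x samples).
#' @export
clock_embedding_betas <- function(clock, ages) {
  emb <- clock$embedding
  if (is.null(emb)) stop("clock has no embedding (not a synthetic clock)",
                         call. = FALSE)
  t_age <- age_transform(ages, clock$transform, clock$adult_age)
  out <- outer(emb$b, t_age) + emb$a
  dimnames(out) <- list(emb$cpg, names(ages))
  out
}

#' Simulate negative-binomial RNA-seq counts for a twin design
#'
#' Counts are drawn per gene and sample from a negative binomial with
#' gene-level baseline means, a per-collection batch offset, and planted
#' genes scaled by `2^log2fc` in affected columns.
#'
#' @param n_genes number of genes.
#' @param sheet sample sheet subset (the samples to simulate).
#' @param n_planted_degs number of planted differentially expressed genes.
#' @param log2fc planted log2 fold change (affected over unaffected).
#' @param dispersion NB dispersion (size = 1/dispersion). Default 0.01,
#'   i.e. a biological coefficient of variation of 0.1 — the standard
#'   figure for genetically identical subjects, which MZ co-twins are.
#' @param baseline_logmean_range range of log2 baseline mean counts.
#'   Default c(4, 12) (16-4096 counts): genes surviving the CPM filter sit
#'   above roughly a dozen raw counts, so the simulated baseline starts
#'   there.
#' @param batch_sd sd of per-collection batch offsets on the log2 scale.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix) and `truth`
#'   (planted gene ids + log2fc).
#' @export
simulate_counts <- function(n_genes, sheet, n_planted_degs = 0, log2fc = 1,
                            dispersion = 0.01,
                            baseline_logmean_range = c(4, 12),
                            batch_sd = 0.1, seed = 1L) {
  stopifnot(n_planted_degs <= n_genes)
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    base <- stats::runif(n_genes, baseline_logmean_range[1],
                         baseline_logmean_range[2])
    planted <- if (n_planted_degs > 0) sample(gene_ids, n_planted_degs)
               else character(0)
    collections <- sort(unique(sheet$collection_index))
    batch <- stats::setNames(stats::rnorm(length(collections), 0, batch_sd),
                             collections)
    is_affected <- sheet$disease_status %in% c("affected",
                                               "asymptomatic_carrier")
    mu <- matrix(2^base, n_genes, nrow(sheet))
    for (j in seq_len(nrow(sheet))) {
      mu[, j] <- mu[, j] * 2^batch[as.character(sheet$collection_index[j])]
      if (is_affected[j]) {
        mu[match(planted, gene_ids), j] <-
          mu[match(planted, gene_ids), j] * 2^log2fc
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion,
                                    mu = mu),
                     n_genes, nrow(sheet),
                     dimnames = list(gene_ids, sheet$sample_id))
    storage.mode(counts) <- "integer"
    list(counts = counts,
         truth = list(planted_degs = planted, log2fc = log2fc))
  })
}
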