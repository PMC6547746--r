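# Sample- and probe-level QC of the 450K-style beta matrix: detection-based
# filters, the replicate-variance probe filter leveraging technical
# replicates, blacklist removal and the clock-correlation sample gate.
# The pipeline ingests an already-normalised beta matrix; intensity-level
# normalisation is upstream of this package.

#' Remove samples with poor genome-wide detection
#'
#' A sample is retained iff the fraction of probes detected (detection
#' p <= `p_threshold`) is at least `min_detected_fraction`.
#'
#' @param detp detection p-value matrix (probes x samples).
#' @param min_detected_fraction default 0.99.
#' @param p_threshold default 0.05.
#' @return list with `retained` sample ids and `removed` (named numeric of
#'   detected fractions for dropped samples).
#' @export
filter_samples_by_detection <- function(detp, min_detected_fraction = 0.99,
                                        p_threshold = 0.05) {
  detected <- colMeans(detp <= p_threshold, na.rm = TRUE)
  keep <- detected >= min_detected_fraction
  list(retained = colnames(detp)[keep],
       removed = detected[!keep])
}

#' Remove probes that fail detection
#'
#' A probe is removed iff it fails detection (p > `p_threshold`) in more
#' than `max_failed_samples` of the retained samples. The default removes
#' a probe failing in any sample.
#'
#' @param detp detection p-value matrix restricted to retained samples.
#' @param p_threshold default 0.05.
#' @param max_failed_samples default 0.
#' @return list with `retained` and `removed` probe ids.
#' @export
filter_probes_by_detection <- function(detp, p_threshold = 0.05,
                                       max_failed_samples = 0) {
  n_failed <- rowSums(detp > p_threshold, na.rm = TRUE)
  keep <- n_failed <= max_failed_samples
  list(retained = rownames(detp)[keep], removed = rownames(detp)[!keep])
}

# all within-replicate-group sample pairs in a sheet
replicate_pairs <- function(sheet) {
  groups <- split(sheet$sample_id, sheet$replicate_group)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  pairs <- lapply(groups, function(ids) {
    cmb <- utils::combn(ids, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  })
  if (!length(pairs)) return(data.frame(a = character(0), b = character(0)))
  do.call(rbind, pairs)
}

#' Replicate-variance probe filter
#'
#' For each probe, absolute beta differences are computed over all technical
#' replicate/duplicate pairs. A pair is an outlier when its difference
#' exceeds the probe's mean difference by more than `sd_multiplier` standard
#' deviations; a probe is discarded when it has at least `min_outlier_pairs`
#' such pairs ("multiple pairs").
#'
#' @param beta beta matrix (probes x samples).
#' @param sheet sample sheet defining replicate groups.
#' @param sd_multiplier default 3.
#' @param min_outlier_pairs default 2.
#' @return character vector of removed probe ids (possibly empty).
#' @export
replicate_variance_filter <- function(beta, sheet, sd_multiplier = 3,
                                      min_outlier_pairs = 2) {
  pairs <- replicate_pairs(sheet)
  pairs <- pairs[pairs$a %in% colnames(beta) & pairs$b %in% colnames(beta), ]
  if (nrow(pairs) < 3) {
    warning("fewer than 3 replicate pairs; replicate_variance_filter is a ",
            "no-op", call. = FALSE)
    return(character(0))
  }
  d <- abs(beta[, pairs$a, drop = FALSE] - beta[, pairs$b, drop = FALSE])
  mu <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  cutoff <- mu + sd_multiplier * sd_d
  n_outlier <- rowSums(d > cutoff)
  rownames(beta)[n_outlier >= min_outlier_pairs]
}

#' Blacklist probe filter
#'
#' Removes probes carrying any of the selected annotation flags
#' (cross-hybridising, sex-chromosome, SNP-overlapping).
#'
#' @param annotation a `probe_annotation`.
#' @param flags subset of `c("cross_hybridising", "sex_chromosome",
#'   "snp_overlap")`; default all three.
#' @return list with `removed` probe ids and `removed_by_flag` (per-flag id
#'   lists; a probe may appear under several flags).
#' @export
blacklist_filter <- function(annotation,
                             flags = c("cross_hybridising", "sex_chromosome",
                                       "snp_overlap")) {
  flags <- match.arg(flags, several.ok = TRUE)
  by_flag <- lapply(flags, function(fl) {
    annotation$probe_id[annotation[[fl]]]
  })
  names(by_flag) <- flags
  list(removed = unique(unlist(by_flag, use.names = FALSE)),
       removed_by_flag = by_flag)
}

#' Clock-correlation sample gate
#'
#' Each sample's clock-CpG beta vector is correlated (Pearson) with a
#' gold-standard per-CpG profile; samples with r below `r_threshold` (or an
#' undefined correlation) are removed.
#'
#' @param beta beta matrix containing clock CpG rows.
#' @param gold_profile named numeric vector: clock CpG -> reference beta.
#' @param r_threshold default 0.85.
#' @return data.frame with columns `sample_id`, `r`, `removed`, `reason`.
#' @export
clock_correlation_gate <- function(beta, gold_profile, r_threshold = 0.85) {
  cpgs <- intersect(names(gold_profile), rownames(beta))
  if (length(cpgs) < 3) {
    stop("need at least 3 clock CpGs present in both matrix and profile",
         call. = FALSE)
  }
  sub <- beta[cpgs, , drop = FALSE]
  ref <- gold_profile[cpgs]
  res <- lapply(colnames(sub), function(s) {
    x <- sub[, s]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      data.frame(sample_id = s, r = NA_real_, removed = TRUE,
                 reason = "undefined correlation",
                 stringsAsFactors = FALSE)
    } else {
      r <- stats::cor(x, ref, use = "complete.obs")
      data.frame(sample_id = s, r = r, removed = r < r_threshold,
                 reason = ifelse(r < r_threshold, "low correlation", ""),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Run the full array QC pipeline
#'
#' Applies, in order: sample detection filter, probe detection filter,
#' replicate-variance probe filter, blacklist removal and (optionally) the
#' clock-correlation sample gate, then subsets the beta matrix. QC never
#' alters retained values, only membership.
#'
#' @param beta beta matrix.
#' @param detp detection p-value matrix (same shape).
#' @param sheet sample sheet.
#' @param annotation probe annotation covering the probes.
#' @param blacklist_flags flags passed to [blacklist_filter()].
#' @param gold_profile optional clock gold-standard profile.
#' @param ... tuning parameters forwarded to the individual filters
#'   (`min_detected_fraction`, `p_threshold`, `max_failed_samples`,
#'   `sd_multiplier`, `min_outlier_pairs`, `r_threshold`).
#' @return list with `beta` (filtered), `report` (an `array_qc_report`).
#' @export
run_array_qc <- function(beta, detp, sheet, annotation,
                         blacklist_flags = c("cross_hybridising",
                                             "sex_chromosome", "snp_overlap"),
                         gold_profile = NULL, ...) {
  dots <- list(...)
  arg <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  samp <- filter_samples_by_detection(
    detp, min_detected_fraction = arg("min_detected_fraction", 0.99),
    p_threshold = arg("p_threshold", 0.05))
  detp_s <- detp[, samp$retained, drop = FALSE]
  beta_s <- beta[, samp$retained, drop = FALSE]

  prob <- filter_probes_by_detection(
    detp_s, p_threshold = arg("p_threshold", 0.05),
    max_failed_samples = arg("max_failed_samples", 0))
  beta_p <- beta_s[prob$retained, , drop = FALSE]

  sheet_s <- sheet[sheet$sample_id %in% samp$retained, , drop = FALSE]
  rep_rm <- replicate_variance_filter(
    beta_p, sheet_s, sd_multiplier = arg("sd_multiplier", 3),
    min_outlier_pairs = arg("min_outlier_pairs", 2))
  beta_p <- beta_p[setdiff(rownames(beta_p), rep_rm), , drop = FALSE]

  bl <- blacklist_filter(annotation, blacklist_flags)
  beta_p <- beta_p[setdiff(rownames(beta_p), bl$removed), , drop = FALSE]

  gate <- NULL
  if (!is.null(gold_profile)) {
    gate <- clock_correlation_gate(beta, gold_profile,
                                   r_threshold = arg("r_threshold", 0.85))
    drop <- gate$sample_id[gate$removed]
    beta_p <- beta_p[, setdiff(colnames(beta_p), drop), drop = FALSE]
  }
  report <- structure(list(
    removed_samples_detection = samp$removed,
    removed_probes_detection = prob$removed,
    removed_probes_replicate_variance = rep_rm,
    removed_probes_blacklist = bl$removed_by_flag,
    removed_samples_clock_gate =
      if (is.null(gate)) character(0) else gate$sample_id[gate$removed]
  ), class = "array_qc_report")
  list(beta = beta_p, report = report)
}
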