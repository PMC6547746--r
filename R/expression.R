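# Paired longitudinal differential expression and case-control validation:
# CPM filtering, trimmed-mean-of-M-values (TMM) scaling factors, gene-wise
# linear models on log2-CPM with optional mean-variance precision weights,
# FDR and fold-change gating. Gene-wise empirical-Bayes moderation is
# deliberately not implemented; ordinary least squares with precision
# weights is the documented approximation.

#' Counts per million
#' @param counts genes x samples count matrix.
#' @param lib_sizes library sizes; default column sums.
#' @return CPM matrix.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive",
                                call. = FALSE)
  t(t(counts) / lib_sizes) * 1e6
}

#' CPM expression filter
#'
#' A gene is retained iff its CPM (computed on raw library sizes) is
#' strictly greater than `min_cpm` in at least `min_samples` samples.
#'
#' @param counts genes x samples count matrix.
#' @param min_cpm CPM threshold (exclusive).
#' @param min_samples minimum number of samples exceeding it.
#' @return character vector of retained gene ids.
#' @export
cpm_filter <- function(counts, min_cpm, min_samples) {
  keep <- rowSums(cpm(counts) > min_cpm) >= min_samples
  rownames(counts)[keep]
}

# quantile of CPM per column (reference-selection statistic)
calc_factor_quantile <- function(counts, lib_sizes, p = 0.75) {
  apply(t(t(counts) / lib_sizes), 2, stats::quantile, probs = p)
}

# TMM factor of one column against the reference column
tmm_pair <- function(obs, ref, lib_obs, lib_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalisation factors
#'
#' Weighted trimmed mean of log2 CPM ratios against a reference column (the
#' sample whose upper-quartile CPM is closest to the mean upper-quartile),
#' with double trimming by log-ratio and by average log expression and
#' inverse asymptotic binomial variance weights; factors are rescaled so
#' their geometric mean is 1.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param logratio_trim fraction trimmed from each tail of the log-ratios,
#'   default 0.30.
#' @param abs_trim fraction trimmed by average expression, default 0.05.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero column(s) present", call. = FALSE)
  # all-zero genes carry no ratio information and would distort the
  # reference-selection quantile
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  f75 <- calc_factor_quantile(counts, lib, 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalise counts to log2-CPM with TMM effective library sizes
#'
#' @param counts genes x samples count matrix (post CPM filter).
#' @param prior_count added before logging, default 0.5.
#' @return list of class `normalised_expression`: `logcpm` matrix,
#'   `tmm_factors`, `effective_lib_sizes`.
#' @export
normalise_expression <- function(counts, prior_count = 0.5) {
  fac <- tmm_factors(counts)
  eff <- colSums(counts) * fac
  logcpm <- log2(t((t(counts) + prior_count) / (eff + 1)) * 1e6)
  structure(list(logcpm = logcpm, tmm_factors = fac,
                 effective_lib_sizes = eff),
            class = "normalised_expression")
}

# voom-style observation-level precision weights: lowess of residual sd
# (quarter-root of variance) against fitted average log2 count
precision_weights <- function(logcpm, X, eff_lib) {
  qx <- qr(X)
  fit <- t(qr.fitted(qx, t(logcpm)))
  res <- logcpm - fit
  sigma <- sqrt(rowSums(res^2) / (ncol(logcpm) - qx$rank))
  # average log2 count per gene
  mean_lc <- rowMeans(logcpm) + mean(log2(eff_lib + 1)) - log2(1e6)
  lo <- stats::lowess(mean_lc, sqrt(sigma), f = 0.5)
  interp <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  # per-observation fitted log-count
  fitted_lc <- fit + matrix(log2(eff_lib + 1), nrow(fit), ncol(fit),
                            byrow = TRUE) - log2(1e6)
  w <- interp(fitted_lc)^(-4)
  dim(w) <- dim(logcpm)
  dimnames(w) <- dimnames(logcpm)
  w
}

# gene-wise weighted least squares for a common design; returns the stats
# of one coefficient
genewise_lm <- function(Y, X, coef_name, weights = NULL) {
  n <- ncol(Y); p <- ncol(X)
  ci <- match(coef_name, colnames(X))
  if (is.na(ci)) stop("coefficient '", coef_name, "' not in design",
                      call. = FALSE)
  if (is.null(weights)) {
    qx <- qr(X)
    if (qx$rank < p) stop("rank-deficient design", call. = FALSE)
    coefs <- t(qr.coef(qx, t(Y)))
    fitted <- coefs %*% t(X)
    rss <- rowSums((Y - fitted)^2)
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(rss / (n - p) * xtx_inv[ci, ci])
    est <- coefs[, ci]
  } else {
    est <- se <- numeric(nrow(Y))
    for (g in seq_len(nrow(Y))) {
      w <- weights[g, ]
      fit <- stats::lm.wfit(X, Y[g, ], w)
      rss <- sum(w * fit$residuals^2)
      R <- qr.R(fit$qr)
      xtx_inv <- chol2inv(R)
      est[g] <- fit$coefficients[ci]
      se[g] <- sqrt(rss / (n - p) * xtx_inv[ci, ci])
    }
  }
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  data.frame(gene_id = rownames(Y), log2_fold_change = unname(est),
             t_statistic = unname(tstat), p_value = unname(pval),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired longitudinal differential expression for a discordant pair
#'
#' Gene-wise linear models on log2-CPM with fixed terms for disease and
#' longitudinal collection (collection index as a factor), optionally with
#' voom-style mean-variance precision weights. Positive log2 fold change
#' means higher expression in the affected twin. Collections present for
#' only one twin are dropped with a warning. BH-FDR is applied across all
#' tested genes.
#'
#' @param norm a `normalised_expression`.
#' @param sheet sample sheet covering the matrix columns (one discordant
#'   pair with >= 2 shared collections).
#' @param use_weights apply precision weights, default TRUE.
#' @return data.frame per gene: `gene_id`, `log2_fold_change`,
#'   `t_statistic`, `p_value`, `fdr`.
#' @export
paired_de_test <- function(norm, sheet, use_weights = TRUE) {
  sheet <- as.data.frame(sheet)
  idx <- match(colnames(norm$logcpm), sheet$sample_id)
  if (anyNA(idx)) stop("matrix columns absent from sheet", call. = FALSE)
  meta <- sheet[idx, ]
  disease <- disease_indicator(meta$disease_status)
  # drop collections observed in only one arm
  tab <- table(meta$collection_index, disease)
  bad <- rownames(tab)[apply(tab > 0, 1, sum) < 2]
  if (length(bad)) {
    warning("dropping unbalanced collection(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    keep <- !(as.character(meta$collection_index) %in% bad)
    meta <- meta[keep, ]
    disease <- disease[keep]
    norm$logcpm <- norm$logcpm[, keep, drop = FALSE]
    norm$effective_lib_sizes <- norm$effective_lib_sizes[keep]
  }
  if (length(unique(meta$collection_index)) < 2) {
    stop("need >= 2 shared collections for the paired design", call. = FALSE)
  }
  X <- stats::model.matrix(~ disease + collection,
                           data.frame(disease = disease,
                                      collection =
                                        factor(meta$collection_index)))
  W <- if (use_weights) {
    precision_weights(norm$logcpm, X, norm$effective_lib_sizes)
  } else NULL
  out <- genewise_lm(norm$logcpm, X, "diseaseaffected", W)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' FDR and fold-change gating of DE results
#'
#' @param results data.frame from [paired_de_test()] (or compatible).
#' @param fdr_threshold default 0.05 (exclusive).
#' @param fc_threshold fold-change threshold on the natural scale,
#'   default 1.5 (inclusive on |log2FC|).
#' @return the subset passing both gates, with `passes_fc_gate` column.
#' @export
threshold_degs <- function(results, fdr_threshold = 0.05,
                           fc_threshold = 1.5) {
  pass <- !is.na(results$fdr) & results$fdr < fdr_threshold &
    abs(results$log2_fold_change) >= log2(fc_threshold)
  out <- results[pass, , drop = FALSE]
  out$passes_fc_gate <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Validate twin DEGs in a case-control cohort
#'
#' Restricts to the subset genes present after filtering, models each as
#' `log2-CPM ~ disease + sex`, and applies BH-FDR across the present subset
#' only (not the whole genome).
#'
#' @param counts case-control count matrix (post CPM filter).
#' @param sheet case-control sample sheet.
#' @param gene_subset twin-identified gene ids to validate.
#' @param use_weights apply precision weights, default TRUE.
#' @return list: `results` (per present gene), `present`, `absent`.
#' @export
validate_degs_case_control <- function(counts, sheet, gene_subset,
                                       use_weights = TRUE) {
  if (!length(gene_subset)) stop("empty gene subset", call. = FALSE)
  present <- intersect(gene_subset, rownames(counts))
  absent <- setdiff(gene_subset, present)
  if (!length(present)) {
    return(list(results = data.frame(), present = character(0),
                absent = absent))
  }
  norm <- normalise_expression(counts)
  sheet <- as.data.frame(sheet)
  idx <- match(colnames(counts), sheet$sample_id)
  if (anyNA(idx)) stop("matrix columns absent from sheet", call. = FALSE)
  meta <- sheet[idx, ]
  disease <- disease_indicator(meta$disease_status)
  X <- stats::model.matrix(~ disease + sex,
                           data.frame(disease = disease,
                                      sex = factor(meta$sex)))
  Y <- norm$logcpm[present, , drop = FALSE]
  W <- if (use_weights) {
    precision_weights(norm$logcpm, X,
                      norm$effective_lib_sizes)[present, , drop = FALSE]
  } else NULL
  out <- genewise_lm(Y, X, "diseaseaffected", W)
  out$fdr <- bh_fdr(out$p_value)
  list(results = out, present = present, absent = absent)
}
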