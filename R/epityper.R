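# QC of amplicon (mass-spectrometry) CpG-unit methylation plates: duplicate
# averaging, the two-step missingness filter, unit-mean imputation and the
# between-plate coefficient of variation from a highly methylated control.

#' Construct an EpiTYPER-like plate
#'
#' A plate holds percent methylation per CpG unit (a unit is one or more
#' adjacent CpG sites quantified as a single mass fragment) for a set of
#' samples; entries may be missing.
#'
#' @param values numeric matrix (units x samples), percent in \[0,100\] or NA.
#' @param n_sites integer vector, CpG sites per unit.
#' @param plate_id plate identifier.
#' @param control_sample_ids columns holding highly methylated control DNA.
#' @return list of class `epityper_plate`.
#' @export
epityper_plate <- function(values, n_sites = rep(1L, nrow(values)),
                           plate_id = "plate1",
                           control_sample_ids = character(0)) {
  stopifnot(is.matrix(values), length(n_sites) == nrow(values))
  if (any(!is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 100) {
      stop("plate values must be percentages in [0,100]", call. = FALSE)
    }
  }
  if (!all(control_sample_ids %in% colnames(values))) {
    stop("control_sample_ids must be plate columns", call. = FALSE)
  }
  structure(list(values = values, n_sites = as.integer(n_sites),
                 plate_id = plate_id,
                 control_sample_ids = control_sample_ids),
            class = "epityper_plate")
}

#' Read an EpiTYPER plate TSV
#'
#' Expected layout: `unit_id`, `n_sites`, then one column per sample; empty
#' cells or `NA` are missing.
#'
#' @param path file path.
#' @param plate_id plate identifier.
#' @param control_sample_ids control columns, if any.
#' @return an `epityper_plate`.
#' @export
read_epityper_plate <- function(path, plate_id = "plate1",
                                control_sample_ids = character(0)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  stopifnot(all(c("unit_id", "n_sites") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("unit_id", "n_sites")),
                       drop = FALSE])
  rownames(vals) <- df$unit_id
  epityper_plate(vals, n_sites = df$n_sites, plate_id = plate_id,
                 control_sample_ids = control_sample_ids)
}

#' Write an EpiTYPER plate TSV
#' @param plate an `epityper_plate`.
#' @param path output path.
#' @export
write_epityper_plate <- function(plate, path) {
  df <- data.frame(unit_id = rownames(plate$values),
                   n_sites = plate$n_sites, plate$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Average CpG-site percentages within one unit
#'
#' Units spanning several CpG sites are normalised by averaging the
#' per-site percentages; missing sites are excluded.
#'
#' @param site_values numeric vector of per-site percent methylation.
#' @return the unit percentage, or NA if every site is missing.
#' @export
average_unit_sites <- function(site_values) {
  if (all(is.na(site_values))) return(NA_real_)
  mean(site_values, na.rm = TRUE)
}

#' Average duplicate samples of one collection
#'
#' Columns sharing a `replicate_group` in the sheet are collapsed to their
#' per-unit mean over non-missing values; the result is missing only where
#' all duplicates are missing. Output columns are named by replicate group
#' (singleton samples keep behaviour but gain their group's name).
#'
#' @param plate an `epityper_plate`.
#' @param sheet a `twin_sample_sheet` covering the plate columns.
#' @return an `epityper_plate` with one column per replicate group.
#' @export
average_duplicates <- function(plate, sheet) {
  idx <- match(colnames(plate$values), sheet$sample_id)
  if (anyNA(idx)) {
    stop("plate column(s) absent from sheet: ",
         paste(colnames(plate$values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  groups <- sheet$replicate_group[idx]
  out <- sapply(unique(groups), function(g) {
    cols <- plate$values[, groups == g, drop = FALSE]
    rowMeans(cols, na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(plate$values),
                dimnames = list(rownames(plate$values), unique(groups)))
  ctrl <- unique(groups[colnames(plate$values) %in% plate$control_sample_ids])
  epityper_plate(out, n_sites = plate$n_sites, plate_id = plate$plate_id,
                 control_sample_ids = ctrl)
}

frac_missing_rows <- function(m) rowMeans(is.na(m))
frac_missing_cols <- function(m) colMeans(is.na(m))

#' Two-step sample/unit missingness filter
#'
#' Step 1 removes failed samples (missing fraction at or above
#' `fail_threshold`), then failed units, recomputing fractions over the
#' remaining samples. Step 2 removes low-detection samples (missing fraction
#' at or above `low_detect_threshold` over remaining units), then
#' low-detection units. Thresholds are inclusive.
#'
#' @param plate an `epityper_plate`.
#' @param fail_threshold step-1 missing fraction, default 0.90.
#' @param low_detect_threshold step-2 missing fraction, default 0.15.
#' @return list with `plate` (filtered) and `report` (an `epityper_qc_report`
#'   recording each removal with the triggering missing fraction).
#' @export
two_step_filter <- function(plate, fail_threshold = 0.90,
                            low_detect_threshold = 0.15) {
  v <- plate$values
  if (length(v) == 0) stop("empty plate", call. = FALSE)
  removals <- list()

  drop_cols <- function(m, thr) {
    f <- frac_missing_cols(m)
    names(f)[f >= thr]
  }
  drop_rows <- function(m, thr) {
    f <- frac_missing_rows(m)
    names(f)[f >= thr]
  }

  s1_samples <- drop_cols(v, fail_threshold)
  removals$removed_samples_step1 <- stats::setNames(
    frac_missing_cols(v)[s1_samples], s1_samples)
  v1 <- v[, setdiff(colnames(v), s1_samples), drop = FALSE]

  s1_units <- drop_rows(v1, fail_threshold)
  removals$removed_units_step1 <- stats::setNames(
    frac_missing_rows(v1)[s1_units], s1_units)
  v1 <- v1[setdiff(rownames(v1), s1_units), , drop = FALSE]

  s2_samples <- drop_cols(v1, low_detect_threshold)
  removals$removed_samples_step2 <- stats::setNames(
    frac_missing_cols(v1)[s2_samples], s2_samples)
  v2 <- v1[, setdiff(colnames(v1), s2_samples), drop = FALSE]

  s2_units <- drop_rows(v2, low_detect_threshold)
  removals$removed_units_step2 <- stats::setNames(
    frac_missing_rows(v2)[s2_units], s2_units)
  v2 <- v2[setdiff(rownames(v2), s2_units), , drop = FALSE]

  report <- structure(list(
    removed_samples_step1 = removals$removed_samples_step1,
    removed_units_step1 = removals$removed_units_step1,
    removed_samples_step2 = removals$removed_samples_step2,
    removed_units_step2 = removals$removed_units_step2,
    n_imputed = 0L, plate_cv_percent = NA_real_
  ), class = "epityper_qc_report")

  if (ncol(v2) == 0) {
    err <- simpleError("two_step_filter removed every sample")
    err$report <- report
    stop(err)
  }
  keep_units <- rownames(v2)
  out <- epityper_plate(v2, n_sites = plate$n_sites[
    match(keep_units, rownames(plate$values))],
    plate_id = plate$plate_id,
    control_sample_ids = intersect(plate$control_sample_ids, colnames(v2)))
  list(plate = out, report = report)
}

#' Impute remaining missing values with unit means
#'
#' @param plate an `epityper_plate` (post-filter; every unit must retain at
#'   least one measured value).
#' @return plate with no missing cells; attribute `n_imputed` counts
#'   replacements.
#' @export
impute_unit_means <- function(plate) {
  v <- plate$values
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("unit(s) with no non-missing values: ",
         paste(rownames(v)[all_missing], collapse = ", "), call. = FALSE)
  }
  n_imputed <- sum(is.na(v))
  means <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- means[idx[, 1]]
  out <- epityper_plate(v, n_sites = plate$n_sites, plate_id = plate$plate_id,
                        control_sample_ids = plate$control_sample_ids)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Between-plate coefficient of variation
#'
#' CV of the highly methylated control DNA across plate batches,
#' 100 * sd / mean.
#'
#' @param control_values one control measurement per plate batch (>= 2).
#' @return CV in percent.
#' @export
plate_cv <- function(control_values) {
  x <- control_values[!is.na(control_values)]
  if (length(x) < 2) stop("plate_cv needs at least two control values",
                          call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("plate_cv undefined: control mean is zero", call. = FALSE)
  100 * stats::sd(x) / m
}
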