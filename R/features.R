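# Per-sample features derived from the QC'd beta matrix: global and
# CpG-density-stratified mean methylation, epigenetic (DNA methylation) age
# from a published-style clock coefficient table, and reference-based blood
# cell-type deconvolution by constrained least squares.

#' Construct an epigenetic clock model
#'
#' A clock is an intercept plus per-CpG weights applied to beta values,
#' followed by an output transform: `identity` (the linear predictor is the
#' age) or `horvath` (log-linear transform around `adult_age`: predictors
#' below zero map through an exponential, above through a line, continuous
#' at zero where the age equals `adult_age`).
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector, clock CpG -> weight.
#' @param transform `"identity"` or `"horvath"`.
#' @param adult_age transition age for the horvath transform (> 0).
#' @return list of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients,
                        transform = c("identity", "horvath"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  if (length(coefficients) < 1 || is.null(names(coefficients))) {
    stop("clock needs at least one named coefficient", call. = FALSE)
  }
  if (transform == "horvath" && adult_age <= 0) {
    stop("adult_age must be positive for the horvath transform",
         call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 transform = transform, adult_age = adult_age),
            class = "clock_model")
}

# transformed-age scale used by the horvath-style clock
age_transform <- function(age, transform, adult_age = 20) {
  if (transform == "identity") return(age)
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

# inverse of age_transform on the linear-predictor scale
age_anti_transform <- function(x, transform, adult_age = 20) {
  if (transform == "identity") return(x)
  ifelse(x < 0, (1 + adult_age) * exp(x) - 1,
         (1 + adult_age) * x + adult_age)
}

#' Read a clock coefficient CSV
#'
#' Columns `cpg` and `weight`; the row whose `cpg` is `"(Intercept)"` holds
#' the intercept.
#'
#' @param path file path.
#' @param transform,adult_age passed to [clock_model()].
#' @return a `clock_model`.
#' @export
read_clock <- function(path, transform = c("identity", "horvath"),
                       adult_age = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cpg", "weight") %in% names(df)))
  ic <- df$cpg == "(Intercept)"
  intercept <- if (any(ic)) df$weight[ic][1] else 0
  co <- df[!ic, ]
  clock_model(intercept, stats::setNames(co$weight, co$cpg),
              transform = match.arg(transform), adult_age = adult_age)
}

#' Write a clock coefficient CSV
#' @param clock a `clock_model`.
#' @param path output path.
#' @export
write_clock <- function(clock, path) {
  df <- data.frame(cpg = c("(Intercept)", names(clock$coefficients)),
                   weight = c(clock$intercept,
                              unname(clock$coefficients)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Global and CpG-density-stratified mean methylation
#'
#' Per sample, the arithmetic mean beta over all probes, and over each of
#' the four CpG-density (HIL) classes; missing values are excluded pairwise.
#'
#' @param beta beta matrix (probes x samples).
#' @param annotation probe annotation covering all matrix probes.
#' @return data.frame with `sample_id`, `global_mean_beta`, and one
#'   `mean_beta_<class>` column per HIL class.
#' @export
global_mean_methylation <- function(beta, annotation) {
  miss <- setdiff(rownames(beta), annotation$probe_id)
  if (length(miss)) {
    stop("annotation missing probe(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  hil <- annotation$hil_category[match(rownames(beta), annotation$probe_id)]
  out <- data.frame(sample_id = colnames(beta),
                    global_mean_beta = colMeans(beta, na.rm = TRUE),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cls in HIL_LEVELS) {
    rows <- hil == cls
    col <- paste0("mean_beta_", cls)
    if (!any(rows)) {
      warning("no probes in HIL class ", cls, call. = FALSE)
      out[[col]] <- NA_real_
    } else {
      out[[col]] <- colMeans(beta[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  out
}

#' DNA methylation age
#'
#' The clock's linear predictor is the intercept plus the weighted sum of
#' clock-CpG betas; the model's output transform maps it to years. Clock
#' CpGs absent from the matrix are imputed with the clock-profile mean when
#' supplied, else with 0.5, and a message is logged.
#'
#' @param beta beta matrix (probes x samples).
#' @param clock a `clock_model`.
#' @param profile optional named per-CpG mean beta used to impute absent
#'   clock CpGs.
#' @return named numeric vector of ages (years) per sample.
#' @export
dnam_age <- function(beta, clock, profile = NULL) {
  cpgs <- names(clock$coefficients)
  present <- intersect(cpgs, rownames(beta))
  if (!length(present)) stop("no clock CpGs present in matrix", call. = FALSE)
  absent <- setdiff(cpgs, present)
  sub <- matrix(NA_real_, length(cpgs), ncol(beta),
                dimnames = list(cpgs, colnames(beta)))
  sub[present, ] <- beta[present, , drop = FALSE]
  if (length(absent)) {
    fill <- if (!is.null(profile)) profile[absent] else rep(0.5,
                                                            length(absent))
    fill[is.na(fill)] <- 0.5
    sub[absent, ] <- fill
    message(length(absent), " clock CpG(s) absent; imputed")
  }
  # per-sample missing clock betas also fall back to the profile/0.5
  if (anyNA(sub)) {
    fill <- if (!is.null(profile)) profile[cpgs] else rep(0.5, length(cpgs))
    fill[is.na(fill)] <- 0.5
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- fill[idx[, 1]]
  }
  x <- clock$intercept + drop(crossprod(sub, clock$coefficients))
  stats::setNames(age_anti_transform(x, clock$transform, clock$adult_age),
                  colnames(beta))
}

#' Read a cell-type reference beta matrix
#'
#' @param path TSV: `id` column of reference probes, one column per cell
#'   type, mean beta in \[0,1\].
#' @return numeric matrix (probes x cell types).
#' @export
read_cell_reference <- function(path) {
  m <- read_matrix(path, kind = "beta")
  if (ncol(m) < 2) stop("cell reference needs at least 2 cell types",
                        call. = FALSE)
  m
}

# Lawson-Hanson nonnegative least squares: minimise ||A x - b|| s.t. x >= 0
nnls_fit <- function(A, b, tol = 1e-10, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 5L * n
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- rep(0, n)
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & (z <= tol)
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate blood cell-type proportions
#'
#' Reference-based deconvolution: each sample's beta profile at the
#' reference probes is projected onto the cell-type reference matrix by
#' least squares under nonnegativity, with either the sum of fractions
#' constrained to at most 1 (default, leaving an unexplained remainder) or
#' exactly 1 (`simplex = TRUE`). Missing betas at reference probes are
#' imputed with the reference row mean.
#'
#' @param beta beta matrix (probes x samples).
#' @param reference cell-type reference matrix (probes x cell types).
#' @param simplex constrain fractions to sum to exactly 1.
#' @return matrix (samples x cell types) of estimated fractions.
#' @export
estimate_cell_proportions <- function(beta, reference, simplex = FALSE) {
  probes <- intersect(rownames(reference), rownames(beta))
  if (length(probes) < ncol(reference)) {
    stop("fewer reference probes present than cell types: underdetermined",
         call. = FALSE)
  }
  R <- reference[probes, , drop = FALSE]
  B <- beta[probes, , drop = FALSE]
  if (anyNA(B)) {
    fill <- rowMeans(R)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- fill[idx[, 1]]
  }
  k <- ncol(R)
  out <- matrix(NA_real_, ncol(B), k,
                dimnames = list(colnames(B), colnames(R)))
  big <- 1e6 * max(abs(R))
  for (s in seq_len(ncol(B))) {
    w <- nnls_fit(R, B[, s])
    if (simplex || sum(w) > 1) {
      # enforce sum(w) (+ slack) = 1 via a heavily weighted augmented row
      A_aug <- rbind(cbind(R, 0), big * rep(1, k + 1))
      b_aug <- c(B[, s], big)
      w <- nnls_fit(A_aug, b_aug)[seq_len(k)]
      if (simplex && sum(w) > 0) w <- w / sum(w)
    }
    out[s, ] <- w
  }
  out
}

#' Assemble the per-sample feature table
#'
#' Combines global/HIL mean methylation, DNA methylation age and cell
#' fractions into one table keyed by sample.
#'
#' @param beta QC'd beta matrix.
#' @param annotation probe annotation.
#' @param clock optional `clock_model`.
#' @param cell_reference optional reference matrix.
#' @param sheet optional sample sheet to merge metadata columns.
#' @return data.frame, one row per sample.
#' @export
feature_table <- function(beta, annotation, clock = NULL,
                          cell_reference = NULL, sheet = NULL) {
  out <- global_mean_methylation(beta, annotation)
  out$global_mean_m <- colMeans(beta_to_m(beta), na.rm = TRUE)
  if (!is.null(clock)) {
    out$dnam_age <- unname(dnam_age(beta, clock)[out$sample_id])
  }
  if (!is.null(cell_reference)) {
    fr <- estimate_cell_proportions(beta, cell_reference)
    colnames(fr) <- paste0("frac_", colnames(fr))
    out <- cbind(out, fr[out$sample_id, , drop = FALSE])
    rownames(out) <- NULL
  }
  if (!is.null(sheet)) {
    out <- merge(out, as.data.frame(sheet), by = "sample_id", sort = FALSE)
  }
  out
}
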