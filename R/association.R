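# Discordance inference on derived features and probes: gaussian linear
# mixed models with twin-set and individual random intercepts, beta-family
# mixed regression for cell-type proportions, likelihood-ratio tests for
# fixed terms, and ordinary per-probe case-control linear models.

# binary disease indicator: affected/carrier vs unaffected/control
disease_indicator <- function(status,
                              affected_levels = c("affected",
                                                  "asymptomatic_carrier")) {
  factor(ifelse(status %in% affected_levels, "affected", "unaffected"),
         levels = c("unaffected", "affected"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the mapping back to
#' input order is preserved.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed, propagated).
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  x <- p[ok]
  if (any(x < 0 | x > 1)) stop("p-values outside [0,1]", call. = FALSE)
  n <- length(x)
  out_ok <- rep(NA_real_, n)
  if (n > 0) {
    o <- order(x, decreasing = TRUE)
    ro <- order(o)
    out_ok <- pmin(1, cummin(n / (n:1) * x[o]))[ro]
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- out_ok
  out
}

fixed_formula <- function(response, covariates, interaction, data) {
  terms <- c("disease", covariates)
  if (interaction) terms <- c(terms, "disease:age_at_collection")
  # drop covariates without variation (e.g. single-sex fixtures)
  if ("sex" %in% terms && length(unique(data$sex)) < 2) {
    terms <- setdiff(terms, "sex")
  }
  terms
}

model_data <- function(data, response) {
  if (!response %in% names(data)) {
    stop("response '", response, "' not found", call. = FALSE)
  }
  d <- data.frame(
    y = data[[response]],
    disease = disease_indicator(data$disease_status),
    age_at_collection = data$age_at_collection,
    sex = factor(data$sex),
    twin_set_id = factor(data$twin_set_id),
    individual_id = factor(data$individual_id),
    collection_index = data$collection_index
  )
  if (!all(is.finite(d$y))) stop("response must be finite", call. = FALSE)
  if (stats::sd(d$y) == 0) {
    stop("response has zero variance", call. = FALSE)
  }
  d
}

#' Gaussian linear mixed model for a derived feature
#'
#' Fits, by maximum likelihood, `response ~ disease + age + sex
#' (+ disease:age) + (1 | twin set) + (1 | individual)` and tests each
#' requested term by a likelihood-ratio test against the model with that
#' term dropped (chi-squared reference, df = parameters removed). The
#' individual random intercept absorbs repeated sampling (longitudinal
#' collections and technical replicates) within a co-twin.
#'
#' @param data data.frame combining the feature column with sheet metadata
#'   (e.g. from [feature_table()] with `sheet=`).
#' @param response name of the feature column to model.
#' @param test_terms terms to test; any of `"disease"`,
#'   `"disease:age_at_collection"`.
#' @param covariates fixed covariates, default age and sex.
#' @param interaction include the disease-by-age interaction.
#' @param random_slope add a per-individual random slope over collections.
#' @return data.frame with one row per tested term: `term`, `estimate`,
#'   `lrt_statistic`, `df`, `p_value`, `converged`.
#' @export
fit_feature_mixed_model <- function(data, response,
                                    test_terms = "disease",
                                    covariates = c("age_at_collection",
                                                   "sex"),
                                    interaction = FALSE,
                                    random_slope = FALSE) {
  d <- model_data(data, response)
  covariates <- intersect(covariates, c("age_at_collection", "sex"))
  if (interaction && !("disease:age_at_collection" %in% test_terms)) {
    test_terms <- unique(c(test_terms, "disease:age_at_collection"))
  }
  fix <- fixed_formula(response, covariates,
                       interaction || "disease:age_at_collection" %in%
                         test_terms, d)
  ran <- if (random_slope) {
    "(1 | twin_set_id) + (1 + collection_index | individual_id)"
  } else {
    "(1 | twin_set_id) + (1 | individual_id)"
  }
  full_f <- stats::as.formula(paste("y ~", paste(c(fix, ran),
                                                 collapse = " + ")))
  fit_one <- function(f) {
    suppressWarnings(suppressMessages(
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore"))))
  }
  res <- lapply(test_terms, function(term) {
    out <- data.frame(term = term, estimate = NA_real_,
                      lrt_statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE)
    tryCatch({
      full <- fit_one(full_f)
      red_fix <- setdiff(fix, term)
      red_f <- stats::as.formula(paste("y ~",
                                       paste(c(red_fix, ran),
                                             collapse = " + ")))
      red <- fit_one(red_f)
      ll_full <- as.numeric(stats::logLik(full))
      ll_red <- as.numeric(stats::logLik(red))
      stat <- max(0, 2 * (ll_full - ll_red))
      df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
      est <- lme4::fixef(full)
      coef_name <- if (term == "disease") "diseaseaffected" else
        grep("disease.*age|age.*disease", names(est), value = TRUE)[1]
      out$estimate <- unname(est[coef_name])
      out$lrt_statistic <- stat
      out$df <- df
      out$p_value <- stats::pchisq(stat, df, lower.tail = FALSE)
      out$converged <- TRUE
      out
    }, error = function(e) out)
  })
  do.call(rbind, res)
}

#' Beta-family mixed regression for cell-type proportions
#'
#' Each cell type's fractions are offset by 0.001 (avoiding a log of zero),
#' rescaled into (0,1) if any offset value reaches 1, and modelled with a
#' logit-link beta regression with random intercepts per individual and per
#' twin set (no random slope). The disease term is tested by LRT. On
#' fitting failure the model falls back to a gaussian mixed model on the
#' logit scale, flagged in the result.
#'
#' @param fractions matrix (samples x cell types) as returned by
#'   [estimate_cell_proportions()].
#' @param sheet sample sheet (rows matched by sample id).
#' @param covariates fixed covariates.
#' @return data.frame: one row per cell type with `cell_type`, `estimate`
#'   (logit-scale disease coefficient), `lrt_statistic`, `p_value`,
#'   `converged`, `fallback_gaussian`.
#' @export
fit_cellprop_beta_regression <- function(fractions, sheet,
                                         covariates = c("age_at_collection",
                                                        "sex")) {
  sheet <- as.data.frame(sheet)
  idx <- match(rownames(fractions), sheet$sample_id)
  if (anyNA(idx)) stop("fraction rows absent from sheet", call. = FALSE)
  meta <- sheet[idx, ]
  res <- lapply(colnames(fractions), function(ct) {
    fr <- fractions[, ct]
    y <- fr + 0.001
    if (any(y >= 1)) y <- y / (max(fr) + 0.002)
    d <- data.frame(
      y = y,
      disease = disease_indicator(meta$disease_status),
      age_at_collection = meta$age_at_collection,
      sex = factor(meta$sex),
      twin_set_id = factor(meta$twin_set_id),
      individual_id = factor(meta$individual_id)
    )
    fix <- fixed_formula(ct, covariates, FALSE, d)
    out <- data.frame(cell_type = ct, estimate = NA_real_,
                      lrt_statistic = NA_real_, p_value = NA_real_,
                      converged = FALSE, fallback_gaussian = FALSE,
                      stringsAsFactors = FALSE)
    beta_fit <- function(terms) {
      f <- stats::as.formula(paste(
        "y ~", paste(c(terms, "s(twin_set_id, bs = 're')",
                       "s(individual_id, bs = 're')"), collapse = " + ")))
      mgcv::gam(f, data = d, family = mgcv::betar(link = "logit"),
                method = "ML")
    }
    fitted <- tryCatch({
      full <- beta_fit(fix)
      red <- beta_fit(setdiff(fix, "disease"))
      # with method = "ML", gcv.ubre is the negative log marginal
      # likelihood, the comparable quantity for nested fixed effects
      # (logLik.gam would return the penalized likelihood, in which the
      # random-intercept smooths can absorb the dropped term)
      stat <- max(0, 2 * (as.numeric(red$gcv.ubre) -
                            as.numeric(full$gcv.ubre)))
      out$estimate <- unname(stats::coef(full)["diseaseaffected"])
      out$lrt_statistic <- stat
      out$p_value <- stats::pchisq(stat, 1, lower.tail = FALSE)
      out$converged <- TRUE
      out
    }, error = function(e) NULL)
    if (is.null(fitted)) {
      # gaussian fallback on the logit scale
      d$y <- stats::qlogis(pmin(pmax(d$y, 1e-6), 1 - 1e-6))
      g <- tryCatch(
        fit_feature_mixed_model(
          data.frame(d, disease_status = as.character(meta$disease_status),
                     sample_id = meta$sample_id,
                     collection_index = meta$collection_index,
                     check.names = FALSE),
          response = "y", covariates = covariates),
        error = function(e) NULL)
      if (!is.null(g)) {
        out$estimate <- g$estimate[1]
        out$lrt_statistic <- g$lrt_statistic[1]
        out$p_value <- g$p_value[1]
        out$converged <- g$converged[1]
      }
      out$fallback_gaussian <- TRUE
      fitted <- out
    }
    fitted
  })
  do.call(rbind, res)
}

#' Per-probe case-control linear models
#'
#' For each selected probe, fits `value ~ disease + age + sex` by ordinary
#' least squares in the case-control cohort and reports the disease
#' coefficient (case minus control), its two-sided p-value, and BH-FDR
#' adjusted p across exactly the selected probe set.
#'
#' @param beta beta matrix rows for the selected probes (probes x samples).
#' @param sheet case-control sample sheet.
#' @param response_scale `"beta"` (default) or `"m"`.
#' @return data.frame per probe: `probe_id`, `estimate`, `se`,
#'   `t_statistic`, `p_value`, `fdr`, `skipped` (constant probes).
#' @export
case_control_probe_models <- function(beta, sheet,
                                      response_scale = c("beta", "m")) {
  response_scale <- match.arg(response_scale)
  sheet <- as.data.frame(sheet)
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) stop("matrix columns absent from sheet", call. = FALSE)
  meta <- sheet[idx, ]
  disease <- disease_indicator(meta$disease_status)
  if (length(unique(disease)) < 2) {
    stop("both disease groups must be present", call. = FALSE)
  }
  X <- stats::model.matrix(~ disease + age + sex,
                           data.frame(disease = disease,
                                      age = meta$age_at_collection,
                                      sex = factor(meta$sex)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient design (collinear covariates)", call. = FALSE)
  }
  Y <- if (response_scale == "m") beta_to_m(beta) else beta
  n <- ncol(Y)
  p <- ncol(X)
  const <- apply(Y, 1, stats::sd) == 0
  coefs <- t(qr.coef(qx, t(Y)))          # probes x p
  fitted <- coefs %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  est <- coefs[, 2]
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  est[const] <- NA; tstat[const] <- NA; pval[const] <- NA
  data.frame(probe_id = rownames(Y), estimate = unname(est),
             se = unname(se), t_statistic = unname(tstat),
             p_value = unname(pval), fdr = bh_fdr(unname(pval)),
             skipped = unname(const), stringsAsFactors = FALSE,
             row.names = NULL)
}
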