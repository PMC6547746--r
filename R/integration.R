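# Cross-platform gene-list integration, Fisher-exact gene-set enrichment
# with fold-enrichment reporting, and the clustering/PCA utilities used for
# disease-signature checks.

#' Overlap gene lists across platforms
#'
#' Each list is first restricted to the other platform's measured universe
#' (a gene absent from, say, the expression data cannot overlap), then the
#' restricted lists are intersected.
#'
#' @param dmp_genes genes annotated to differentially methylated probes.
#' @param deg_genes differentially expressed genes.
#' @param methylation_universe all genes measured on the methylation
#'   platform post-processing.
#' @param expression_universe all genes measured in the expression data
#'   post-processing.
#' @return list: `dmp_in_expression`, `deg_in_methylation`, `intersection`,
#'   plus the input lists/universes.
#' @export
overlap_genes <- function(dmp_genes, deg_genes, methylation_universe,
                          expression_universe) {
  if (!length(methylation_universe) || !length(expression_universe)) {
    stop("universes must be non-empty", call. = FALSE)
  }
  dmp_restricted <- intersect(dmp_genes, expression_universe)
  deg_restricted <- intersect(deg_genes, methylation_universe)
  list(
    dmp_genes = dmp_genes, deg_genes = deg_genes,
    methylation_universe = methylation_universe,
    expression_universe = expression_universe,
    dmp_in_expression = dmp_restricted,
    deg_in_methylation = deg_restricted,
    intersection = intersect(dmp_restricted, deg_restricted)
  )
}

#' Read gene sets from a GMT file
#'
#' @param path tab-separated: term id, description, then member genes.
#' @return named list of character vectors; descriptions kept as the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# two-sided Fisher exact p by hypergeometric summation: sum of the
# probabilities of all tables as or less likely than the observed one
fisher_p_two_sided <- function(k, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher-exact gene-set enrichment
#'
#' For each term, a 2x2 table of list membership by term membership over
#' the background is tested two-sided; fold enrichment is
#' `(k/n) / (K/N)` with a direction label (`over` when > 1), and BH-FDR is
#' applied across the tested terms.
#'
#' @param gene_list genes of interest (must be a subset of `background`).
#' @param gene_sets named list of term gene vectors (e.g. [read_gmt()]).
#' @param background the measured gene universe.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return data.frame per term: `term`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `log2_fold_enrichment`, `p_value`, `fdr`,
#'   `direction`.
#' @export
fisher_enrichment <- function(gene_list, gene_sets, background,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, background)
  if (length(stray)) {
    stop("gene_list not a subset of background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(term) {
    term_genes <- intersect(gene_sets[[term]], background)
    K <- length(term_genes)
    k <- length(intersect(gene_list, term_genes))
    p <- switch(alternative,
      two.sided = fisher_p_two_sided(k, n, K, N),
      greater = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      less = stats::phyper(k, K, N - K, n))
    fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(term = term, k = k, n = n, K = K, N = N,
               fold_enrichment = fold,
               log2_fold_enrichment = log2(fold),
               p_value = min(1, p),
               direction = ifelse(!is.na(fold) & fold > 1, "over", "under"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[, c("term", "k", "n", "K", "N", "fold_enrichment",
          "log2_fold_enrichment", "p_value", "fdr", "direction")]
}

#' Agglomerative clustering of samples
#'
#' Manhattan distance with Ward linkage (Ward.D2 convention) suits
#' methylation matrices; Spearman correlation distance (1 - rank
#' correlation) with average linkage suits log-transformed expression.
#'
#' @param mat features x samples matrix.
#' @param distance `"manhattan"` or `"spearman"`.
#' @param linkage `"ward"` (Ward.D2) or `"average"`.
#' @param k number of clusters to cut.
#' @return list: `labels` (integer per sample, numbered by first
#'   occurrence), `hclust` (the dendrogram object).
#' @export
hierarchical_cluster <- function(mat,
                                 distance = c("manhattan", "spearman"),
                                 linkage = c("ward", "average"), k = 2) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- if (distance == "manhattan") {
    stats::dist(t(mat), method = "manhattan")
  } else {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant sample vector: spearman distance undefined",
           call. = FALSE)
    }
    stats::as.dist(1 - stats::cor(mat, method = "spearman"))
  }
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                  else "average")
  raw <- stats::cutree(hc, k = k)
  # deterministic labels: number clusters by first occurrence in input order
  labels <- match(raw, unique(raw))
  names(labels) <- colnames(mat)
  list(labels = labels, hclust = hc)
}

#' Principal components of samples
#'
#' Features are centred; samples are projected onto the top right-singular
#' directions.
#'
#' @param mat features x samples matrix.
#' @param n_components number of components (<= min dimension).
#' @return list: `coordinates` (samples x components),
#'   `variance_explained` (fractions, non-increasing, summing to <= 1).
#' @export
pca_samples <- function(mat, n_components = 2) {
  n_components <- min(n_components, nrow(mat), ncol(mat))
  x <- t(mat - rowMeans(mat))            # samples x features, centred
  sv <- svd(x, nu = n_components, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(coords) <- list(colnames(mat),
                           paste0("PC", seq_len(n_components)))
  list(coordinates = coords,
       variance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}
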