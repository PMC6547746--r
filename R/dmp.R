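# Cross-set and within-set differentially methylated probe (DMP) calling.
# The cross-set procedure combines two rankings — statistical significance
# of a paired test on M-values across twin sets, and the magnitude of the
# mean beta difference — then restricts to high-CpG-density probes and
# truncates the ranked list immediately before the first probe whose
# per-set direction of change is not consistent.

#' Collapse samples to one value per individual and per twin set
#'
#' Each individual's longitudinal and technical-replicate samples are
#' averaged; each set's unaffected value is the mean over its unaffected
#' individuals (so unaffected triplets are averaged). Emitted on both the
#' beta and M scale (M collapsed from per-sample M-values). Sets with no
#' affected/carrier individual are treated as control sets, using the
#' first-listed individual as the magnitude reference.
#'
#' @param beta beta matrix (probes x samples).
#' @param sheet sample sheet restricted to the twin cohort.
#' @param affected_levels disease statuses counted as affected.
#' @param epsilon clipping bound for the M transform.
#' @return list of class `collapsed_cohort`: matrices `affected_beta`,
#'   `unaffected_beta`, `affected_m`, `unaffected_m`, `delta_beta`,
#'   `delta_m` (probes x sets), `set_ids`, `is_control` per set.
#' @export
collapse_per_individual <- function(beta, sheet,
                                    affected_levels = c(
                                      "affected", "asymptomatic_carrier"),
                                    epsilon = 1e-6) {
  sheet <- as.data.frame(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(beta), ]
  m <- beta_to_m(beta, epsilon)
  sets <- unique(sheet$twin_set_id)

  ind_mean <- function(mat, ids) {
    rowMeans(mat[, ids, drop = FALSE], na.rm = TRUE)
  }
  aff_b <- aff_m <- un_b <- un_m <- matrix(
    NA_real_, nrow(beta), length(sets),
    dimnames = list(rownames(beta), sets))
  is_control <- stats::setNames(logical(length(sets)), sets)
  for (s in sets) {
    rows <- sheet[sheet$twin_set_id == s, ]
    inds <- unique(rows$individual_id)
    status <- vapply(inds, function(i) {
      rows$disease_status[rows$individual_id == i][1]
    }, character(1))
    aff_ids <- inds[status %in% affected_levels]
    un_ids <- inds[!(status %in% affected_levels)]
    if (!length(un_ids)) {
      stop("twin set '", s, "' has no unaffected individual", call. = FALSE)
    }
    if (!length(aff_ids)) {
      # control set: first-listed co-twin is the reference
      is_control[s] <- TRUE
      aff_ids <- un_ids[1]
      un_ids <- un_ids[-1]
    }
    collapse <- function(mat, ids) {
      per_ind <- vapply(ids, function(i) {
        ind_mean(mat, rows$sample_id[rows$individual_id == i])
      }, numeric(nrow(mat)))
      rowMeans(matrix(per_ind, nrow = nrow(mat)))
    }
    aff_b[, s] <- collapse(beta, aff_ids)
    un_b[, s] <- collapse(beta, un_ids)
    aff_m[, s] <- collapse(m, aff_ids)
    un_m[, s] <- collapse(m, un_ids)
  }
  structure(list(
    affected_beta = aff_b, unaffected_beta = un_b,
    affected_m = aff_m, unaffected_m = un_m,
    delta_beta = aff_b - un_b, delta_m = aff_m - un_m,
    set_ids = sets, is_control = is_control
  ), class = "collapsed_cohort")
}

#' Paired t-test across twin sets on the M scale
#'
#' Classic paired t on per-set M-value differences (affected minus
#' unaffected), df = number of sets minus one, two-sided p. Probes whose
#' differences are identical get t = 0 / p = 1 when the common value is
#' zero, and p = 0 with a `zero_variance` flag otherwise.
#'
#' @param collapsed a `collapsed_cohort`; control sets are excluded.
#' @return data.frame per probe: `probe_id`, `t_statistic`, `p_value`,
#'   `mean_delta_m`, `zero_variance`.
#' @export
paired_twin_test <- function(collapsed) {
  keep <- collapsed$set_ids[!collapsed$is_control]
  if (length(keep) < 2) stop("need at least 2 discordant sets", call. = FALSE)
  d <- collapsed$delta_m[, keep, drop = FALSE]
  n <- ncol(d)
  mu <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  t_stat <- mu / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  zero_var <- sd_d == 0
  t_stat[zero_var & mu == 0] <- 0
  p[zero_var & mu == 0] <- 1
  p[zero_var & mu != 0] <- 0
  data.frame(probe_id = rownames(d), t_statistic = unname(t_stat),
             p_value = unname(p), mean_delta_m = unname(mu),
             zero_variance = unname(zero_var), stringsAsFactors = FALSE,
             row.names = NULL)
}

sign_consistent <- function(deltas) {
  apply(deltas, 1, function(x) all(x > 0) || all(x < 0))
}

#' Ranked magnitude-significance DMP procedure
#'
#' Probes are ranked by ascending paired-test p (significance rank, on the
#' M scale) and by descending absolute mean delta-beta (magnitude rank, on
#' the beta scale), ties receiving average ranks over all probes; the final
#' rank is the mean of the two. The list is then restricted to probes in
#' the requested CpG-density class (high-density islands by default),
#' sorted by mean rank (ties broken by probe id), and truncated immediately
#' before the first probe whose per-set delta-beta signs are not all
#' identical across the discordant sets.
#'
#' @param collapsed a `collapsed_cohort` (control sets excluded
#'   automatically).
#' @param annotation probe annotation.
#' @param hil_restrict CpG-density class for the top list, default `"HC"`.
#' @return list of class `ranked_dmp_result`: `table` (per-probe stats with
#'   ranks and direction consistency over all probes) and `top_list`
#'   (ordered probe ids surviving restriction and truncation).
#' @export
rank_combine_and_truncate <- function(collapsed, annotation,
                                      hil_restrict = "HC") {
  test <- paired_twin_test(collapsed)
  keep <- collapsed$set_ids[!collapsed$is_control]
  deltas <- collapsed$delta_beta[test$probe_id, keep, drop = FALSE]
  mean_db <- rowMeans(deltas)
  tab <- data.frame(
    probe_id = test$probe_id,
    t_statistic = test$t_statistic,
    p_value = test$p_value,
    mean_delta_beta = unname(mean_db),
    direction_consistent = unname(sign_consistent(deltas)),
    stringsAsFactors = FALSE
  )
  tab$significance_rank <- rank(tab$p_value, ties.method = "average")
  tab$magnitude_rank <- rank(-abs(tab$mean_delta_beta),
                             ties.method = "average")
  tab$mean_rank <- (tab$significance_rank + tab$magnitude_rank) / 2
  hil <- annotation$hil_category[match(tab$probe_id, annotation$probe_id)]
  tab$hil_category <- hil

  hc <- tab[!is.na(hil) & hil == hil_restrict, , drop = FALSE]
  if (!nrow(hc)) {
    warning("no probes in HIL class ", hil_restrict, call. = FALSE)
    top <- character(0)
  } else {
    hc <- hc[order(hc$mean_rank, hc$probe_id), , drop = FALSE]
    first_bad <- match(FALSE, hc$direction_consistent)
    top <- if (is.na(first_bad)) hc$probe_id else
      hc$probe_id[seq_len(first_bad - 1)]
  }
  structure(list(table = tab, top_list = top,
                 per_set_delta_beta = deltas),
            class = "ranked_dmp_result")
}

#' Within-set DMP calling by absolute delta-beta
#'
#' A probe is differentially methylated within a twin set when the absolute
#' difference in beta between the affected individual and the (mean of the)
#' unaffected co-twin(s) is at least `threshold` (inclusive). Control sets
#' use the first-listed co-twin as reference and carry magnitude only (no
#' direction interpretation).
#'
#' @param collapsed a `collapsed_cohort` on the beta scale.
#' @param threshold default 0.25.
#' @param include_sets optional subset of set ids.
#' @return list of class `within_set_dmp_result`: per set a data.frame
#'   `probe_id`, `delta_beta`, `direction` (`hyper`/`hypo` in the affected,
#'   `NA` for control sets); plus `is_control`.
#' @export
within_set_dmps <- function(collapsed, threshold = 0.25,
                            include_sets = NULL) {
  sets <- if (is.null(include_sets)) collapsed$set_ids else
    intersect(collapsed$set_ids, include_sets)
  per_set <- lapply(sets, function(s) {
    d <- collapsed$delta_beta[, s]
    hit <- !is.na(d) & abs(d) >= threshold
    data.frame(
      probe_id = rownames(collapsed$delta_beta)[hit],
      delta_beta = unname(d[hit]),
      direction = if (collapsed$is_control[s]) NA_character_ else
        ifelse(d[hit] > 0, "hyper", "hypo"),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  names(per_set) <- sets
  structure(list(per_set = per_set, threshold = threshold,
                 is_control = collapsed$is_control[sets]),
            class = "within_set_dmp_result")
}

#' Aggregate per-set DMPs to genes and tally cross-set overlaps
#'
#' Per set, genes with at least `min_probes_per_gene` annotated DMPs
#' (probes annotated to several genes count toward each). Pairwise and
#' multi-set overlap tallies are reported for probes and genes, with
#' control sets kept separate from discordant-set overlap counts.
#'
#' @param dmps a `within_set_dmp_result`, or a named list of probe-id
#'   vectors per set.
#' @param annotation probe annotation covering the listed probes.
#' @param min_probes_per_gene default 2 (genes hit by multiple probes);
#'   set 1 for genes with at least one DMP.
#' @param control_sets set ids to treat as controls (inferred from a
#'   `within_set_dmp_result`).
#' @return list: `genes_per_set`, `probes_per_set`,
#'   `probe_overlap` / `gene_overlap` (items seen in 2+ discordant sets),
#'   `pairwise` data.frame of probe/gene overlap counts for every set pair.
#' @export
aggregate_dmps_to_genes <- function(dmps, annotation,
                                    min_probes_per_gene = 2,
                                    control_sets = NULL) {
  if (inherits(dmps, "within_set_dmp_result")) {
    control_sets <- names(dmps$is_control)[dmps$is_control]
    dmps <- lapply(dmps$per_set, function(d) d$probe_id)
  }
  gene_map <- split_genes(annotation$genes)
  names(gene_map) <- annotation$probe_id
  genes_of <- function(probes) {
    tabulated <- table(unlist(gene_map[probes], use.names = FALSE))
    names(tabulated)[tabulated >= min_probes_per_gene]
  }
  genes_per_set <- lapply(dmps, genes_of)
  disc <- setdiff(names(dmps), control_sets)
  count_multi <- function(lst) {
    tab <- table(unlist(lapply(lst, unique), use.names = FALSE))
    names(tab)[tab >= 2]
  }
  if (length(dmps) >= 2) {
    pairs <- utils::combn(names(dmps), 2)
    pairwise <- data.frame(
      set_a = pairs[1, ], set_b = pairs[2, ],
      probe_overlap = apply(pairs, 2, function(p) {
        length(intersect(dmps[[p[1]]], dmps[[p[2]]]))
      }),
      gene_overlap = apply(pairs, 2, function(p) {
        length(intersect(genes_per_set[[p[1]]], genes_per_set[[p[2]]]))
      }),
      stringsAsFactors = FALSE
    )
  } else {
    pairwise <- data.frame(set_a = character(0), set_b = character(0),
                           probe_overlap = integer(0),
                           gene_overlap = integer(0))
  }
  list(
    probes_per_set = dmps,
    genes_per_set = genes_per_set,
    probe_overlap = count_multi(dmps[disc]),
    gene_overlap = count_multi(genes_per_set[disc]),
    pairwise = pairwise,
    control_sets = control_sets
  )
}
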