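test_that("collapse_per_individual averages longitudinal samples and twins", {
  sheet <- tiny_sheet(n_sets = 1, n_collections = 3, triplet_first = TRUE)
  beta <- matrix(NA_real_, 1, nrow(sheet),
                 dimnames = list("p1", sheet$sample_id))
  # affected longitudinal 0.4/0.5/0.6 -> 0.5 + 0.3 shift => 0.8
  aff <- sheet$sample_id[sheet$disease_status == "affected"]
  beta["p1", aff] <- c(0.7, 0.8, 0.9)
  un <- sheet$sample_id[sheet$disease_status == "unaffected"]
  # two unaffected triplet members collapse to 0.3 and 0.5 -> mean 0.4
  beta["p1", un[1:3]] <- 0.3
  beta["p1", un[4:6]] <- 0.5
  col <- collapse_per_individual(beta, sheet)
  expect_equal(unname(col$affected_beta["p1", "set1"]), 0.8)
  expect_equal(unname(col$unaffected_beta["p1", "set1"]), 0.4)
  expect_equal(unname(col$delta_beta["p1", "set1"]), 0.4)

  # no unaffected individual -> error naming the set
  bad <- as.data.frame(sheet)
  bad$disease_status <- "affected"
  expect_error(collapse_per_individual(beta, sample_sheet(bad)), "set1")

  # all-unaffected set becomes a control set
  ctrl <- as.data.frame(sheet)
  ctrl$disease_status <- "unaffected"
  col_ctrl <- collapse_per_individual(beta, sample_sheet(ctrl))
  expect_true(col_ctrl$is_control[["set1"]])
})

test_that("paired_twin_test matches the hand example and a t.test oracle", {
  d <- matrix(c(0.1, -0.1, 0.1, -0.1,
                0.2, 0.3, 0.25, 0.25), 2, 4, byrow = TRUE,
              dimnames = list(c("sym", "shift"), paste0("set", 1:4)))
  col <- structure(list(delta_m = d, set_ids = colnames(d),
                        is_control = setNames(rep(FALSE, 4), colnames(d))),
                   class = "collapsed_cohort")
  res <- paired_twin_test(col)
  expect_equal(res$t_statistic[res$probe_id == "sym"], 0)
  expect_equal(res$p_value[res$probe_id == "sym"], 1)
  expect_equal(res$t_statistic[res$probe_id == "shift"], 12.24745,
               tolerance = 1e-5)

  # brute-force oracle: stats::t.test on 300 random probes
  set.seed(20)
  dm <- matrix(rnorm(300 * 5, 0, 0.5), 300, 5,
               dimnames = list(paste0("p", 1:300), paste0("set", 1:5)))
  col2 <- structure(list(delta_m = dm, set_ids = colnames(dm),
                         is_control = setNames(rep(FALSE, 5),
                                               colnames(dm))),
                    class = "collapsed_cohort")
  mine <- paired_twin_test(col2)
  for (i in seq(1, 300, by = 7)) {
    tt <- t.test(dm[i, ])
    expect_equal(mine$t_statistic[i], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p_value[i], tt$p.value, tolerance = 1e-10)
  }

  # zero-variance nonzero-mean differences flagged with p = 0
  dz <- matrix(0.2, 1, 4, dimnames = list("z", paste0("set", 1:4)))
  colz <- structure(list(delta_m = dz, set_ids = colnames(dz),
                         is_control = setNames(rep(FALSE, 4),
                                               colnames(dz))),
                    class = "collapsed_cohort")
  rz <- paired_twin_test(colz)
  expect_true(rz$zero_variance)
  expect_equal(rz$p_value, 0)
})

test_that("rank_combine_and_truncate ranks, restricts and truncates", {
  # 6 HC probes engineered so mean-rank order is h1..h6 and h5 is the
  # first direction-inconsistent probe -> top list = h1..h4
  deltas <- rbind(
    h1 = c(0.40, 0.41, 0.39, 0.40),
    h2 = c(0.35, 0.36, 0.34, 0.35),
    h3 = c(0.30, 0.31, 0.29, 0.30),
    h4 = c(0.25, 0.26, 0.24, 0.25),
    h5 = c(0.22, 0.21, -0.20, 0.20),
    h6 = c(0.02, -0.01, 0.01, -0.02))
  colnames(deltas) <- paste0("set", 1:4)
  col <- fake_collapsed(deltas, baseline = 0.3)
  ann <- flat_annotation(rownames(deltas), hil = "HC")
  res <- rank_combine_and_truncate(col, ann)
  expect_equal(res$top_list, c("h1", "h2", "h3", "h4"))
  expect_true(all(res$table$direction_consistent[
    match(res$top_list, res$table$probe_id)]))
  # mean rank is the average of the two rankings
  expect_equal(res$table$mean_rank,
               (res$table$significance_rank + res$table$magnitude_rank) / 2)

  # input probe order does not change the outcome
  perm <- c(4, 2, 6, 1, 3, 5)
  col_p <- fake_collapsed(deltas[perm, ], baseline = 0.3)
  res_p <- rank_combine_and_truncate(col_p, ann)
  expect_equal(res_p$top_list, res$top_list)

  # no probes in the restricted class -> empty list with warning
  ann_lc <- flat_annotation(rownames(deltas), hil = "LC")
  expect_warning(res_lc <- rank_combine_and_truncate(col, ann_lc),
                 "no probes")
  expect_length(res_lc$top_list, 0)
})

test_that("planted shared DMPs are recovered from a simulated cohort", {
  cfg <- twin_sim_config(n_probes = 2000, n_planted_dmps_shared = 10,
                         n_planted_dmps_private = 0, seed = 17)
  sim <- simulate_twin_methylomes(cfg)
  col <- collapse_per_individual(sim$beta, sim$sheet)
  res <- rank_combine_and_truncate(col, sim$annotation)
  planted <- sim$truth$planted_shared_dmps$probe_id
  expect_gte(mean(planted %in% res$top_list), 0.9)
})

test_that("within_set_dmps thresholds inclusively with sign labels", {
  deltas <- cbind(set1 = c(0.30, 0.20, -0.25, 0.10, -0.40, 0))
  rownames(deltas) <- paste0("p", 1:6)
  col <- fake_collapsed(deltas, baseline = 0.45)
  res <- within_set_dmps(col)
  hits <- res$per_set$set1
  expect_setequal(hits$probe_id, c("p1", "p3", "p5"))
  expect_equal(hits$direction[hits$probe_id == "p1"], "hyper")
  expect_equal(hits$direction[hits$probe_id == "p3"], "hypo")

  # threshold 0 returns everything; counts monotone in threshold
  expect_equal(nrow(within_set_dmps(col, 0)$per_set$set1), 6)
  n_at <- vapply(c(0, 0.1, 0.25, 0.3, 0.5),
                 function(th) nrow(within_set_dmps(col, th)$per_set$set1),
                 numeric(1))
  expect_true(all(diff(n_at) <= 0))

  # control sets carry magnitude only
  colc <- fake_collapsed(deltas, baseline = 0.45,
                         is_control = c(set1 = TRUE))
  expect_true(all(is.na(within_set_dmps(colc)$per_set$set1$direction)))
})

test_that("pure-noise simulation yields no within-set DMPs at 0.25", {
  hits <- vapply(1:10, function(s) {
    cfg <- twin_sim_config(n_twin_sets = 2, triplet_sets = integer(0),
                           n_probes = 500, n_planted_dmps_shared = 0,
                           n_planted_dmps_private = 0, seed = 100 + s)
    sim <- simulate_twin_methylomes(cfg)
    col <- collapse_per_individual(sim$beta, sim$sheet)
    sum(vapply(within_set_dmps(col)$per_set, nrow, numeric(1)))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("aggregate_dmps_to_genes counts multi-probe genes and overlaps", {
  ann <- flat_annotation(paste0("p", 1:5),
                         genes = c("A", "A", "B", "B;C", "C"))
  dmps <- list(set1 = c("p1", "p2", "p3"),
               set2 = c("p1", "p4", "p5"),
               ctrl = c("p3"))
  agg <- aggregate_dmps_to_genes(dmps, ann, control_sets = "ctrl")
  expect_equal(agg$genes_per_set$set1, "A")          # A has p1+p2
  expect_setequal(agg$genes_per_set$set2, "C")       # C has p4+p5
  expect_equal(agg$probe_overlap, "p1")              # shared by set1/set2
  agg1 <- aggregate_dmps_to_genes(dmps, ann, min_probes_per_gene = 1,
                                  control_sets = "ctrl")
  expect_setequal(agg1$genes_per_set$set1, c("A", "B"))
  expect_setequal(agg1$gene_overlap, c("A", "B"))
  # hand-tallied pairwise table
  pw <- agg$pairwise
  expect_equal(pw$probe_overlap[pw$set_a == "set1" & pw$set_b == "set2"], 1)
  expect_equal(pw$probe_overlap[pw$set_a == "set1" & pw$set_b == "ctrl"], 1)
  expect_equal(pw$probe_overlap[pw$set_a == "set2" & pw$set_b == "ctrl"], 0)
})
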