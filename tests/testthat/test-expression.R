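test_that("cpm and cpm_filter follow their definitions and boundaries", {
  counts <- matrix(c(500L, 0L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  counts[2, 1] <- 999500L
  expect_equal(cpm(counts)["g1", "s1"], 500)

  # counts giving CPM (0.4, 0.4, 0.4, 0.1) in libraries of 1e7
  m <- rbind(g = as.integer(c(4, 4, 4, 1)),
             f = as.integer(c(1e7 - 4, 1e7 - 4, 1e7 - 4, 1e7 - 1)))
  colnames(m) <- paste0("s", 1:4)
  expect_true("g" %in% cpm_filter(m, 0.3, 3))
  # CPM exactly at the threshold everywhere is excluded (strictly greater)
  m2 <- rbind(g = as.integer(c(3, 3, 3, 3)),
              f = as.integer(rep(1e7 - 3, 4)))
  colnames(m2) <- paste0("s", 1:4)
  expect_false("g" %in% cpm_filter(m2, 0.3, 3))

  # retained set monotone in both parameters
  set.seed(30)
  counts3 <- matrix(rnbinom(500 * 6, mu = 20, size = 5), 500, 6,
                    dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  k1 <- cpm_filter(counts3, 100, 3)
  k2 <- cpm_filter(counts3, 500, 3)
  k3 <- cpm_filter(counts3, 100, 5)
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k1))
})

test_that("tmm_factors has the symmetry and invariance properties", {
  set.seed(31)
  counts <- matrix(rnbinom(300 * 4, mu = 50, size = 5), 300, 4,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(same)), rep(1, 3))

  # pure depth change between two libraries: factors exactly 1
  two <- cbind(s1 = counts[, 1], s2 = counts[, 1] * 2L)
  expect_equal(unname(tmm_factors(two)), c(1, 1))
  # depth rescaling of one of several libraries: near-invariant (the
  # binomial precision weights retain a weak library-size dependence)
  f0 <- tmm_factors(counts)
  doubled <- counts
  doubled[, 2] <- doubled[, 2] * 2L
  expect_equal(tmm_factors(doubled), f0, tolerance = 0.02)

  # gene order invariance
  perm <- sample(nrow(counts))
  expect_equal(tmm_factors(counts[perm, ]), f0, tolerance = 1e-12)

  # geometric mean of factors is 1
  expect_equal(exp(mean(log(f0))), 1, tolerance = 1e-12)

  zero <- counts
  zero[, 1] <- 0L
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("tmm_factors matches the independent edgeR oracle", {
  set.seed(32)
  for (i in 1:5) {
    counts <- matrix(rnbinom(200 * 6, mu = 2^runif(200, 2, 9), size = 10),
                     200, 6,
                     dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
    mine <- tmm_factors(counts)
    oracle <- edgeR::calcNormFactors(edgeR::DGEList(counts))
    expect_equal(unname(mine),
                 oracle$samples$norm.factors, tolerance = 1e-8)
  }
})

test_that("paired_de_test recovers planted effects with the sign convention", {
  sheet <- tiny_sheet(n_sets = 1, n_collections = 3, n_replicates = 2)
  sim <- simulate_counts(300, sheet, n_planted_degs = 15, log2fc = 1,
                         seed = 33)
  keep <- cpm_filter(sim$counts, 0.3, 3)
  norm <- normalise_expression(sim$counts[keep, , drop = FALSE])
  res <- paired_de_test(norm, sheet)
  planted <- intersect(sim$truth$planted_degs, res$gene_id)
  est <- res$log2_fold_change[match(planted, res$gene_id)]
  # positive log2FC = higher in affected, matching the planted direction
  expect_true(all(est > 0))
  expect_lt(abs(mean(est) - 1), 0.3)
  # single-replicate detection rate; the 80% criterion is averaged over
  # 200 replicates in the acceptance suite
  expect_gte(mean(res$fdr[match(planted, res$gene_id)] < 0.05), 0.6)

  # unbalanced collection dropped with a warning
  drop_ids <- sheet$sample_id[sheet$disease_status == "affected" &
                                sheet$collection_index == 3]
  norm_ub <- normalise_expression(
    sim$counts[keep, setdiff(colnames(sim$counts), drop_ids)])
  expect_warning(paired_de_test(norm_ub, sheet), "unbalanced")
})

test_that("threshold_degs applies both gates", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2_fold_change = c(0.8, 0.4, 2),
                    t_statistic = 1, p_value = 0.01,
                    fdr = c(0.03, 0.03, 0.06))
  out <- threshold_degs(res)
  expect_equal(out$gene_id, "a")
  expect_equal(nrow(threshold_degs(res[0, ])), 0)
})

test_that("case-control validation restricts FDR to the present subset", {
  sheet_df <- do.call(rbind, lapply(1:160, function(i) {
    data.frame(sample_id = paste0("v", i), individual_id = paste0("v", i),
               twin_set_id = "none",
               disease_status = if (i <= 90) "affected" else "control",
               sex = sample(c("F", "M"), 1),
               age_at_collection = 60, collection_index = 1L,
               replicate_group = paste0("v", i), cohort = "case_control",
               stringsAsFactors = FALSE)
  }))
  set.seed(34)
  sheet <- sample_sheet(sheet_df)
  sim <- simulate_counts(200, sheet, n_planted_degs = 5, log2fc = 0.6,
                         seed = 35)
  subset_genes <- c(sim$truth$planted_degs, "not_measured",
                    sample(setdiff(rownames(sim$counts),
                                   sim$truth$planted_degs), 10))
  out <- validate_degs_case_control(sim$counts, sheet, subset_genes)
  expect_equal(out$absent, "not_measured")
  expect_equal(sort(out$present), sort(setdiff(subset_genes,
                                               "not_measured")))
  # BH divisor is the subset size, not the genome
  expect_equal(out$results$fdr, p.adjust(out$results$p_value, "BH"))
  planted_fdr <- out$results$fdr[out$results$gene_id %in%
                                   sim$truth$planted_degs]
  expect_gte(mean(planted_fdr < 0.05), 0.8)
  expect_error(validate_degs_case_control(sim$counts, sheet, character(0)),
               "empty")
})
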