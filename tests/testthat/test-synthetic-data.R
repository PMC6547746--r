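test_that("twin simulator is deterministic and counts samples correctly", {
  cfg <- twin_sim_config(n_twin_sets = 4, triplet_sets = 1L, n_probes = 200,
                         n_planted_dmps_shared = 5,
                         n_planted_dmps_private = 2,
                         n_collections = 1, n_replicates = 1, seed = 3)
  a <- simulate_twin_methylomes(cfg)
  b <- simulate_twin_methylomes(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$detp, b$detp)
  expect_identical(as.data.frame(a$sheet), as.data.frame(b$sheet))
  # 3 pairs + 1 triplet, one sample each
  expect_equal(ncol(a$beta), 3 * 2 + 3)
  expect_true(all(a$beta >= 0 & a$beta <= 1))
  expect_true(all(a$detp >= 0 & a$detp <= 1))
  # truth references existing probes only
  expect_true(all(a$truth$planted_shared_dmps$probe_id %in%
                    rownames(a$beta)))
  expect_true(all(unlist(a$truth$planted_private_dmps) %in%
                    rownames(a$beta)))
  expect_error(simulate_twin_methylomes(
    twin_sim_config(n_probes = 10, n_planted_dmps_shared = 8,
                    n_planted_dmps_private = 5)), "exceed")
})

test_that("planted shared effect magnitude is recovered over many sets", {
  # Monte-Carlo: collapse affected-vs-unaffected over 200 sets at the
  # planted probes; the configured delta of 0.3 must be realised
  cfg <- twin_sim_config(n_twin_sets = 200, triplet_sets = integer(0),
                         n_probes = 60, n_planted_dmps_shared = 5,
                         n_planted_dmps_private = 0,
                         n_collections = 1, n_replicates = 1, seed = 11)
  sim <- simulate_twin_methylomes(cfg)
  col <- collapse_per_individual(sim$beta, sim$sheet)
  tr <- sim$truth$planted_shared_dmps
  realised <- rowMeans(col$delta_beta[tr$probe_id, , drop = FALSE])
  expect_true(all(abs(realised - tr$sign * 0.3) < 0.02))
})

test_that("case-control simulator plants group-mean differences", {
  sim <- simulate_case_control(600, 500, probe_effects = c(p1 = -0.07),
                               n_probes = 30, seed = 5)
  expect_identical(
    sim$beta,
    simulate_case_control(600, 500, probe_effects = c(p1 = -0.07),
                          n_probes = 30, seed = 5)$beta)
  case <- sim$sheet$disease_status == "affected"
  d <- mean(sim$beta["p1", case]) - mean(sim$beta["p1", !case])
  expect_lt(abs(d - (-0.07)), 0.01)
  # null probes: no systematic difference at this n
  null_d <- rowMeans(sim$beta[-1, case]) - rowMeans(sim$beta[-1, !case])
  expect_lt(max(abs(null_d)), 0.02)
  expect_warning(
    simulate_case_control(5, 5, probe_effects = c(p1 = 0.9), n_probes = 2,
                          seed = 1),
    "clipped")
})

test_that("epityper simulator plants failures and respects missing_rate", {
  sim <- simulate_epityper(20, 10, missing_rate = 0.05, failed_samples = 1,
                           failed_units = 1, seed = 9)
  v <- sim$plate$values
  fs <- sim$truth$failed_samples
  expect_gte(mean(is.na(v[, fs])), 0.9)
  expect_gte(mean(is.na(v[sim$truth$failed_units, ])), 0.9)
  full <- simulate_epityper(20, 10, missing_rate = 0, seed = 9)
  expect_false(anyNA(full$plate$values))
  expect_true(all(full$plate$values >= 0 & full$plate$values <= 100))
})

test_that("synthetic clock embedding inverts exactly through dnam_age", {
  for (tr in c("identity", "horvath")) {
    clk <- make_synthetic_clock(15, tr, adult_age = 20, seed = 4)
    ages <- c(a = 5, b = 20, c = 50, d = 85)
    emb <- clock_embedding_betas(clk, ages)
    expect_true(all(emb >= 0 & emb <= 1))
    expect_equal(unname(dnam_age(emb, clk)), unname(ages), tolerance = 1e-8)
  }
  expect_identical(make_synthetic_clock(5, seed = 2)$coefficients,
                   make_synthetic_clock(5, seed = 2)$coefficients)
})

test_that("count simulator plants fold changes and is internally consistent", {
  sheet <- tiny_sheet(n_sets = 1, n_collections = 3, n_replicates = 2)
  sim <- simulate_counts(400, sheet, n_planted_degs = 100, log2fc = 1,
                         seed = 6)
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts))
  aff <- sheet$disease_status == "affected"
  # Monte-Carlo over 100 planted genes: mean empirical log2 ratio near 1
  ratio <- log2(rowMeans(sim$counts[sim$truth$planted_degs, aff]) /
                  rowMeans(sim$counts[sim$truth$planted_degs, !aff]))
  expect_lt(abs(mean(ratio) - 1), 0.1)
  null_genes <- setdiff(rownames(sim$counts), sim$truth$planted_degs)
  nr <- log2(rowMeans(sim$counts[null_genes, aff]) /
               rowMeans(sim$counts[null_genes, !aff]))
  expect_lt(abs(mean(nr)), 0.05)
})

test_that("replicate discordance injection corrupts only chosen probes", {
  sheet <- tiny_sheet(n_sets = 2, n_collections = 2, n_replicates = 2)
  set.seed(1)
  beta <- matrix(runif(50 * nrow(sheet), 0.2, 0.8), 50, nrow(sheet),
                 dimnames = list(paste0("p", 1:50), sheet$sample_id))
  out <- inject_replicate_discordance(beta, sheet, c("p1", "p2"), seed = 2)
  changed <- rownames(beta)[rowSums(out != beta) > 0]
  expect_setequal(changed, c("p1", "p2"))
  expect_true(all(out >= 0 & out <= 1))
})
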