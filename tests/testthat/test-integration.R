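test_that("overlap_genes restricts to universes before intersecting", {
  out <- overlap_genes(c("A", "B", "C"), c("B", "C", "D"),
                       methylation_universe = LETTERS[1:10],
                       expression_universe = LETTERS[1:10])
  expect_setequal(out$intersection, c("B", "C"))

  # a DMP gene absent from the expression universe cannot overlap
  out2 <- overlap_genes(c("A", "E"), c("E"),
                        methylation_universe = c("A", "E"),
                        expression_universe = c("A"))
  expect_equal(out2$dmp_in_expression, "A")
  expect_length(out2$intersection, 0)

  # symmetry: swapping lists and universes transposes the result
  out3 <- overlap_genes(c("B", "C", "D"), c("A", "B", "C"),
                        methylation_universe = LETTERS[1:10],
                        expression_universe = LETTERS[1:10])
  expect_setequal(out3$intersection, out$intersection)
  expect_error(overlap_genes("A", "B", character(0), "B"), "non-empty")
})

test_that("fisher_enrichment matches the worked example and fisher.test", {
  bg <- paste0("G", 1:1000)
  lst <- paste0("G", 1:50)
  term <- paste0("G", c(1:10, 101:130))  # 10 in list, 40 in background
  res <- fisher_enrichment(lst, list(T1 = term), bg)
  expect_equal(res$k, 10)
  expect_equal(res$fold_enrichment, 5.0)
  expect_equal(res$log2_fold_enrichment, log2(5), tolerance = 1e-12)
  expect_equal(res$direction, "over")
  expect_equal(res$p_value,
               fisher.test(matrix(c(10, 40, 30, 920), 2))$p.value,
               tolerance = 1e-10)

  # disjoint term: fold 0, under
  res0 <- fisher_enrichment(lst, list(T0 = paste0("G", 900:999)), bg)
  expect_equal(res0$fold_enrichment, 0)
  expect_equal(res0$direction, "under")

  # degenerate: list equals background
  resd <- fisher_enrichment(bg, list(T1 = term), bg)
  expect_equal(resd$fold_enrichment, 1)
  expect_equal(resd$p_value, 1)

  expect_error(fisher_enrichment(c("X1"), list(T1 = term), bg),
               "not a subset")
})

test_that("fisher p equals the hypergeometric-summation oracle broadly", {
  set.seed(40)
  for (i in 1:100) {
    N <- sample(50:2000, 1)
    K <- sample(2:min(100, N - 1), 1)
    n <- sample(2:min(100, N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    mine <- twindiscord:::fisher_p_two_sided(k, n, K, N)
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
    expect_equal(mine, fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("GMT files round-trip", {
  sets <- list(T1 = c("A", "B"), T2 = c("C"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("one", "two"))
  back <- read_gmt(path)
  expect_equal(back, sets, ignore_attr = TRUE)
  expect_equal(attr(back, "description"), c("one", "two"))
})

test_that("hierarchical clustering recovers planted groups deterministically", {
  set.seed(41)
  g1 <- matrix(rnorm(50 * 5, 0), 50, 5)
  g2 <- matrix(rnorm(50 * 5, 5), 50, 5)
  mat <- cbind(g1, g2)
  colnames(mat) <- paste0("s", 1:10)
  res <- hierarchical_cluster(mat, "manhattan", "ward", k = 2)
  expect_equal(unname(res$labels), rep(c(1L, 2L), each = 5))
  # invariant to sample order up to label permutation
  perm <- sample(10)
  res_p <- hierarchical_cluster(mat[, perm], "manhattan", "ward", k = 2)
  tab <- table(res$labels[perm], res_p$labels)
  expect_equal(sum(tab > 0), 2)

  # duplicated samples merge first (distance zero)
  dup <- cbind(mat, s11 = mat[, 1])
  resd <- hierarchical_cluster(dup, "manhattan", "average", k = 3)
  expect_equal(resd$labels[["s11"]], resd$labels[["s1"]])

  flat <- mat
  flat[, 1] <- 3
  expect_error(hierarchical_cluster(flat, "spearman", "average"),
               "constant sample")
})

test_that("pca_samples centres, projects and orders variance", {
  set.seed(42)
  mat <- cbind(matrix(rnorm(40 * 4, 0), 40, 4),
               matrix(rnorm(40 * 4, 4), 40, 4))
  colnames(mat) <- paste0("s", 1:8)
  res <- pca_samples(mat, 3)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  expect_lte(sum(res$variance_explained), 1 + 1e-12)

  dup <- cbind(mat, s9 = mat[, 1])
  resd <- pca_samples(dup, 2)
  expect_equal(resd$coordinates["s9", ], resd$coordinates["s1", ],
               tolerance = 1e-8)

  # planted two-group shift separates on PC1 (simple silhouette check)
  pc1 <- res$coordinates[, 1]
  grp <- rep(1:2, each = 4)
  between <- abs(mean(pc1[grp == 1]) - mean(pc1[grp == 2]))
  within <- max(tapply(pc1, grp, sd))
  expect_gt(between / within, 2)
})

test_that("the CLI writes simulation, DMP and DEG outputs", {
  out <- withr::local_tempdir()
  twindiscord_cli(c("simulate", "--sets", "3", "--probes", "300",
                    "--seed", "2", "--out", out))
  expect_true(file.exists(file.path(out, "beta.tsv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  out2 <- withr::local_tempdir()
  twindiscord_cli(c("dmp", "--beta", file.path(out, "beta.tsv"),
                    "--sheet", file.path(out, "sheet.csv"),
                    "--annot", file.path(out, "annotation.tsv"),
                    "--out", out2))
  expect_true(file.exists(file.path(out2, "dmp_stats.tsv")))
  expect_true(file.exists(file.path(out2, "top_dmps.txt")))
  expect_error(twindiscord_cli(c("bogus")), "unknown subcommand")
})
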