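sim_geno <- function(n_per_class = 50L, p = 100L, n_signal = 0L,
                     delta = 0.4, seed = 1L) {
  cfg <- sim_config(seed = seed,
                    n_samples = c(a = n_per_class, b = n_per_class),
                    delta = delta)
  ids <- sprintf("f%03d", seq_len(p))
  simulate_genotypes(cfg, ids, important_ids = ids[seq_len(n_signal)])
}

test_that("shadow columns are per-feature permutations, seeded", {
  gt <- sim_geno(30L, 20L, seed = 3L)
  set.seed(1)
  ext <- shadow_augment(gt$genotypes)
  expect_equal(ncol(ext), 40L)
  for (j in 1:20)
    expect_equal(sort(ext[, 20 + j]), sort(gt$genotypes[, j]),
                 ignore_attr = TRUE)
  set.seed(1)
  expect_identical(ext, shadow_augment(gt$genotypes))
  # shuffling destroys label association on average
  labs <- as.integer(gt$labels) - 1
  cors <- replicate(50, {
    sh <- shadow_augment(gt$genotypes)[, 21:40]
    mean(abs(suppressWarnings(cor(sh, labs))), na.rm = TRUE)
  })
  raw_cor <- mean(abs(suppressWarnings(cor(gt$genotypes, labs))),
                  na.rm = TRUE)
  expect_lt(abs(mean(cors) - raw_cor), 0.1)
})

test_that("genotype imputation fills NAs with the feature mode", {
  M <- matrix(c(0, 0, 0, 2, NA, 1, 1, NA), ncol = 2)
  colnames(M) <- c("a", "b")
  Mi <- impute_genotypes(M)
  expect_equal(Mi[, "a"], c(0, 0, 0, 2))
  expect_equal(Mi[, "b"], c(1, 1, 1, 1))
  expect_error(impute_genotypes(matrix(NA_real_, 2, 1,
                                       dimnames = list(NULL, "x"))),
               "entirely missing")
})

test_that("a perfect separator outranks every shadow feature", {
  gt <- sim_geno(40L, 30L, seed = 5L)
  M <- gt$genotypes
  M[, 1] <- (as.integer(gt$labels) - 1) * 2  # identical to the label
  set.seed(2)
  ext <- shadow_augment(M)
  z <- rf_importance(ext, gt$labels, n_trees = 100L, seed = 9L)
  expect_gt(z[1], max(z[31:60]))
  # deterministic given the seed
  z2 <- rf_importance(ext, gt$labels, n_trees = 100L, seed = 9L)
  expect_identical(z, z2)
  expect_error(rf_importance(M, rep("a", nrow(M)), n_trees = 10L),
               "single-class")
})

test_that("pure-noise features are exchangeable with their shadows", {
  gt <- sim_geno(40L, 20L, n_signal = 0L, seed = 6L)
  set.seed(3)
  ranks <- replicate(10, {
    ext <- shadow_augment(gt$genotypes)
    z <- rf_importance(ext, gt$labels, n_trees = 50L,
                       seed = sample.int(1e6, 1))
    mean(rank(z)[1:20])  # mean rank of the real features
  })
  # under exchangeability the mean rank of 20 of 40 columns is 20.5
  expect_lt(abs(mean(ranks) - 20.5), 4)
})

test_that("Boruta confirms planted signal and rejects constants", {
  gt <- sim_geno(60L, 40L, n_signal = 3L, delta = 0.5, seed = 8L)
  M <- gt$genotypes
  M[, "f040"] <- 1  # constant feature
  # a constant column is never split on: zero importance variance warning
  expect_warning(rf_importance(M, gt$labels, n_trees = 20L, seed = 1L),
                 "zero importance")
  br <- boruta_run(M, gt$labels, n_trees = 100L, seed = 4L)
  conf <- names(br$decision)[br$decision == "Confirmed"]
  expect_true(all(c("f001", "f002", "f003") %in% conf))
  expect_equal(as.character(br$decision[["f040"]]), "Rejected")
  expect_error(boruta_run(M, gt$labels, max_iter = 0L), "max_iter")
  # decisions partition the features
  expect_equal(sum(table(br$decision)), ncol(M))
})

test_that("consensus is the intersection of confirmed sets and shrinks", {
  gt <- sim_geno(50L, 30L, n_signal = 2L, seed = 9L)
  c1 <- consensus_important(gt$genotypes, gt$labels, n_runs = 1L,
                            base_seed = 2L, n_trees = 60L)
  expect_equal(c1$important, sort(c1$confirmed_per_run[[1]]))
  c3 <- consensus_important(gt$genotypes, gt$labels, n_runs = 3L,
                            base_seed = 2L, n_trees = 60L)
  # shared seed prefix: more runs can only shrink the set
  expect_true(all(c3$important %in% c1$important))
  expect_identical(c3$confirmed_per_run[[1]], c1$confirmed_per_run[[1]])
  expect_true(all(c("f001", "f002") %in% c3$important))
})

test_that("genotype and label TSVs round-trip", {
  gt <- sim_geno(10L, 5L, seed = 11L)
  gfile <- tempfile(fileext = ".tsv")
  lfile <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(sample = rownames(gt$genotypes), gt$genotypes,
                       check.names = FALSE), gfile)
  write_tsv(data.frame(sample = names(gt$labels),
                       label = as.character(gt$labels)), lfile)
  M <- read_genotype_tsv(gfile)
  L <- read_labels_tsv(lfile)
  expect_equal(M, gt$genotypes)
  expect_equal(unname(L[names(gt$labels)]), unname(gt$labels))
})
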