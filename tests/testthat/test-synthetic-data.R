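test_that("simulated genome matches the configured GC and placement rules", {
  cfg <- sim_config(seed = 31L, n_genes = 20L)
  gg <- simulate_genome_and_genes(cfg)
  for (chr in gg$genome) {
    n <- nchar(chr)
    gcn <- gc_content(chr)
    sd3 <- 3 * sqrt(cfg$gc * (1 - cfg$gc) / n)
    expect_lt(abs(gcn - cfg$gc), sd3)
  }
  # genes do not overlap within a chromosome
  by_chr <- split(gg$genes, gg$genes$chrom)
  for (g in by_chr) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # promoters fully inside chromosomes
  pw <- promoter_windows(gg$genes, chrom_lengths =
                           vapply(gg$genome, nchar, integer(1)))
  expect_false(any(pw$clipped))
})

test_that("one seed reproduces every fixture file byte-identically", {
  cfg <- sim_config(seed = 32L, n_gain = 3L, n_loss = 3L, n_neutral = 4L,
                    n_genes = 20L, n_samples = c(a = 10L, b = 10L),
                    n_up = 3L, n_down = 3L)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 8L)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("planted consequences are verified against the package scanner", {
  ds <- small_fixture()
  expect_equal(nrow(ds$truth), nrow(ds$snps))
  cons <- classify_snp_consequences(ds$genome, ds$snps, ds$pwms)
  gains <- unique(cons$snp_id[cons$consequence == "GainOfTFBS"])
  losses <- unique(cons$snp_id[cons$consequence == "LossOfTFBS"])
  for (i in seq_len(nrow(ds$truth))) {
    id <- ds$truth$snp_id[i]
    switch(ds$truth$class[i],
      gain = expect_true(id %in% gains, label = paste(id, "gain")),
      loss = expect_true(id %in% losses, label = paste(id, "loss")),
      neutral = expect_false(id %in% c(gains, losses),
                             label = paste(id, "neutral")))
  }
})

test_that("genotypes carry the planted class differentiation", {
  cfg <- sim_config(seed = 33L, n_samples = c(a = 100L, b = 100L),
                    delta = 0.4)
  ids <- sprintf("f%03d", 1:60)
  gt <- simulate_genotypes(cfg, ids, important_ids = ids[1:5])
  ca <- gt$labels == "a"
  fdiff <- vapply(ids, function(j)
    mean(gt$genotypes[ca, j]) / 2 - mean(gt$genotypes[!ca, j]) / 2,
    numeric(1))
  # planted SNPs: |difference - 0.4| within 3 binomial sd
  sd3 <- 3 * sqrt(2 * 0.35 * 0.65 / (2 * 100))
  expect_true(all(abs(abs(fdiff[1:5]) - 0.4) < sd3))
  # null SNPs: difference near zero
  expect_true(all(abs(fdiff[6:60]) < 5 * sd3))
  # overall MAF above the quality threshold
  maf <- apply(gt$genotypes, 2, function(g) {
    f <- mean(g) / 2
    min(f, 1 - f)
  })
  expect_true(all(maf > 0.05))
  # delta = 0: empirical differences are pure noise
  gt0 <- simulate_genotypes(sim_config(seed = 33L,
                                       n_samples = c(a = 100L, b = 100L),
                                       delta = 0), ids, ids[1:5])
  fdiff0 <- vapply(ids[1:5], function(j)
    mean(gt0$genotypes[ca, j]) / 2 - mean(gt0$genotypes[!ca, j]) / 2,
    numeric(1))
  expect_true(all(abs(fdiff0) < sd3))
})

test_that("DEG tables honor the overlap parameter", {
  cfg1 <- sim_config(seed = 34L, deg_overlap = 1)
  ids <- sprintf("gene%03d", 1:60)
  d1 <- simulate_deg_tables(cfg1, ids)
  ups <- lapply(d1$truth, `[[`, "up")
  expect_true(all(vapply(ups, identical, logical(1), ups[[1]])))
  d0 <- simulate_deg_tables(sim_config(seed = 34L, n_up = 0L,
                                       n_down = 0L), ids)
  sets <- filter_degs(d0$tables$flower)
  expect_length(sets$up, 0L)
  expect_length(sets$down, 0L)
})
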