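genes2 <- data.frame(gene_id = c("gp", "gm"), chrom = "c1",
                     strand = c("+", "-"), start = c(1000L, 1000L),
                     end = c(2000L, 2000L), stringsAsFactors = FALSE)

test_that("TSS is the strand-aware gene boundary", {
  expect_equal(derive_tss(genes2), c(1000L, 2000L))
  # mirrored genes on opposite strands have mirrored TSSs
  L <- 3000L
  mirrored <- genes2
  mirrored$strand <- c("-", "+")
  mirrored$start <- L + 1L - c(2000L, 2000L)
  mirrored$end <- L + 1L - c(1000L, 1000L)
  expect_equal(L + 1L - derive_tss(mirrored), derive_tss(genes2))
})

test_that("promoter windows follow the -500/+100 geometry on both strands", {
  pw <- promoter_windows(genes2)
  # + strand, tss 1000: [499, 1099); - strand, tss 2000: [1900, 2500)
  expect_equal(pw$abs_start0, c(499L, 1900L))
  expect_equal(pw$abs_end0, c(1099L, 2500L))
  expect_equal(pw$abs_end0 - pw$abs_start0, c(600L, 600L))
  expect_false(any(pw$clipped))

  near <- data.frame(gene_id = "g0", chrom = "c1", strand = "+",
                     start = 100L, end = 500L, stringsAsFactors = FALSE)
  pw2 <- promoter_windows(near)
  expect_true(pw2$clipped)
  expect_equal(pw2$abs_start0, 0L)
  # explicit minus-strand example: tss=1000 covers [900, 1500)
  gm <- data.frame(gene_id = "g", chrom = "c1", strand = "-",
                   start = 500L, end = 1000L, stringsAsFactors = FALSE)
  pwm_ <- promoter_windows(gm)
  expect_equal(c(pwm_$abs_start0, pwm_$abs_end0), c(900L, 1500L))
})

test_that("promoter sequences come out in transcription orientation", {
  chrom <- paste(rep("ACGT", 1000), collapse = "")
  genome <- c(c1 = chrom)
  pw <- promoter_windows(genes2, up = 4L, down = 2L)
  seqs <- extract_promoter_sequences(genome, pw)
  plus <- substr(chrom, pw$abs_start0[1] + 1, pw$abs_end0[1])
  expect_equal(unname(seqs["gp"]), plus)
  minus_raw <- substr(chrom, pw$abs_start0[2] + 1, pw$abs_end0[2])
  expect_equal(unname(seqs["gm"]), revcomp(minus_raw))
  expect_equal(revcomp(revcomp(minus_raw)), minus_raw)
  expect_error(extract_promoter_sequences(c(cX = "ACGT"), pw), "absent")
})

test_that("planted fixture promoter extraction matches the genome slice", {
  ds <- small_fixture()
  seqs <- extract_promoter_sequences(ds$genome, ds$promoters)
  i <- which(ds$promoters$strand == "-")[1]
  raw <- substr(ds$genome[[ds$promoters$chrom[i]]],
                ds$promoters$abs_start0[i] + 1, ds$promoters$abs_end0[i])
  expect_equal(unname(seqs[ds$promoters$gene_id[i]]), revcomp(raw))
})

test_that("SNP assignment offsets are signed, strand-aware distances", {
  pw <- promoter_windows(genes2)
  snps <- data.frame(
    id = c("up152", "at_tss", "dn90", "up152m", "outside"),
    chrom = "c1",
    pos = c(1000L - 152L, 1000L, 1000L + 90L, 2000L + 152L, 5000L),
    ref = "A", alt = "G", maf = 0.2, stringsAsFactors = FALSE)
  asg <- assign_snps_to_promoters(snps, pw)
  get <- function(id, gene) asg$offset[asg$snp_id == id &
                                         asg$gene_id == gene]
  expect_equal(get("up152", "gp"), -152L)
  expect_equal(get("at_tss", "gp"), 0L)
  expect_equal(get("dn90", "gp"), 90L)
  expect_equal(get("up152m", "gm"), -152L)  # minus strand mirrors
  expect_false("outside" %in% asg$snp_id)
})

test_that("assignment agrees with brute-force containment on random fixtures", {
  set.seed(11)
  for (rep in 1:3) {
    genes <- data.frame(
      gene_id = sprintf("g%d", 1:15), chrom = sample(c("c1", "c2"), 15, TRUE),
      strand = sample(c("+", "-"), 15, TRUE),
      start = sample(1000:50000, 15), stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(500:3000, 15)
    pw <- promoter_windows(genes)
    snps <- data.frame(id = sprintf("s%d", 1:200),
                       chrom = sample(c("c1", "c2"), 200, TRUE),
                       pos = sample(1:55000, 200), ref = "A", alt = "C",
                       maf = 0.2, stringsAsFactors = FALSE)
    asg <- assign_snps_to_promoters(snps, pw)
    # O(n*m) oracle
    expected <- list()
    for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(pw))) {
      if (snps$chrom[i] == pw$chrom[j] &&
          snps$pos[i] > pw$abs_start0[j] && snps$pos[i] <= pw$abs_end0[j])
        expected[[length(expected) + 1]] <- data.frame(
          snp_id = snps$id[i], gene_id = pw$gene_id[j],
          offset = if (pw$strand[j] == "+") snps$pos[i] - pw$tss[j]
                   else pw$tss[j] - snps$pos[i],
          stringsAsFactors = FALSE)
    }
    expected <- if (length(expected)) do.call(rbind, expected) else
      data.frame(snp_id = character(), gene_id = character(),
                 offset = integer())
    ord <- function(d) {
      d <- d[order(d$snp_id, d$gene_id), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(asg), ord(expected))
    # offsets always within the window
    expect_true(all(asg$offset >= -500L & asg$offset < 100L))
  }
})

test_that("offsets round-trip back to exact genomic positions", {
  ds <- small_fixture()
  asg <- assign_snps_to_promoters(ds$snps, ds$promoters)
  pos <- offset_to_position(asg, ds$promoters)
  expect_equal(pos, ds$snps$pos[match(asg$snp_id, ds$snps$id)])
})

test_that("position histograms bin half-open and conserve counts", {
  h0 <- position_histogram(integer(0), bin_width = 50L)
  expect_equal(sum(h0$count), 0L)
  h1 <- position_histogram(-1L, bin_width = 50L)
  expect_equal(h1$count[h1$bin_start == -50L & h1$bin_end == 0L], 1L)
  expect_equal(sum(h1$count), 1L)
  set.seed(5)
  offs <- sample(-500:99, 2000, replace = TRUE)
  h <- position_histogram(offs, bin_width = 50L)
  expect_equal(sum(h$count), 2000L)
  # uniform offsets give flat bins within multinomial error (5 sd)
  expected <- 2000 / nrow(h)
  sd_bin <- sqrt(2000 * (1 / nrow(h)) * (1 - 1 / nrow(h)))
  expect_true(all(abs(h$count - expected) < 5 * sd_bin))
})

test_that("gc_content counts G+C over non-N length", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCNN"), 1.0)
  expect_error(gc_content("NNN"), "all-N")
})
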