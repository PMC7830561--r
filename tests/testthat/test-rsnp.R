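test_that("flank extraction swaps exactly the central base", {
  genome <- c(c1 = "AACGTCA")
  snp <- data.frame(id = "s1", chrom = "c1", pos = 4L, ref = "G",
                    alt = "T", maf = 0.2, stringsAsFactors = FALSE)
  fl <- extract_flanks(genome, snp, k = 1L)
  expect_equal(fl$ref_seq, "CGT")
  expect_equal(fl$alt_seq, "CTT")
  # minimal k=1 example on "ACG": center C, alt G
  fl2 <- extract_flanks(c(c1 = "ACG"),
                        data.frame(id = "s", chrom = "c1", pos = 2L,
                                   ref = "C", alt = "G", maf = 0.2),
                        k = 1L)
  expect_equal(c(fl2$ref_seq, fl2$alt_seq), c("ACG", "AGG"))
  # ref mismatch is an error
  bad <- snp; bad$ref <- "A"
  expect_error(extract_flanks(genome, bad, k = 1L), "disagrees")
  # edge SNPs are flagged and skipped
  edge <- data.frame(id = "e", chrom = "c1", pos = 1L, ref = "A",
                     alt = "G", maf = 0.2)
  expect_warning(fe <- extract_flanks(genome, edge, k = 2L), "edge")
  expect_true(fe$skipped)
})

test_that("flank pairs differ at exactly one position on the fixture", {
  ds <- small_fixture()
  fl <- extract_flanks(ds$genome, ds$snps, k = 25L)
  expect_false(any(fl$skipped))
  expect_equal(nchar(fl$ref_seq), rep(51L, nrow(fl)))
  ham <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    fl$ref_seq, fl$alt_seq)
  expect_equal(unname(ham), rep(1L, nrow(fl)))
  expect_equal(substr(fl$ref_seq, 26, 26), ds$snps$ref)
  expect_equal(substr(fl$alt_seq, 26, 26), ds$snps$alt)
})

test_that("overlap filter keeps only sites covering the SNP base", {
  sites <- data.frame(matrix_id = "M", tf_name = "T",
                      start = c(20L, 26L, 19L, 25L), length = 6L,
                      strand = "+", mss = 0.9, stringsAsFactors = FALSE)
  kept <- overlap_filter(sites, center = 25L)
  expect_equal(kept$start, c(20L, 25L))  # 26 and 19 fall outside
})

test_that("consequence classification follows the four-way rule", {
  site <- function(start, mssv, id = "M1")
    data.frame(matrix_id = rep(id, length(start)),
               tf_name = rep("T", length(start)), start = start,
               length = rep(6L, length(start)),
               strand = rep("+", length(start)), mss = mssv,
               stringsAsFactors = FALSE)
  none <- site(integer(0), numeric(0))
  # ref-only site: loss; alt-only: gain
  expect_equal(classify_pair(site(22L, 0.91), none)$consequence,
               "LossOfTFBS")
  expect_equal(classify_pair(none, site(22L, 0.88))$consequence,
               "GainOfTFBS")
  # matched site with changed / unchanged score
  expect_equal(classify_pair(site(22L, 0.86), site(22L, 0.93))$consequence,
               "ScoreChange")
  expect_equal(classify_pair(site(22L, 0.90), site(22L, 0.90))$consequence,
               "NoChange")
  # a site shifting position counts as one loss plus one gain
  shifted <- classify_pair(site(22L, 0.9), site(23L, 0.9))
  expect_setequal(shifted$consequence, c("LossOfTFBS", "GainOfTFBS"))
})

test_that("rSNP calls require at least one gain or loss", {
  cons <- data.frame(
    snp_id = c("a", "a", "b", "c"),
    consequence = c("ScoreChange", "NoChange", "GainOfTFBS", "NoChange"),
    stringsAsFactors = FALSE)
  expect_equal(call_rsnps(cons), "b")
  expect_length(call_rsnps(cons[cons$snp_id == "c", , drop = FALSE]), 0L)
})

test_that("planted fixture is recovered exactly and labels are verified", {
  ds <- small_fixture()
  cons <- classify_snp_consequences(ds$genome, ds$snps, ds$pwms)
  called <- call_rsnps(cons)
  planted <- sort(ds$truth$snp_id[ds$truth$class %in% c("gain", "loss")])
  expect_equal(called, planted)
  gains <- unique(cons$snp_id[cons$consequence == "GainOfTFBS"])
  expect_true(all(ds$truth$snp_id[ds$truth$class == "gain"] %in% gains))
  losses <- unique(cons$snp_id[cons$consequence == "LossOfTFBS"])
  expect_true(all(ds$truth$snp_id[ds$truth$class == "loss"] %in% losses))
})

test_that("swapping ref and alt flips every loss into a gain and back", {
  ds <- small_fixture()
  cons <- classify_snp_consequences(ds$genome, ds$snps, ds$pwms)
  swapped_snps <- ds$snps
  names(swapped_snps)[names(swapped_snps) == "ref"] <- "tmp"
  names(swapped_snps)[names(swapped_snps) == "alt"] <- "ref"
  names(swapped_snps)[names(swapped_snps) == "tmp"] <- "alt"
  # genome must carry the (new) ref base: write the swap into the genome
  genome2 <- ds$genome
  for (i in seq_len(nrow(swapped_snps))) {
    ch <- swapped_snps$chrom[i]
    substr(genome2[[ch]], swapped_snps$pos[i], swapped_snps$pos[i]) <-
      swapped_snps$ref[i]
  }
  cons_sw <- classify_snp_consequences(genome2, swapped_snps, ds$pwms)
  flip <- c(LossOfTFBS = "GainOfTFBS", GainOfTFBS = "LossOfTFBS",
            ScoreChange = "ScoreChange", NoChange = "NoChange")
  key <- function(d) paste(d$snp_id, d$matrix_id, d$site_start, d$strand)
  expect_setequal(key(cons), key(cons_sw))
  m <- match(key(cons), key(cons_sw))
  expect_equal(cons_sw$consequence[m],
               unname(flip[cons$consequence]))
  expect_equal(cons_sw$mss_ref[m], cons$mss_alt)
  expect_equal(cons_sw$mss_alt[m], cons$mss_ref)
})

test_that("rSNP position annotation joins calls with offsets", {
  asg <- data.frame(snp_id = c("s1", "s2", "s3"),
                    gene_id = c("g1", "g1", "g2"),
                    offset = c(90L, -247L, 5L), stringsAsFactors = FALSE)
  ann <- annotate_rsnp_positions(c("s1", "s2"), asg)
  expect_equal(ann$offset, c(90L, -247L))
  expect_equal(nrow(annotate_rsnp_positions(character(0), asg)), 0L)
})
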