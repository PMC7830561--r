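# Allele-swap rSNP engine: build +/-25 bp flank pairs around each promoter
# SNP, scan both alleles with every PWM, keep sites that pass the MSS
# threshold and overlap the SNP base, and classify each SNP-TFBS pair as
# NoChange / ScoreChange / LossOfTFBS / GainOfTFBS. A SNP is an rSNP iff it
# causes at least one Loss or Gain.

CONSEQUENCE_LEVELS <- c("NoChange", "ScoreChange", "LossOfTFBS",
                        "GainOfTFBS")

#' Extract allele-swapped flanking sequences for SNPs
#'
#' For each SNP takes the `k` bp of genome on either side (a `2k+1` bp
#' window, 51 bp at the default `k = 25`, SNP in the central position) and
#' returns two copies: one carrying the reference allele at the center, one
#' the alternate. SNPs within `k` bp of a chromosome edge are flagged
#' (`skipped = TRUE`) with `NA` sequences and excluded from scanning.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param snps SNP data.frame (see [read_snp_vcf()]).
#' @param k Flank half-width in bp (default 25).
#' @return A data.frame with columns `snp_id`, `ref_seq`, `alt_seq`,
#'   `skipped`.
#' @export
extract_flanks <- function(genome, snps, k = 25L) {
  genome <- as_genome(genome)
  check_snps_against_genome(snps, genome)
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- nrow(snps)
  ref_seq <- alt_seq <- rep(NA_character_, n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    pos <- snps$pos[i]
    if (pos - k < 1L || pos + k > chrlen[[snps$chrom[i]]]) {
      skipped[i] <- TRUE
      next
    }
    s <- as.character(Biostrings::subseq(genome[[snps$chrom[i]]],
                                         start = pos - k, end = pos + k))
    substr(s, k + 1L, k + 1L) <- snps$ref[i]
    ref_seq[i] <- s
    substr(s, k + 1L, k + 1L) <- snps$alt[i]
    alt_seq[i] <- s
  }
  if (any(skipped))
    warning(sum(skipped), " SNP(s) within ", k,
            " bp of a chromosome edge skipped", call. = FALSE)
  data.frame(snp_id = snps$id, ref_seq = ref_seq, alt_seq = alt_seq,
             skipped = skipped, stringsAsFactors = FALSE)
}

#' Keep only sites overlapping the SNP position of a flank
#'
#' Retains sites whose interval `[start, start + length)` contains the
#' central (0-based) index of the flank.
#'
#' @param sites ScoredSite data.frame from [scan_sequence()].
#' @param center 0-based index of the SNP base in the flank (default 25).
#' @return The retained subset of `sites`.
#' @export
overlap_filter <- function(sites, center = 25L) {
  keep <- sites$start <= center & center < sites$start + sites$length
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify allele-dependent binding-site consequences for one SNP
#'
#' Takes the threshold- and overlap-filtered site lists of the reference
#' and alternate flank of a single SNP, matches sites across alleles by
#' `(matrix_id, start, strand)`, and labels each pair: matched with
#' `|delta MSS| <= eps` is `NoChange`, matched with a larger difference is
#' `ScoreChange`, reference-only is `LossOfTFBS`, alternate-only is
#' `GainOfTFBS`. A site that shifts position between alleles counts as one
#' Loss plus one Gain.
#'
#' @param ref_sites,alt_sites Filtered site data.frames for the two
#'   alleles.
#' @param eps Score-equality tolerance separating `NoChange` from
#'   `ScoreChange` (default 1e-9, a floating-point guard).
#' @return A data.frame with columns `matrix_id`, `tf_name`, `site_start`,
#'   `strand`, `mss_ref`, `mss_alt` (NA when the site is absent on that
#'   allele), `consequence`.
#' @export
classify_pair <- function(ref_sites, alt_sites, eps = 1e-9) {
  key <- function(s) paste(s$matrix_id, s$start, s$strand, sep = "\r")
  rk <- key(ref_sites)
  ak <- key(alt_sites)
  all_keys <- union(rk, ak)
  if (length(all_keys) == 0L)
    return(data.frame(matrix_id = character(), tf_name = character(),
                      site_start = integer(), strand = character(),
                      mss_ref = numeric(), mss_alt = numeric(),
                      consequence = character(), stringsAsFactors = FALSE))
  ri <- match(all_keys, rk)
  ai <- match(all_keys, ak)
  mss_ref <- ref_sites$mss[ri]   # NA where the site is absent on ref
  mss_alt <- alt_sites$mss[ai]
  matrix_id <- ifelse(is.na(ri), alt_sites$matrix_id[ai],
                      ref_sites$matrix_id[ri])
  tf_name <- ifelse(is.na(ri), alt_sites$tf_name[ai],
                    ref_sites$tf_name[ri])
  site_start <- as.integer(ifelse(is.na(ri), alt_sites$start[ai],
                                  ref_sites$start[ri]))
  strand <- ifelse(is.na(ri), alt_sites$strand[ai], ref_sites$strand[ri])
  consequence <- ifelse(
    is.na(mss_ref), "GainOfTFBS",
    ifelse(is.na(mss_alt), "LossOfTFBS",
           ifelse(abs(mss_ref - mss_alt) <= eps, "NoChange",
                  "ScoreChange")))
  out <- data.frame(matrix_id = matrix_id, tf_name = tf_name,
                    site_start = site_start, strand = strand,
                    mss_ref = mss_ref, mss_alt = mss_alt,
                    consequence = consequence, stringsAsFactors = FALSE)
  out <- out[order(out$matrix_id, out$site_start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict binding-site consequences for a set of SNPs
#'
#' The full allele-swap engine: flank extraction, dual-allele scanning of
#' every PWM on both strands, MSS thresholding, SNP-overlap filtering and
#' four-way classification. Callers restrict `snps` to promoter SNPs first
#' (see [assign_snps_to_promoters()]); the engine itself is
#' promoter-agnostic.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param snps SNP data.frame.
#' @param pwms List of `pwm` objects.
#' @param threshold MSS threshold (default 0.85).
#' @param k Flank half-width (default 25).
#' @param eps NoChange/ScoreChange tolerance (default 1e-9).
#' @param strands Strand policy passed to [scan_sequence()].
#' @return A data.frame with one row per (SNP, TFBS) consequence: columns
#'   `snp_id`, `matrix_id`, `tf_name`, `site_start`, `strand`, `mss_ref`,
#'   `mss_alt`, `consequence`.
#' @export
classify_snp_consequences <- function(genome, snps, pwms, threshold = 0.85,
                                      k = 25L, eps = 1e-9,
                                      strands = "both") {
  flanks <- extract_flanks(genome, snps, k = k)
  out <- vector("list", nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    if (flanks$skipped[i]) next
    ref_sites <- overlap_filter(
      scan_sequence(pwms, flanks$ref_seq[i], threshold = threshold,
                    strands = strands), center = k)
    alt_sites <- overlap_filter(
      scan_sequence(pwms, flanks$alt_seq[i], threshold = threshold,
                    strands = strands), center = k)
    rec <- classify_pair(ref_sites, alt_sites, eps = eps)
    if (nrow(rec))
      out[[i]] <- cbind(data.frame(snp_id = flanks$snp_id[i],
                                   stringsAsFactors = FALSE), rec)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(snp_id = character(), matrix_id = character(),
                      tf_name = character(), site_start = integer(),
                      strand = character(), mss_ref = numeric(),
                      mss_alt = numeric(), consequence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call rSNPs from consequence records
#'
#' A SNP is a regulatory SNP iff at least one of its records is a
#' `LossOfTFBS` or `GainOfTFBS`. Score changes alone do not qualify.
#'
#' @param consequences Output of [classify_snp_consequences()].
#' @return Character vector of rSNP ids (sorted, unique).
#' @export
call_rsnps <- function(consequences) {
  sort(unique(consequences$snp_id[
    consequences$consequence %in% c("LossOfTFBS", "GainOfTFBS")]))
}

#' Annotate rSNP calls with TSS-relative promoter positions
#'
#' Joins the rSNP id set with SNP-to-promoter assignments, yielding the
#' per-(rSNP, gene) offset table behind TSS-distance histograms.
#'
#' @param rsnp_ids Character vector from [call_rsnps()].
#' @param assignments Output of [assign_snps_to_promoters()].
#' @return The subset of `assignments` whose `snp_id` is an rSNP.
#' @export
annotate_rsnp_positions <- function(rsnp_ids, assignments) {
  out <- assignments[assignments$snp_id %in% rsnp_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
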