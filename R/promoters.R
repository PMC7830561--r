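# Promoter geometry. External formats keep their native conventions
# (VCF/GFF3 are 1-based inclusive); internally promoter windows are 0-based
# half-open [abs_start0, abs_end0), converted at the I/O boundary.

#' Derive transcription start sites from gene models
#'
#' The TSS is the strand-aware gene boundary: `start` for `+` genes, `end`
#' for `-` genes (gene-level anchoring; no per-transcript TSSs).
#'
#' @param genes Gene-model data.frame (see [read_gene_gff3()]).
#' @return Integer vector of 1-based TSS coordinates, one per gene.
#' @export
derive_tss <- function(genes) {
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$start <= genes$end))
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Promoter windows around gene TSSs
#'
#' Builds the strand-aware promoter window covering `up` bp upstream
#' through `down` bp downstream of each TSS (default -500/+100, a 600 bp
#' window). In 0-based half-open genomic coordinates a `+`-strand promoter
#' at 1-based TSS `t` covers `[t-1-up, t-1+down)` and a `-`-strand promoter
#' covers `[t-down, t+up)`. Windows running past a chromosome edge are
#' clipped and flagged in the `clipped` column, never silently shortened.
#'
#' @param genes Gene-model data.frame.
#' @param up Upstream extent in bp (default 500).
#' @param down Downstream extent in bp (default 100).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   right-edge clipping.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (1-based), `abs_start0`, `abs_end0` (0-based half-open), `up`, `down`,
#'   `clipped`.
#' @export
promoter_windows <- function(genes, up = 500L, down = 100L,
                             chrom_lengths = NULL) {
  stopifnot(up >= 0L, down >= 0L)
  tss <- derive_tss(genes)
  plus <- genes$strand == "+"
  abs_start0 <- ifelse(plus, tss - 1L - up, tss - down)
  abs_end0 <- ifelse(plus, tss - 1L + down, tss + up)
  clipped <- abs_start0 < 0L
  abs_start0 <- pmax(abs_start0, 0L)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[genes$chrom])
    if (anyNA(len))
      stop("chromosome(s) missing from chrom_lengths: ",
           paste(setdiff(unique(genes$chrom), names(chrom_lengths)),
                 collapse = ", "), call. = FALSE)
    clipped <- clipped | abs_end0 > len
    abs_end0 <- pmin(abs_end0, len)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = tss,
             abs_start0 = as.integer(abs_start0),
             abs_end0 = as.integer(abs_end0),
             up = as.integer(up), down = as.integer(down),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Extract promoter sequences in transcription orientation
#'
#' Minus-strand windows are reverse-complemented so every returned string
#' reads 5' to 3' in the direction of transcription.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param promoters Promoter data.frame from [promoter_windows()].
#' @return Named character vector of promoter sequences (names =
#'   `gene_id`).
#' @export
extract_promoter_sequences <- function(genome, promoters) {
  genome <- as_genome(genome)
  missing_chr <- setdiff(unique(promoters$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  seqs <- vapply(seq_len(nrow(promoters)), function(i) {
    s <- as.character(Biostrings::subseq(
      genome[[promoters$chrom[i]]],
      start = promoters$abs_start0[i] + 1L,
      end = promoters$abs_end0[i]))
    if (promoters$strand[i] == "-") revcomp(s) else s
  }, character(1))
  names(seqs) <- promoters$gene_id
  seqs
}

#' Assign SNPs to promoter windows with TSS-relative offsets
#'
#' One record is emitted per (SNP, gene) pair whose promoter contains the
#' SNP; a SNP inside two overlapping promoters yields two records. The
#' offset is the signed strand-aware distance from the TSS: negative
#' offsets are upstream of the TSS in transcription orientation, offset 0
#' is the TSS base itself, and downstream offsets run 0 ... down-1.
#'
#' @param snps SNP data.frame (see [read_snp_vcf()]).
#' @param promoters Promoter data.frame from [promoter_windows()].
#' @return A data.frame with columns `snp_id`, `gene_id`, `offset`.
#' @export
assign_snps_to_promoters <- function(snps, promoters) {
  empty <- data.frame(snp_id = character(), gene_id = character(),
                      offset = integer(), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || nrow(promoters) == 0L) return(empty)
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  prom_gr <- GenomicRanges::GRanges(
    seqnames = promoters$chrom,
    ranges = IRanges::IRanges(start = promoters$abs_start0 + 1L,
                              end = promoters$abs_end0))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, prom_gr))
  if (length(hits) == 0L) return(empty)
  si <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  offset <- ifelse(promoters$strand[pi] == "+",
                   snps$pos[si] - promoters$tss[pi],
                   promoters$tss[pi] - snps$pos[si])
  out <- data.frame(snp_id = snps$id[si], gene_id = promoters$gene_id[pi],
                    offset = as.integer(offset), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reconstruct genomic positions from TSS-relative offsets
#'
#' Inverse of the offset arithmetic in [assign_snps_to_promoters()]:
#' `pos = tss + offset` on `+` strands and `pos = tss - offset` on `-`
#' strands. Used to verify coordinate round-trips.
#'
#' @param assignments Data.frame with `gene_id` and `offset` columns.
#' @param promoters Promoter data.frame from [promoter_windows()].
#' @return Integer vector of 1-based genomic positions.
#' @export
offset_to_position <- function(assignments, promoters) {
  i <- match(assignments$gene_id, promoters$gene_id)
  if (anyNA(i))
    stop("gene_id(s) absent from promoters: ",
         paste(unique(assignments$gene_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  as.integer(ifelse(promoters$strand[i] == "+",
                    promoters$tss[i] + assignments$offset,
                    promoters$tss[i] - assignments$offset))
}

#' Histogram of TSS-relative SNP positions
#'
#' Bins signed offsets over `[-up, down)` with half-open bins; counts sum
#' to the number of input records.
#'
#' @param offsets Integer vector of signed TSS-relative offsets.
#' @param bin_width Bin width in bp (>= 1).
#' @param up,down Window extents defining the histogram range.
#' @return A data.frame with columns `bin_start`, `bin_end` (half-open) and
#'   `count`.
#' @export
position_histogram <- function(offsets, bin_width = 50L, up = 500L,
                               down = 100L) {
  stopifnot(bin_width >= 1L)
  starts <- seq(-up, down - 1L, by = bin_width)
  ends <- pmin(starts + bin_width, down)  # last bin may be narrower
  counts <- vapply(seq_along(starts), function(i)
    sum(offsets >= starts[i] & offsets < ends[i]), integer(1))
  if (length(offsets) && any(offsets < -up | offsets >= down))
    warning("offset(s) outside [-up, down) ignored", call. = FALSE)
  data.frame(bin_start = as.integer(starts), bin_end = as.integer(ends),
             count = counts)
}

#' GC content of a sequence
#'
#' `(#G + #C) / (length - #N)`; `N` bases are excluded from the
#' denominator.
#'
#' @param sequence Non-empty character string over `A/C/G/T/N`.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  stopifnot(nchar(sequence) > 0L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  denom <- sum(chars != "N")
  if (denom == 0L)
    stop("all-N sequence has undefined GC content", call. = FALSE)
  sum(chars %in% c("G", "C")) / denom
}

#' Plot a TSS-relative position histogram
#'
#' Simple base-graphics bar rendering of [position_histogram()] output,
#' written to a PNG file. With zero total counts a warning is raised and an
#' empty plot is still produced.
#'
#' @param hist_df Output of [position_histogram()].
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_position_histogram <- function(hist_df, path,
                                    main = "SNP positions relative to TSS") {
  if (sum(hist_df$count) == 0L)
    warning("empty position table: writing an empty plot", call. = FALSE)
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::barplot(hist_df$count,
                    names.arg = hist_df$bin_start,
                    space = 0, las = 2, col = "grey40", border = NA,
                    xlab = "offset from TSS (bp, bin start)",
                    ylab = "count", main = main)
  invisible(path)
}
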