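#' @useDynLib rsnpscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Read a genome FASTA file
#'
#' Sequences are uppercased on read; lowercase (soft-masked) input is
#' accepted. Only `A`, `C`, `G`, `T` and `N` are permitted.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one entry per chromosome.
#'   Names are the first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L)
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in '", path, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence in '", path, "'", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other",
                                                              drop = TRUE]
  if (any(bad > 0))
    stop("non-ACGTN characters in sequences: ",
         paste(names(seqs)[bad > 0], collapse = ", "), call. = FALSE)
  seqs
}

#' Write a genome FASTA file
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

as_genome <- function(genome) {
  if (is.character(genome)) {
    stopifnot(!is.null(names(genome)))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` are retained; `gene_id` is taken from the
#' `ID` attribute. Records with unknown strand (`.`) are skipped with a
#' warning, since no TSS can be derived for them.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive).
#' @export
read_gene_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("GFF3 gene feature without an ID attribute in '", path, "'",
         call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning(sum(strand == "*"), " gene record(s) with unknown strand '.' ",
            "skipped", call. = FALSE)
    keep <- strand != "*"
    gr <- gr[keep]; ids <- ids[keep]; strand <- strand[keep]
  }
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to a GFF3 file
#'
#' @param genes Gene-model data.frame as returned by [read_gene_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "rsnpscan"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read biallelic SNVs from a VCF file
#'
#' Multi-allelic records are split into one record per ALT allele; indels
#' and alleles outside `A/C/G/T` are dropped. The minor allele frequency is
#' taken from the `MAF` INFO field when present, otherwise computed from
#' genotypes when the file has sample columns, otherwise left `NA`.
#'
#' @param path Path to a VCF 4.x file (sites-only or with genotypes).
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when given,
#'   every record's REF allele is checked against the genome base and a
#'   mismatch raises an error naming the site.
#' @return A data.frame with columns `id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `maf`.
#' @export
read_snp_vcf <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  vcf <- VariantAnnotation::readVcf(path)
  ids0 <- names(SummarizedExperiment::rowRanges(vcf))
  n_alt <- S4Vectors::elementNROWS(
    VariantAnnotation::alt(vcf))
  vcf <- VariantAnnotation::expand(vcf)  # one row per ALT allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  # expand() drops row names; replicate the originals per ALT allele
  id <- if (is.null(ids0)) paste0(chrom, ":", pos) else rep(ids0, n_alt)

  maf <- rep(NA_real_, length(pos))
  info <- VariantAnnotation::info(vcf)
  if ("MAF" %in% colnames(info)) {
    m <- info$MAF
    if (is.list(m) || methods::is(m, "List")) m <- vapply(m, function(x)
      if (length(x)) as.numeric(x[[1]]) else NA_real_, numeric(1))
    maf <- as.numeric(m)
  } else if (ncol(vcf) > 0L) {
    gt <- VariantAnnotation::geno(vcf)$GT
    if (!is.null(gt)) maf <- apply(gt, 1L, maf_from_gt)
  }

  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  snps <- data.frame(id = id[keep], chrom = chrom[keep], pos = pos[keep],
                     ref = ref[keep], alt = alt[keep], maf = maf[keep],
                     stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    check_snps_against_genome(snps, genome)
  }
  snps
}

maf_from_gt <- function(gt) {
  alleles <- unlist(strsplit(gt, "[/|]"))
  alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) return(NA_real_)
  f <- mean(alleles > 0)
  min(f, 1 - f)
}

check_snps_against_genome <- function(snps, genome) {
  if (nrow(snps) == 0L) return(invisible(snps))
  missing_chr <- setdiff(unique(snps$chrom), names(genome))
  if (length(missing_chr))
    stop("SNP chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  base <- vapply(seq_len(nrow(snps)), function(i) {
    as.character(Biostrings::subseq(genome[[snps$chrom[i]]],
                                    start = snps$pos[i], width = 1L))
  }, character(1))
  bad <- which(base != snps$ref)
  if (length(bad))
    stop("REF allele disagrees with genome at ",
         paste0(snps$chrom[bad], ":", snps$pos[bad],
                " (VCF ", snps$ref[bad], ", genome ", base[bad], ")",
                collapse = "; "), call. = FALSE)
  invisible(snps)
}

#' Write SNVs to a minimal VCF 4.2 file
#'
#' @param snps SNP data.frame as returned by [read_snp_vcf()].
#' @param path Output path.
#' @param contigs Optional named integer vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(snps$maf), ".", sprintf("MAF=%g", snps$maf))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  snps$chrom, snps$pos, snps$id, snps$ref, snps$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs whose MAF is strictly greater than `threshold` (the
#' high-quality marker rule MAF > 0.05).
#'
#' @param snps SNP data.frame with a populated `maf` column.
#' @param threshold MAF threshold; default 0.05.
#' @return The retained subset of `snps`.
#' @export
filter_maf <- function(snps, threshold = 0.05) {
  if (nrow(snps) > 0L && anyNA(snps$maf))
    stop("missing MAF for ", sum(is.na(snps$maf)), " SNP(s); supply ",
         "genotypes in the VCF or a precomputed MAF INFO field",
         call. = FALSE)
  out <- snps[snps$maf > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a DEG results table
#'
#' Expects a TSV with header columns `gene`, `log2FoldChange`, `padj` (extra
#' columns are ignored). Rows with missing `padj` are retained with
#' `padj = NA`; they are never called significant downstream, mirroring the
#' independent-filtering semantics of the upstream DE tool.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene`, `log2fc`, `padj`.
#' @export
read_deg_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "log2FoldChange", "padj")
  if (!all(need %in% colnames(tab)))
    stop("DEG table '", path, "' lacks required column(s): ",
         paste(setdiff(need, colnames(tab)), collapse = ", "), call. = FALSE)
  data.frame(gene = as.character(tab$gene),
             log2fc = as.numeric(tab$log2FoldChange),
             padj = as.numeric(tab$padj),
             stringsAsFactors = FALSE)
}

#' Write a DEG results table
#'
#' @param deg DEG data.frame with columns `gene`, `log2fc`, `padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  out <- data.frame(gene = deg$gene, log2FoldChange = deg$log2fc,
                    padj = deg$padj)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a generic TSV table
#'
#' Canonical writer used for all pipeline outputs (tab-separated, header,
#' no quoting, no row names) so that reruns are byte-identical.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
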