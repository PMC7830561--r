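# End-to-end orchestration: DEG filtering -> promoter extraction ->
# per-tissue TFBS enrichment -> SNP-to-promoter assignment -> allele-swap
# rSNP classification -> Boruta consensus -> joins and TSS histograms.
# Every stage writes its table; a manifest records versions, seed and a
# parameter hash so any output is exactly reproducible.

#' Build a pipeline configuration
#'
#' @param genome,gff,vcf,pfm Input file paths (FASTA, GFF3, VCF, JASPAR
#'   PFM).
#' @param deg_tables Named character vector of per-tissue DEG TSV paths.
#' @param genotypes,labels Genotype matrix and label TSV paths (optional;
#'   the association stage is skipped when absent).
#' @param out_dir Output directory.
#' @param promoter_up,promoter_down Promoter window (bp).
#' @param mss_threshold MSS threshold for site calls.
#' @param flank_k SNP flank half-width (bp).
#' @param maf_threshold MAF filter (strictly greater than).
#' @param lfc,deg_alpha DEG thresholds.
#' @param enrich_alpha Bonferroni-adjusted enrichment threshold.
#' @param bg_ratio,gc_bin_width GC-matched background parameters.
#' @param boruta_runs,boruta_trees,boruta_max_iter Association parameters.
#' @param hist_bin_width TSS histogram bin width (bp).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param write_plots Also render PNG histograms (default FALSE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff, vcf, pfm, deg_tables,
                            genotypes = NULL, labels = NULL,
                            out_dir = "rsnpscan_out",
                            promoter_up = 500L, promoter_down = 100L,
                            mss_threshold = 0.85, flank_k = 25L,
                            maf_threshold = 0.05,
                            lfc = 2, deg_alpha = 0.05,
                            enrich_alpha = 0.01, bg_ratio = 1L,
                            gc_bin_width = 0.05,
                            boruta_runs = 20L, boruta_trees = 500L,
                            boruta_max_iter = 100L,
                            hist_bin_width = 50L,
                            seed = 1L, write_plots = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()];
#' `deg_tables` is a mapping tissue -> path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$deg_tables <- unlist(y$deg_tables)
  do.call(pipeline_config, y)
}

validate_config <- function(cfg) {
  paths <- c(genome = cfg$genome, gff = cfg$gff, vcf = cfg$vcf,
             pfm = cfg$pfm, cfg$deg_tables,
             genotypes = cfg$genotypes, labels = cfg$labels)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) do not exist: ",
         paste(sprintf("%s (%s)", names(missing), missing),
               collapse = "; "), call. = FALSE)
  stopifnot(cfg$mss_threshold >= 0, cfg$mss_threshold <= 1,
            cfg$flank_k >= 1, cfg$enrich_alpha > 0, cfg$enrich_alpha <= 1)
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message("[rsnpscan] ", stage, ": ", ...)
}

#' Run the full rSNP analysis pipeline
#'
#' Executes all stages in order against the configured inputs and writes
#' every intermediate table plus `manifest.json` into `out_dir`. Reruns
#' with an identical configuration and seed produce byte-identical
#' outputs. A stage failure aborts with the stage name; tables already
#' written are retained.
#'
#' @param cfg A `pipeline_config` (or path to a YAML file).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res <- list(config = cfg)

  run_stage("load_inputs", {
    res$genome <- read_genome_fasta(cfg$genome)
    res$genes <- read_gene_gff3(cfg$gff)
    res$snps <- read_snp_vcf(cfg$vcf, genome = res$genome)
    res$pwms <- read_jaspar_pfm(cfg$pfm)
    res$deg_raw <- lapply(cfg$deg_tables, read_deg_table)
    stage_log("load_inputs", nrow(res$snps), " SNPs, ",
              nrow(res$genes), " genes, ", length(res$pwms), " PWMs, ",
              length(res$deg_raw), " DEG tables")
  })

  run_stage("maf_filter", {
    res$snps <- filter_maf(res$snps, cfg$maf_threshold)
    stage_log("maf_filter", nrow(res$snps), " SNPs with MAF > ",
              cfg$maf_threshold)
    write_tsv(res$snps, file.path(cfg$out_dir, "snps_maf_filtered.tsv"))
  })

  run_stage("filter_degs", {
    res$deg_sets <- lapply(res$deg_raw, filter_degs, lfc = cfg$lfc,
                           alpha = cfg$deg_alpha)
    for (tis in names(res$deg_sets)) {
      s <- res$deg_sets[[tis]]
      stage_log("filter_degs", tis, ": ", length(s$up), " up, ",
                length(s$down), " down")
      write_tsv(data.frame(
        gene_id = c(s$up, s$down),
        direction = rep(c("up", "down"), c(length(s$up), length(s$down)))),
        file.path(cfg$out_dir, paste0("degs_", tis, ".tsv")))
    }
  })

  run_stage("promoters", {
    chrom_len <- stats::setNames(Biostrings::width(res$genome),
                                 names(res$genome))
    res$promoters <- promoter_windows(res$genes, up = cfg$promoter_up,
                                      down = cfg$promoter_down,
                                      chrom_lengths = chrom_len)
    res$promoter_seqs <- extract_promoter_sequences(res$genome,
                                                    res$promoters)
    res$promoter_gc <- vapply(res$promoter_seqs, gc_content, numeric(1))
    stage_log("promoters", nrow(res$promoters), " promoter windows (",
              sum(res$promoters$clipped), " clipped)")
    write_tsv(res$promoters, file.path(cfg$out_dir, "promoters.tsv"))
  })

  run_stage("enrichment", {
    tf_names <- vapply(res$pwms, `[[`, character(1), "tf_name")
    all_genes <- res$promoters$gene_id
    res$presence_all <- tfbs_presence(res$promoter_seqs, res$pwms,
                                      threshold = cfg$mss_threshold)
    res$enrichment <- list()
    for (tis in names(res$deg_sets)) {
      fg_genes <- intersect(
        unlist(res$deg_sets[[tis]], use.names = FALSE), all_genes)
      if (length(fg_genes) == 0L) {
        stage_log("enrichment", tis, ": no DEG promoters; skipped")
        next
      }
      bg_genes <- select_background(
        fg_genes, setdiff(all_genes, fg_genes), res$promoter_gc,
        ratio = cfg$bg_ratio, bin_width = cfg$gc_bin_width,
        seed = stage_seed(cfg$seed, paste0("enrich:", tis)))
      er <- enrich(res$presence_all[fg_genes, , drop = FALSE],
                   res$presence_all[bg_genes, , drop = FALSE],
                   alpha = cfg$enrich_alpha, tf_names = tf_names)
      res$enrichment[[tis]] <- er
      stage_log("enrichment", tis, ": ", sum(er$enriched),
                " enriched TF(s) of ", nrow(er))
      write_tsv(er, file.path(cfg$out_dir,
                              paste0("enrichment_", tis, ".tsv")))
    }
  })

  run_stage("assign_snps", {
    res$assignments <- assign_snps_to_promoters(res$snps, res$promoters)
    stage_log("assign_snps", nrow(res$assignments),
              " SNP-promoter assignments (",
              length(unique(res$assignments$snp_id)), " promoter SNPs)")
    write_tsv(res$assignments,
              file.path(cfg$out_dir, "snp_promoter_assignments.tsv"))
  })

  run_stage("classify_rsnps", {
    prom_snps <- res$snps[res$snps$id %in% res$assignments$snp_id, ,
                          drop = FALSE]
    res$consequences <- classify_snp_consequences(
      res$genome, prom_snps, res$pwms, threshold = cfg$mss_threshold,
      k = cfg$flank_k)
    res$rsnps <- call_rsnps(res$consequences)
    res$rsnp_positions <- annotate_rsnp_positions(res$rsnps,
                                                  res$assignments)
    stage_log("classify_rsnps", nrow(res$consequences),
              " consequence records; ", length(res$rsnps), " rSNPs")
    cons_out <- merge(res$consequences,
                      res$snps[, c("id", "chrom", "pos", "ref", "alt")],
                      by.x = "snp_id", by.y = "id", sort = FALSE)
    cons_out <- cons_out[order(cons_out$snp_id, cons_out$matrix_id,
                               cons_out$site_start, cons_out$strand), ]
    write_tsv(cons_out, file.path(cfg$out_dir, "consequences.tsv"))
    write_tsv(data.frame(snp_id = res$rsnps),
              file.path(cfg$out_dir, "rsnps.tsv"))
    write_tsv(res$rsnp_positions,
              file.path(cfg$out_dir, "rsnp_positions.tsv"))
    res$rsnp_hist <- position_histogram(res$rsnp_positions$offset,
                                        bin_width = cfg$hist_bin_width,
                                        up = cfg$promoter_up,
                                        down = cfg$promoter_down)
    write_tsv(res$rsnp_hist,
              file.path(cfg$out_dir, "rsnp_position_histogram.tsv"))
    if (isTRUE(cfg$write_plots))
      plot_position_histogram(res$rsnp_hist,
                              file.path(cfg$out_dir, "rsnp_positions.png"),
                              main = "rSNP positions relative to TSS")
  })

  if (!is.null(cfg$genotypes) && !is.null(cfg$labels)) {
    run_stage("association", {
      M <- read_genotype_tsv(cfg$genotypes)
      L <- read_labels_tsv(cfg$labels)
      M <- M[names(L), colnames(M) %in% res$rsnps, drop = FALSE]
      cons <- consensus_important(
        M, L, n_runs = cfg$boruta_runs,
        base_seed = stage_seed(cfg$seed, "boruta"),
        max_iter = cfg$boruta_max_iter, n_trees = cfg$boruta_trees)
      res$important <- cons$important
      stage_log("association", length(res$important),
                " important rSNPs of ", ncol(M), " tested (",
                cfg$boruta_runs, " runs)")
      write_tsv(data.frame(snp_id = res$important),
                file.path(cfg$out_dir, "important_rsnps.tsv"))
      decisions <- do.call(rbind, lapply(seq_along(cons$runs), function(i)
        data.frame(run = i, snp_id = names(cons$runs[[i]]$decision),
                   decision = as.character(cons$runs[[i]]$decision),
                   stringsAsFactors = FALSE)))
      write_tsv(decisions, file.path(cfg$out_dir, "boruta_decisions.tsv"))
    })
  }

  run_stage("joins", {
    deg_union <- lapply(res$deg_sets, function(s)
      unique(c(s$up, s$down)))
    res$degs_with_rsnps <- degs_with_rsnps(deg_union, res$rsnp_positions)
    for (tis in names(res$degs_with_rsnps))
      write_tsv(res$degs_with_rsnps[[tis]],
                file.path(cfg$out_dir,
                          paste0("degs_with_rsnps_", tis, ".tsv")))
    if (!is.null(res$important)) {
      res$important_per_tissue <- important_rsnps_per_tissue(
        res$important, res$rsnp_positions, deg_union)
      for (tis in names(res$important_per_tissue)) {
        tab <- res$important_per_tissue[[tis]]
        stage_log("joins", tis, ": ", length(unique(tab$snp_id)),
                  " important rSNPs in DEG promoters, ",
                  length(unique(tab$gene_id)), " DEGs harboring them")
        write_tsv(tab, file.path(cfg$out_dir,
                                 paste0("important_rsnps_", tis, ".tsv")))
      }
    }
    if (length(deg_union) >= 2L)
      write_tsv(venn_counts(deg_union),
                file.path(cfg$out_dir, "deg_venn_counts.tsv"))
  })

  run_stage("manifest", {
    cfg_plain <- unclass(cfg)
    # output location and plot toggles do not affect any table; keep the
    # manifest invariant to them so reruns are comparable byte for byte
    cfg_plain$out_dir <- NULL
    cfg_plain$write_plots <- NULL
    cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    manifest <- list(
      package = "rsnpscan",
      version = as.character(utils::packageVersion("rsnpscan")),
      seed = cfg$seed,
      parameter_hash = unname(tools::md5sum(tmp)),
      parameters = cfg_plain,
      counts = list(
        snps = nrow(res$snps),
        promoter_snps = length(unique(res$assignments$snp_id)),
        rsnps = length(res$rsnps),
        important_rsnps = if (is.null(res$important)) NULL
                          else length(res$important)))
    unlink(tmp)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(res)
}
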