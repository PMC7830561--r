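# Deterministic synthetic fixtures with the statistical structure the
# pipeline assumes: an i.i.d. background genome with non-overlapping genes,
# a motif library with sharp and moderate columns, planted allele-swap
# gains/losses verified against the package's own scanner at generation
# time (truth labels are guaranteed, not probabilistic), Hardy-Weinberg
# genotypes with class-differentiated allele frequencies at planted
# association SNPs, and DEG tables with planted up/down sets.

#' Simulation configuration
#'
#' Defaults describe a desk-scale world mirroring the structure of the
#' real data: a two-cultivar panel of 280 + 133 samples, -500/+100
#' promoters, +/-25 bp SNP flanks, MSS threshold 0.85, MAF > 0.05, an
#' allele-frequency differentiation of 0.4 at planted association SNPs,
#' and DEG calls at |log2FC| > 2, padj < 0.05 in four tissues.
#'
#' @param seed Master seed; one seed reproduces every fixture byte for
#'   byte.
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param gc Background GC fraction (0.37, a typical Brassica genome-wide
#'   value).
#' @param n_genes Total genes, split evenly over chromosomes.
#' @param promoter_up,promoter_down Promoter window extents in bp.
#' @param n_pwms Motif library size.
#' @param motif_length Range (min, max) of motif lengths.
#' @param n_gain,n_loss,n_neutral Planted SNP counts per consequence class.
#' @param flank_k SNP flank half-width.
#' @param mss_threshold Scanner threshold used by the generator-verifier.
#' @param n_samples Named pair of per-class sample counts.
#' @param delta Planted allele-frequency difference between classes.
#' @param n_important Number of planted association SNPs (drawn from the
#'   planted gain/loss rSNPs).
#' @param tissues Tissue names for DEG tables.
#' @param n_up,n_down Planted up/down DEG counts per tissue.
#' @param deg_overlap Fraction of planted DEGs shared across all tissues.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 200000L,
                       gc = 0.37,
                       n_genes = 60L,
                       promoter_up = 500L,
                       promoter_down = 100L,
                       n_pwms = 8L,
                       motif_length = c(8L, 10L),
                       n_gain = 50L,
                       n_loss = 50L,
                       n_neutral = 100L,
                       flank_k = 25L,
                       mss_threshold = 0.85,
                       n_samples = c(high_oil = 280L, low_oil = 133L),
                       delta = 0.4,
                       n_important = 5L,
                       tissues = c("flower", "leaf", "stem", "root"),
                       n_up = 8L,
                       n_down = 8L,
                       deg_overlap = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$delta >= 0, cfg$delta <= 1,
            cfg$n_gain >= 0, cfg$n_loss >= 0, cfg$n_neutral >= 0,
            length(cfg$n_samples) == 2L, all(cfg$n_samples > 0),
            cfg$deg_overlap >= 0, cfg$deg_overlap <= 1)
  structure(cfg, class = "sim_config")
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %%
               (.Machine$integer.max - 1)) + 1L
}

random_dna <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate a genome with non-overlapping genes
#'
#' Chromosomes are i.i.d. bases at the configured GC; genes are laid out
#' in per-chromosome slots on random strands with enough margin that every
#' promoter (and every SNP flank inside it) lies fully inside its
#' chromosome.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector) and `genes`
#'   (gene-model data.frame).
#' @export
simulate_genome_and_genes <- function(config) {
  cfg <- config
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  slot <- cfg$chromosome_length %/% per_chrom
  margin <- cfg$promoter_up + cfg$promoter_down + 2L * cfg$flank_k + 50L
  gene_len_range <- c(800L, 2000L)
  if (slot < margin * 2L + gene_len_range[2])
    stop("chromosomes too short to place ", per_chrom,
         " genes per chromosome without overlap; increase ",
         "chromosome_length", call. = FALSE)
  with_seed(stage_seed(cfg$seed, "genome"), {
    genome <- stats::setNames(
      vapply(seq_len(cfg$n_chromosomes), function(i)
        random_dna(cfg$chromosome_length, cfg$gc), character(1)),
      sprintf("chrA%02d", seq_len(cfg$n_chromosomes)))
    recs <- list()
    g <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      for (si in seq_len(per_chrom)) {
        if (g >= cfg$n_genes) break
        g <- g + 1L
        slot_start <- (si - 1L) * slot + 1L
        glen <- sample(seq(gene_len_range[1], gene_len_range[2]), 1L)
        lo <- slot_start + margin
        hi <- slot_start + slot - margin - glen
        start <- sample(seq(lo, hi), 1L)
        recs[[g]] <- data.frame(
          gene_id = sprintf("BnaSim%03d", g),
          chrom = names(genome)[ci],
          strand = sample(c("+", "-"), 1L),
          start = start, end = start + glen - 1L,
          stringsAsFactors = FALSE)
      }
    }
    list(genome = genome, genes = do.call(rbind, recs))
  })
}

#' Simulate a motif library
#'
#' Each motif mixes sharp columns (dominant base frequency ~0.90-0.97)
#' with moderate columns (~0.45-0.65) so that mutating the
#' highest-information column of an embedded consensus word reliably
#' crosses the MSS threshold, as the planting step requires.
#'
#' @param config A [sim_config()].
#' @return A list of `pwm` objects carrying integer `counts` attributes
#'   for lossless PFM round-trips.
#' @export
simulate_pwms <- function(config) {
  cfg <- config
  with_seed(stage_seed(cfg$seed, "pwms"), {
    pwms <- lapply(seq_len(cfg$n_pwms), function(i) {
      L <- sample(seq(cfg$motif_length[1], cfg$motif_length[2]), 1L)
      n_sharp <- floor(L / 2)
      sharp <- sample(seq_len(L), n_sharp)
      counts <- matrix(0L, nrow = 4L, ncol = L,
                       dimnames = list(DNA_BASES, NULL))
      for (j in seq_len(L)) {
        p <- if (j %in% sharp) stats::runif(1, 0.90, 0.97)
             else stats::runif(1, 0.45, 0.65)
        dom <- sample(1:4, 1L)
        rest <- as.integer(round((1 - p) * 100 / 3))
        col <- rep(rest, 4L)
        col[dom] <- 100L - 3L * rest
        counts[, j] <- col
      }
      p <- pfm_to_pwm(sprintf("SIM%04d", i), sprintf("SimTF%d", i), counts)
      p$counts <- counts
      p
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "matrix_id")
    pwms
  })
}

choose_site_position <- function(prom, L, k, chrom_len, used, min_gap) {
  # returns a 1-based genomic start for a motif of length L inside the
  # promoter, with every base of the site >= k from the chromosome edge,
  # not closer than min_gap to any used interval; NA if no slot
  lo <- max(prom$abs_start0 + 1L, k + 1L)
  hi <- min(prom$abs_end0, chrom_len - k) - L + 1L
  if (hi < lo) return(NA_integer_)
  cand <- seq(lo, hi)
  if (nrow(used)) {
    ok <- vapply(cand, function(s)
      all(s + L - 1L + min_gap < used$start | s - min_gap > used$end),
      logical(1))
    cand <- cand[ok]
  }
  if (length(cand) == 0L) return(NA_integer_)
  cand[sample.int(length(cand), 1L)]
}

#' Plant scanner-verified SNP consequences into a genome
#'
#' Gains: the consensus word of a random motif is written into a random
#' promoter with its highest-information column mutated to the
#' anti-consensus base; the SNP restores the consensus on the alternate
#' allele. Losses are symmetric (intact consensus, SNP breaks it).
#' Neutral SNPs are random promoter substitutions away from planted
#' sites. Every candidate is verified by running the package's own
#' allele-swap classifier; candidates failing verification are re-drawn,
#' so the returned truth labels are exact.
#'
#' @param genome Named character vector (mutated copy is returned).
#' @param promoters Promoter data.frame from [promoter_windows()].
#' @param pwms Motif library from [simulate_pwms()].
#' @param config A [sim_config()].
#' @param max_tries Placement retries per SNP before giving up.
#' @return A list with `genome` (edited), `snps` (SNP data.frame) and
#'   `truth` (data.frame snp_id, class, gene_id, matrix_id).
#' @export
plant_snp_consequences <- function(genome, promoters, pwms, config,
                                   max_tries = 200L) {
  cfg <- config
  k <- cfg$flank_k
  chrom_len <- vapply(genome, nchar, integer(1))
  max_L <- max(vapply(pwms, pwm_length, integer(1)))
  used <- data.frame(chrom = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  snps <- list(); truth <- list(); n_id <- 0L

  plant_one <- function(class) {
    for (try in seq_len(max_tries)) {
      pi <- sample.int(nrow(promoters), 1L)
      prom <- promoters[pi, ]
      clen <- chrom_len[[prom$chrom]]
      used_c <- used[used$chrom == prom$chrom, , drop = FALSE]
      if (class == "neutral") {
        s <- choose_site_position(prom, 1L, k, clen, used_c, max_L)
        if (is.na(s)) next
        pos <- s
        ref <- substr(genome[[prom$chrom]], pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        mid <- NA_character_
      } else {
        wi <- sample.int(length(pwms), 1L)
        pwm <- pwms[[wi]]
        L <- pwm_length(pwm)
        s <- choose_site_position(prom, L, k, clen, used_c, max_L)
        if (is.na(s)) next
        word <- consensus_word(pwm)
        j <- which.max(information_vector(pwm))
        good <- substr(word, j, j)
        bad <- substr(anti_consensus_word(pwm), j, j)
        if (bad == good) next
        broken <- word
        substr(broken, j, j) <- bad
        planted <- if (class == "gain") broken else word
        substr(genome[[prom$chrom]], s, s + L - 1L) <<- planted
        pos <- s + j - 1L
        ref <- substr(planted, j, j)
        alt <- if (class == "gain") good else bad
        mid <- pwm$matrix_id
      }
      id <- sprintf("snp%04d", n_id + 1L)
      cand <- data.frame(id = id, chrom = prom$chrom, pos = pos,
                         ref = ref, alt = alt,
                         maf = round(stats::runif(1, 0.06, 0.5), 4L),
                         stringsAsFactors = FALSE)
      cons <- classify_snp_consequences(genome, cand, pwms,
                                        threshold = cfg$mss_threshold,
                                        k = k)
      ok <- switch(class,
        gain = any(cons$consequence == "GainOfTFBS"),
        loss = any(cons$consequence == "LossOfTFBS"),
        neutral = !any(cons$consequence %in%
                         c("GainOfTFBS", "LossOfTFBS")))
      if (ok) {
        n_id <<- n_id + 1L
        span <- if (class == "neutral") c(pos, pos)
                else c(s, s + nchar(planted) - 1L)
        used <<- rbind(used, data.frame(chrom = prom$chrom,
                                        start = span[1], end = span[2],
                                        stringsAsFactors = FALSE))
        snps[[n_id]] <<- cand
        truth[[n_id]] <<- data.frame(snp_id = id, class = class,
                                     gene_id = prom$gene_id,
                                     matrix_id = mid,
                                     stringsAsFactors = FALSE)
        return(TRUE)
      }
      # undo a failed motif edit by restoring random background
      if (class != "neutral")
        substr(genome[[prom$chrom]], s, s + nchar(planted) - 1L) <<-
          random_dna(nchar(planted), cfg$gc)
    }
    stop("could not place a '", class, "' SNP after ", max_tries,
         " tries; enlarge the genome or reduce planted counts",
         call. = FALSE)
  }

  with_seed(stage_seed(cfg$seed, "plant"), {
    for (i in seq_len(cfg$n_gain)) plant_one("gain")
    for (i in seq_len(cfg$n_loss)) plant_one("loss")
    for (i in seq_len(cfg$n_neutral)) plant_one("neutral")
  })
  list(genome = genome,
       snps = do.call(rbind, snps),
       truth = do.call(rbind, truth))
}

#' Simulate Hardy-Weinberg genotypes with planted class differentiation
#'
#' Each SNP gets a class-shared alt-allele frequency drawn uniform(0.1,
#' 0.5); planted association SNPs instead differ by `delta` between the
#' two classes (base frequency uniform(0.3, 0.5), clipped into (0, 1)
#' with a warning if needed). Genotypes are Binomial(2, p) within class.
#' Columns whose empirical MAF falls at or below 0.05 are re-drawn.
#'
#' @param config A [sim_config()].
#' @param snp_ids All SNP ids to simulate.
#' @param important_ids Subset of `snp_ids` planted as class-associated.
#' @return A list with `genotypes` (samples x SNPs matrix), `labels`
#'   (named factor), `important` (character vector).
#' @export
simulate_genotypes <- function(config, snp_ids, important_ids = NULL) {
  cfg <- config
  stopifnot(all(important_ids %in% snp_ids))
  n1 <- cfg$n_samples[[1]]; n2 <- cfg$n_samples[[2]]
  classes <- names(cfg$n_samples)
  if (is.null(classes)) classes <- c("class1", "class2")
  with_seed(stage_seed(cfg$seed, "genotypes"), {
    labels <- factor(rep(classes, c(n1, n2)), levels = classes)
    names(labels) <- sprintf("s%03d", seq_len(n1 + n2))
    geno <- matrix(NA_real_, nrow = n1 + n2, ncol = length(snp_ids),
                   dimnames = list(names(labels), snp_ids))
    clipped <- FALSE
    for (j in seq_along(snp_ids)) {
      assoc <- snp_ids[j] %in% important_ids
      for (try in 1:100) {
        if (assoc) {
          base <- stats::runif(1, 0.3, 0.5)
          p1 <- base + cfg$delta / 2
          p2 <- base - cfg$delta / 2
          if (p1 >= 1 || p2 <= 0) {
            clipped <- TRUE
            p1 <- min(p1, 0.99); p2 <- max(p2, 0.01)
          }
        } else {
          p1 <- p2 <- stats::runif(1, 0.1, 0.5)
        }
        g <- c(stats::rbinom(n1, 2L, p1), stats::rbinom(n2, 2L, p2))
        f <- mean(g) / 2
        if (min(f, 1 - f) > 0.05) break
      }
      geno[, j] <- g
    }
    if (clipped)
      warning("delta pushed allele frequencies outside (0,1); clipped",
              call. = FALSE)
    list(genotypes = geno, labels = labels,
         important = as.character(important_ids))
  })
}

#' Simulate per-tissue DEG tables with planted truth
#'
#' Planted up genes get `log2fc > 2` and `padj < 0.05`; planted down genes
#' the mirror image; all remaining genes fail at least one criterion.
#' Boundary rows (`log2fc` exactly 2 or `padj` exactly 0.05) and `padj =
#' NA` rows are planted among the nulls to exercise the strict
#' inequalities. Cross-tissue overlap of the planted sets is controlled by
#' `deg_overlap` (1 means identical sets in every tissue).
#'
#' @param config A [sim_config()].
#' @param gene_ids Genes to tabulate (from the simulated annotation).
#' @return A list with `tables` (named list of DEG data.frames) and
#'   `truth` (named list of `list(up, down)`).
#' @export
simulate_deg_tables <- function(config, gene_ids) {
  cfg <- config
  n_planted <- cfg$n_up + cfg$n_down
  stopifnot(length(gene_ids) >= 2L * n_planted + 5L)
  with_seed(stage_seed(cfg$seed, "degs"), {
    n_shared_up <- round(cfg$deg_overlap * cfg$n_up)
    n_shared_down <- round(cfg$deg_overlap * cfg$n_down)
    pool <- sample(gene_ids)  # deterministic permutation
    shared_up <- pool[seq_len(n_shared_up)]
    shared_down <- pool[n_shared_up + seq_len(n_shared_down)]
    free <- pool[-(seq_len(n_shared_up + n_shared_down))]
    truth <- list(); tables <- list()
    for (tis in cfg$tissues) {
      extra_up <- sample(free, cfg$n_up - n_shared_up)
      extra_down <- sample(setdiff(free, extra_up),
                           cfg$n_down - n_shared_down)
      up <- c(shared_up, extra_up)
      down <- c(shared_down, extra_down)
      lfc <- stats::runif(length(gene_ids), -1.9, 1.9)
      padj <- stats::runif(length(gene_ids), 0, 1)
      names(lfc) <- names(padj) <- gene_ids
      lfc[up] <- 2 + stats::runif(length(up), 0.2, 3)
      padj[up] <- 10^-stats::runif(length(up), 2, 8)
      lfc[down] <- -(2 + stats::runif(length(down), 0.2, 3))
      padj[down] <- 10^-stats::runif(length(down), 2, 8)
      nulls <- setdiff(gene_ids, c(up, down))
      bnd <- nulls[seq_len(min(5L, length(nulls)))]
      if (length(bnd) >= 1L) { lfc[bnd[1]] <- 2; padj[bnd[1]] <- 0.001 }
      if (length(bnd) >= 2L) { lfc[bnd[2]] <- -2; padj[bnd[2]] <- 0.001 }
      if (length(bnd) >= 3L) { lfc[bnd[3]] <- 3.5; padj[bnd[3]] <- 0.05 }
      if (length(bnd) >= 4L) { lfc[bnd[4]] <- 3.5; padj[bnd[4]] <- NA }
      if (length(bnd) >= 5L) { lfc[bnd[5]] <- -3.5; padj[bnd[5]] <- 0.6 }
      tables[[tis]] <- data.frame(gene = gene_ids,
                                  log2fc = round(unname(lfc), 6L),
                                  padj = signif(unname(padj), 6L),
                                  stringsAsFactors = FALSE)
      truth[[tis]] <- list(up = sort(up), down = sort(down))
    }
    list(tables = tables, truth = truth)
  })
}

#' Generate and optionally write a complete synthetic dataset
#'
#' Runs every generator stage in order and, when `outdir` is given, writes
#' FASTA, GFF3, VCF, JASPAR PFM, genotype/label TSVs, per-tissue DEG TSVs
#' and truth TSVs. Fully deterministic: one seed reproduces every file
#' byte-identically.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @return A list with `genome`, `genes`, `promoters`, `pwms`, `snps`,
#'   `truth`, `genotypes`, `labels`, `important`, `deg_tables`,
#'   `deg_truth`, and `paths` (when written).
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  cfg <- config
  gg <- simulate_genome_and_genes(cfg)
  pwms <- simulate_pwms(cfg)
  chrom_len <- vapply(gg$genome, nchar, integer(1))
  promoters <- promoter_windows(gg$genes, up = cfg$promoter_up,
                                down = cfg$promoter_down,
                                chrom_lengths = chrom_len)
  stopifnot(!any(promoters$clipped))
  planted <- plant_snp_consequences(gg$genome, promoters, pwms, cfg)
  rsnp_ids <- planted$truth$snp_id[planted$truth$class %in%
                                     c("gain", "loss")]
  important_ids <- with_seed(stage_seed(cfg$seed, "important"),
                             sample(rsnp_ids, min(cfg$n_important,
                                                  length(rsnp_ids))))
  gt <- simulate_genotypes(cfg, planted$snps$id, important_ids)
  degs <- simulate_deg_tables(cfg, gg$genes$gene_id)
  out <- list(genome = planted$genome, genes = gg$genes,
              promoters = promoters, pwms = pwms,
              snps = planted$snps, truth = planted$truth,
              genotypes = gt$genotypes, labels = gt$labels,
              important = sort(gt$important),
              deg_tables = degs$tables, deg_truth = degs$truth,
              config = cfg)
  if (!is.null(outdir)) out$paths <- write_dataset(out, outdir)
  out
}

write_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "snps.vcf"),
    pfm = file.path(outdir, "motifs.pfm"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    truth_snps = file.path(outdir, "truth_snps.tsv"),
    truth_important = file.path(outdir, "truth_important.tsv")
  )
  write_genome_fasta(ds$genome, p$genome)
  write_gene_gff3(ds$genes, p$gff)
  write_snp_vcf(ds$snps, p$vcf,
                contigs = vapply(ds$genome, nchar, integer(1)))
  write_jaspar_pfm(ds$pwms, p$pfm)
  gt <- data.frame(sample = rownames(ds$genotypes), ds$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gt, p$genotypes)
  write_tsv(data.frame(sample = names(ds$labels),
                       label = as.character(ds$labels)), p$labels)
  write_tsv(ds$truth, p$truth_snps)
  write_tsv(data.frame(snp_id = ds$important), p$truth_important)
  for (tis in names(ds$deg_tables)) {
    p[[paste0("deg_", tis)]] <- file.path(outdir,
                                          paste0("deg_", tis, ".tsv"))
    write_deg_table(ds$deg_tables[[tis]], p[[paste0("deg_", tis)]])
  }
  p
}
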