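# TFBS over-representation in DEG promoters versus GC-matched background
# promoters: gene-level presence/absence, one-sided Fisher exact test,
# Bonferroni control over the matrices tested.

#' Select a GC-matched background promoter set
#'
#' Promoters are binned by GC content (`bin_width` wide bins); for each
#' foreground promoter, `ratio` background promoters are drawn without
#' replacement from the same bin, so the background GC histogram matches
#' the foreground's. Foreground genes are always excluded. When a bin has
#' too few candidates, the deficit is borrowed from progressively more
#' distant neighbouring bins with a warning.
#'
#' @param fg_genes Foreground gene ids.
#' @param candidate_genes Candidate background gene ids (any overlap with
#'   `fg_genes` is removed).
#' @param promoter_gc Named numeric vector of promoter GC contents covering
#'   both sets.
#' @param ratio Background promoters drawn per foreground promoter
#'   (default 1).
#' @param bin_width GC bin width (default 0.05).
#' @param seed Integer seed making the draw reproducible.
#' @return Character vector of background gene ids.
#' @export
select_background <- function(fg_genes, candidate_genes, promoter_gc,
                              ratio = 1L, bin_width = 0.05, seed = 1L) {
  candidate_genes <- setdiff(candidate_genes, fg_genes)
  missing <- setdiff(c(fg_genes, candidate_genes), names(promoter_gc))
  if (length(missing))
    stop("promoter GC missing for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  n_needed <- length(fg_genes) * ratio
  if (length(candidate_genes) < n_needed)
    stop("background pool too small: need ", n_needed, " promoters, have ",
         length(candidate_genes), " (deficit ",
         n_needed - length(candidate_genes), ")", call. = FALSE)
  gc_bin <- function(g) as.integer(floor(promoter_gc[g] / bin_width))
  fg_bins <- table(gc_bin(fg_genes))
  cand_bins <- split(candidate_genes, gc_bin(candidate_genes))
  chosen <- character(0)
  borrowed <- 0L
  with_seed(seed, {
    # iterate bins in deterministic order
    for (b in names(fg_bins)) {
      want <- as.integer(fg_bins[[b]]) * ratio
      pool <- setdiff(cand_bins[[b]], chosen)
      take <- sample_n_of(pool, min(want, length(pool)))
      chosen <- c(chosen, take)
      deficit <- want - length(take)
      dist <- 1L
      while (deficit > 0L) {
        nb <- as.character(c(as.integer(b) - dist, as.integer(b) + dist))
        pool <- setdiff(unlist(cand_bins[nb], use.names = FALSE), chosen)
        take <- sample_n_of(pool, min(deficit, length(pool)))
        chosen <- c(chosen, take)
        borrowed <- borrowed + length(take)
        deficit <- deficit - length(take)
        dist <- dist + 1L
        if (dist > 1L / bin_width + 1L && deficit > 0L)
          stop("cannot satisfy GC bin ", b, ": deficit ", deficit,
               call. = FALSE)
      }
    }
  })
  if (borrowed > 0L)
    warning(borrowed, " background promoter(s) borrowed from adjacent GC ",
            "bins", call. = FALSE)
  chosen
}

sample_n_of <- function(x, n) {
  # sample() mis-handles length-1 numeric-looking vectors; guard it
  if (n <= 0L || length(x) == 0L) return(character(0))
  if (length(x) == 1L) return(x[seq_len(min(n, 1L))])
  sample(x, n)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Binding-site presence matrix over promoter sequences
#'
#' Scans every promoter with every PWM (both strands) and records whether
#' at least one site reaches the MSS threshold.
#'
#' @param promoter_seqs Named character vector of promoter sequences (in
#'   transcription orientation).
#' @param pwms List of `pwm` objects.
#' @param threshold MSS threshold (default 0.85).
#' @return Binary integer matrix, rows = genes, columns = matrix ids.
#' @export
tfbs_presence <- function(promoter_seqs, pwms, threshold = 0.85) {
  ids <- vapply(pwms, `[[`, character(1), "matrix_id")
  m <- matrix(0L, nrow = length(promoter_seqs), ncol = length(pwms),
              dimnames = list(names(promoter_seqs), ids))
  for (j in seq_along(pwms)) {
    for (i in seq_along(promoter_seqs)) {
      sites <- scan_sequence(pwms[[j]], promoter_seqs[[i]],
                             threshold = threshold, strands = "both")
      if (nrow(sites)) m[i, j] <- 1L
    }
  }
  m
}

#' Test TFBS over-representation in foreground vs background promoters
#'
#' Per matrix, a one-sided Fisher exact test (over-representation in the
#' foreground) on the 2x2 table of promoters with/without at least one
#' site, Bonferroni-corrected over the number of matrices actually tested.
#'
#' @param fg,bg Presence matrices from [tfbs_presence()] with identical
#'   columns.
#' @param alpha Bonferroni-adjusted significance threshold (default 0.01).
#' @param tf_names Optional vector of TF names aligned with the matrix
#'   columns; defaults to the matrix ids.
#' @return A data.frame with columns `matrix_id`, `tf_name`, `fg_hits`,
#'   `fg_total`, `bg_hits`, `bg_total`, `odds_ratio`, `p_value`,
#'   `p_bonferroni`, `enriched`, ordered by p-value.
#' @export
enrich <- function(fg, bg, alpha = 0.01, tf_names = NULL) {
  stopifnot(identical(colnames(fg), colnames(bg)))
  n_tests <- ncol(fg)
  a <- colSums(fg); c_ <- colSums(bg)
  m <- nrow(fg); n <- nrow(bg)
  p <- fisher_one_sided(a, m, c_, n)
  or <- (a * (n - c_)) / ((m - a) * c_)  # sample OR; Inf/NaN left as is
  out <- data.frame(
    matrix_id = colnames(fg),
    tf_name = if (is.null(tf_names)) colnames(fg) else unname(tf_names),
    fg_hits = unname(a), fg_total = m,
    bg_hits = unname(c_), bg_total = n,
    odds_ratio = unname(or), p_value = unname(p),
    stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, out$p_value * n_tests)
  out$enriched <- out$p_bonferroni < alpha
  out <- out[order(out$p_value, out$matrix_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  attr(out, "alternative") <- "greater"
  out
}

#' One-sided Fisher exact p-value for over-representation
#'
#' Exact probability, under the hypergeometric null with both margins
#' fixed, of observing at least `a` foreground hits: the one-sided
#' (greater) Fisher exact test for the table
#' `[a, m - a; c, n - c]`. Computed as the upper hypergeometric tail;
#' vectorized over tables. A zero-width table (`m` or `n` zero) gives
#' p = 1.
#'
#' @param a Foreground hit counts.
#' @param m Foreground totals.
#' @param c_ Background hit counts.
#' @param n Background totals.
#' @return Vector of p-values.
#' @export
fisher_one_sided <- function(a, m, c_, n) {
  p <- stats::phyper(a - 1, a + c_, (m - a) + (n - c_), m,
                     lower.tail = FALSE)
  p[m == 0 | n == 0] <- 1
  p
}
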