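# Boruta all-relevant feature selection over rSNP genotypes: shadow
# attributes, random-forest importance z-scores, binomial hit testing, and
# the consensus-over-repeats rule defining "important rSNPs".

#' Read a genotype matrix from TSV
#'
#' Expects samples in rows (first column `sample`) and rSNP ids in the
#' remaining column names; cells are alt-allele counts in `{0, 1, 2}` (NA
#' allowed, imputed later).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, rownames = sample ids, colnames = rSNP ids.
#' @export
read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "sample")
    stop("genotype TSV must have 'sample' as its first column", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab$sample
  m
}

#' Read binary sample labels from TSV
#'
#' Expects columns `sample` and `label` with exactly two label values.
#'
#' @param path Path to the TSV file.
#' @return Named factor of labels (names = sample ids).
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "label") %in% colnames(tab)))
  lab <- factor(tab$label)
  if (nlevels(lab) != 2L)
    stop("labels must have exactly 2 classes, found ", nlevels(lab),
         call. = FALSE)
  stats::setNames(lab, tab$sample)
}

#' Mode-impute missing genotypes per feature
#'
#' Tree ensembles need complete matrices; each feature's missing entries
#' are replaced by that feature's most frequent observed genotype.
#'
#' @param M Genotype matrix (samples x features).
#' @return The completed matrix.
#' @export
impute_genotypes <- function(M) {
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) {
      obs <- M[!miss, j]
      if (length(obs) == 0L)
        stop("feature ", colnames(M)[j], " is entirely missing",
             call. = FALSE)
      tab <- table(obs)
      M[miss, j] <- as.numeric(names(tab)[which.max(tab)])
    }
  }
  M
}

#' Augment a feature matrix with shadow attributes
#'
#' Appends, for every feature, one shadow column holding an independent
#' row-permutation of that feature (same value multiset, association with
#' any label destroyed). Shadow columns are named `shadow_<feature>`.
#'
#' @param M Feature matrix (samples x features).
#' @return Matrix of width `2 * ncol(M)`: originals then shadows.
#' @export
shadow_augment <- function(M) {
  stopifnot(ncol(M) >= 1L)
  shadows <- apply(M, 2L, sample)
  colnames(shadows) <- paste0("shadow_", colnames(M))
  cbind(M, shadows)
}

#' Random-forest variable importance z-scores
#'
#' Fits `n_trees` CART trees on stratified bootstrap samples (handles the
#' class imbalance of unequal cultivar panels) and computes each feature's
#' per-tree out-of-bag permutation importance. The VIS z-score is the mean
#' per-tree importance divided by its standard deviation across trees;
#' features with zero importance variance get z = 0 with a warning.
#'
#' @param X Feature matrix (samples x features), complete.
#' @param y Binary labels (factor, logical, or 0/1), one per row of `X`.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param seed Integer seed; the forest is deterministic given it.
#' @return Named numeric vector of z-scores, one per column of `X`.
#' @export
rf_importance <- function(X, y, n_trees = 500L, mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.integer(as.factor(y)) - 1L
  if (length(unique(y01)) < 2L)
    stop("labels are single-class; need both classes present", call. = FALSE)
  stopifnot(length(y01) == nrow(X))
  if (min(table(y01)) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  per_tree <- rf_per_tree_importance_cpp(X, y01, as.integer(n_trees),
                                         as.integer(mtry),
                                         as.integer(seed))
  mu <- colMeans(per_tree)
  sdv <- apply(per_tree, 2L, stats::sd)
  z <- ifelse(sdv > 0, mu / sdv, 0)
  if (any(sdv == 0))
    warning(sum(sdv == 0), " feature(s) with zero importance variance; ",
            "z-score set to 0", call. = FALSE)
  stats::setNames(z, colnames(X))
}

#' One Boruta run
#'
#' Iteratively: re-shuffle shadow attributes, fit the forest on the
#' extended matrix, score a "hit" for every active feature whose VIS
#' z-score exceeds the maximum shadow z-score, and decide features by a
#' two-sided binomial test of accumulated hits against 0.5 — significantly
#' more hits confirms, significantly fewer rejects. Decided features are
#' removed from the matrix; the loop ends when all features are decided or
#' `max_iter` is reached (the rest stay `Tentative`).
#'
#' @param M Genotype matrix (samples x rSNPs); NAs are mode-imputed.
#' @param L Binary labels, one per sample.
#' @param max_iter Iteration cap (default 100).
#' @param n_trees Trees per forest (default 500).
#' @param hit_alpha Binomial test level (default 0.05).
#' @param seed Integer seed for shuffles and forests.
#' @return A list of class `boruta_run` with elements `decision` (named
#'   factor: Confirmed/Rejected/Tentative), `hits`, `n_iter`,
#'   `importance_history` (iterations x features matrix of z-scores, NA
#'   after a feature is decided), `seed`.
#' @export
boruta_run <- function(M, L, max_iter = 100L, n_trees = 500L,
                       hit_alpha = 0.05, seed = 1L) {
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  M <- impute_genotypes(as.matrix(M))
  if (is.null(colnames(M)))
    colnames(M) <- paste0("f", seq_len(ncol(M)))
  features <- colnames(M)
  decision <- stats::setNames(rep("Tentative", length(features)), features)
  hits <- stats::setNames(rep(0L, length(features)), features)
  history <- matrix(NA_real_, nrow = 0L, ncol = length(features),
                    dimnames = list(NULL, features))
  active <- features
  iter <- 0L
  with_seed(seed, {
    while (length(active) > 0L && iter < max_iter) {
      iter <- iter + 1L
      ext <- shadow_augment(M[, active, drop = FALSE])
      z <- suppressWarnings(
        rf_importance(ext, L, n_trees = n_trees,
                      seed = sample.int(.Machine$integer.max, 1L)))
      shadow_max <- max(z[-seq_along(active)])
      z_feat <- z[seq_along(active)]
      hits[active] <- hits[active] + as.integer(z_feat > shadow_max)
      row <- rep(NA_real_, length(features))
      names(row) <- features
      row[active] <- z_feat
      history <- rbind(history, row)
      # two-sided binomial test of hit count vs 0.5
      for (f in active) {
        h <- hits[[f]]
        p_hi <- stats::pbinom(h - 1L, iter, 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(h, iter, 0.5)
        p2 <- min(1, 2 * min(p_hi, p_lo))
        if (p2 < hit_alpha)
          decision[[f]] <- if (h > iter / 2) "Confirmed" else "Rejected"
      }
      active <- features[decision[features] == "Tentative"]
    }
  })
  structure(list(
    decision = factor(decision,
                      levels = c("Confirmed", "Rejected", "Tentative")),
    hits = hits, n_iter = iter,
    importance_history = history, seed = seed),
    class = "boruta_run")
}

#' @export
print.boruta_run <- function(x, ...) {
  cat("Boruta run (seed ", x$seed, "): ", x$n_iter, " iterations\n",
      sep = "")
  print(table(x$decision))
  invisible(x)
}

derive_run_seeds <- function(base_seed, n_runs) {
  # affine stream mod 2^31 - 1: prefix-stable, so consensus sets are
  # monotone in n_runs for a shared base seed
  m <- .Machine$integer.max
  as.integer((as.numeric(base_seed) + 1664525 * seq_len(n_runs)) %% m) + 1L
}

#' Consensus important rSNPs over repeated Boruta runs
#'
#' Runs Boruta `n_runs` times with independently derived seeds and returns
#' the features confirmed in every run — the "important" set. Tentative
#' never counts as confirmed, so the set shrinks (weakly) as `n_runs`
#' grows under a shared seed prefix.
#'
#' @inheritParams boruta_run
#' @param n_runs Number of repeated runs (default 20; the published
#'   protocol suggests e.g. 1000).
#' @param base_seed Seed from which the per-run seeds are derived.
#' @param early_stop Stop once the running intersection is empty; the
#'   intersection is monotone, so the returned `important` set is
#'   unchanged, only `runs`/`confirmed_per_run` may be shorter (default
#'   FALSE).
#' @return A list with `important` (character vector), `confirmed_per_run`
#'   (list), `runs` (list of `boruta_run` objects).
#' @export
consensus_important <- function(M, L, n_runs = 20L, base_seed = 1L,
                                max_iter = 100L, n_trees = 500L,
                                hit_alpha = 0.05, early_stop = FALSE) {
  stopifnot(n_runs >= 1L)
  seeds <- derive_run_seeds(base_seed, n_runs)
  runs <- list()
  confirmed <- list()
  current <- NULL
  for (i in seq_len(n_runs)) {
    r <- boruta_run(M, L, max_iter = max_iter, n_trees = n_trees,
                    hit_alpha = hit_alpha, seed = seeds[i])
    runs[[i]] <- r
    confirmed[[i]] <- names(r$decision)[r$decision == "Confirmed"]
    current <- if (i == 1L) confirmed[[1]] else
      intersect(current, confirmed[[i]])
    if (early_stop && length(current) == 0L) break
  }
  list(important = sort(current), confirmed_per_run = confirmed,
       runs = runs)
}
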