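# Shared fixtures and independent oracles, all built in code.

# PWM from a raw count matrix (4 x L, rows A,C,G,T)
make_pwm <- function(counts, id = "TEST1", name = "TestTF",
                     pseudocount = 1e-4) {
  rsnpscan:::pfm_to_pwm(id, name, counts, pseudocount)
}

# random informative PWM of length L (deterministic given the RNG state)
random_pwm <- function(L, id = "RND") {
  counts <- replicate(L, {
    p <- runif(1, 0.5, 0.95)
    dom <- sample(1:4, 1)
    col <- rep(round((1 - p) * 60 / 3), 4)
    col[dom] <- 60 - sum(col[-dom])
    col
  })
  make_pwm(counts, id = id)
}

random_seq <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Independent MSS oracle: recompute the information-weighted min-max score
# from first principles, scalar arithmetic only.
oracle_mss <- function(pwm, word) {
  f <- pwm$freqs
  L <- ncol(f)
  iv <- vapply(seq_len(L), function(i)
    sum(f[, i] * log(4 * f[, i])), numeric(1))
  iv <- pmax(iv, 0)
  w <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  cur <- 0; mn <- 0; mx <- 0
  for (i in seq_len(L)) {
    cur <- cur + iv[i] * f[w[i], i]
    mn <- mn + iv[i] * min(f[, i])
    mx <- mx + iv[i] * max(f[, i])
  }
  (cur - mn) / (mx - mn)
}

# Naive double-loop scanner oracle built on oracle_mss
oracle_scan <- function(pwm, sequence, threshold) {
  L <- ncol(pwm$freqs)
  n <- nchar(sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rsnpscan::revcomp(sequence)
    for (off in seq_len(n - L + 1)) {
      word <- substr(s, off, off + L - 1)
      if (grepl("N", word)) next
      sc <- oracle_mss(pwm, word)
      if (sc >= threshold) {
        start0 <- if (strand == "+") off - 1 else n - L - (off - 1)
        rows[[length(rows) + 1]] <- data.frame(
          start = start0, strand = strand, mss = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), strand = character(),
                      mss = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exhaustive hypergeometric tail oracle: sum the probability of every
# table with at least `a` foreground hits, via log-binomials.
oracle_fisher_greater <- function(a, m, c_, n) {
  if (m == 0 || n == 0) return(1)
  K <- a + c_
  N <- m + n
  ks <- max(0, K - n):min(K, m)
  logp <- lchoose(m, ks) + lchoose(n, K - ks) - lchoose(N, K)
  sum(exp(logp[ks >= a]))
}

# One shared generator-verified default fixture, built once per session
# (used by several tests; ~200 planted SNPs takes tens of seconds).
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- simulate_dataset(sim_config(seed = 20260918L))
  .fixture_cache$ds
}

# Small fixture for cheap end-to-end tests
small_fixture <- function(seed = 7L) {
  key <- paste0("small", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_dataset(sim_config(
      seed = seed, n_gain = 5L, n_loss = 5L, n_neutral = 8L,
      n_genes = 24L, n_samples = c(high_oil = 30L, low_oil = 24L),
      n_up = 4L, n_down = 4L))
  .fixture_cache[[key]]
}
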