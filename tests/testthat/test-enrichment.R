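test_that("GC-matched background matches the foreground histogram", {
  set.seed(9)
  gc <- c(runif(40, 0.3, 0.35), runif(40, 0.3, 0.35),
          runif(60, 0.4, 0.45))
  names(gc) <- sprintf("g%03d", seq_along(gc))
  fg <- names(gc)[1:40]
  cand <- setdiff(names(gc), fg)
  bg <- select_background(fg, cand, gc, seed = 4L)
  expect_length(bg, 40L)
  expect_length(intersect(bg, fg), 0L)
  bins <- function(g) table(floor(gc[g] / 0.05))
  expect_equal(bins(bg), bins(fg), ignore_attr = TRUE)
  # determinism
  expect_identical(bg, select_background(fg, cand, gc, seed = 4L))
  expect_false(identical(bg, select_background(fg, cand, gc, seed = 5L)))
})

test_that("background selection borrows with a warning and errors on deficit", {
  gc <- c(a1 = 0.30, a2 = 0.31, b1 = 0.32, b2 = 0.41, b3 = 0.42)
  expect_warning(
    bg <- select_background(c("a1", "a2"), c("b1", "b2", "b3"), gc,
                            seed = 1L),
    "borrowed")
  expect_length(bg, 2L)
  expect_error(
    select_background(c("a1", "a2", "b1"), c("b2"), gc, seed = 1L),
    "deficit")
})

test_that("presence matrix flags promoters containing a passing site", {
  set.seed(10)
  p <- random_pwm(7, id = "M1")
  cons <- consensus_word(p)
  seqs <- c(gA = paste0(random_seq(40, 0), cons, random_seq(40, 0)),
            gB = paste(rep("A", 80), collapse = ""))
  m <- tfbs_presence(seqs, list(p), threshold = 0.85)
  expect_equal(m["gA", "M1"], 1L)
  expect_equal(m["gB", "M1"], 0L)
  # column sums match direct per-gene re-scans
  pwms <- list(p, random_pwm(6, id = "M2"))
  seqs2 <- vapply(1:12, function(i) random_seq(120), character(1))
  names(seqs2) <- sprintf("s%02d", 1:12)
  m2 <- tfbs_presence(seqs2, pwms, threshold = 0.8)
  direct <- vapply(pwms, function(pw)
    sum(vapply(seqs2, function(s)
      nrow(scan_sequence(pw, s, threshold = 0.8)) > 0, logical(1))),
    numeric(1))
  expect_equal(unname(colSums(m2)), direct)
})

test_that("enrichment p-values equal fisher.test and the enumeration oracle", {
  set.seed(12)
  for (i in 1:100) {
    m <- sample(1:30, 1); n <- sample(1:30, 1)
    a <- sample(0:m, 1); c_ <- sample(0:n, 1)
    p_pkg <- fisher_one_sided(a, m, c_, n)
    p_ft <- stats::fisher.test(
      matrix(c(a, m - a, c_, n - c_), nrow = 2, byrow = TRUE),
      alternative = "greater")$p.value
    p_or <- oracle_fisher_greater(a, m, c_, n)
    expect_equal(p_pkg, p_ft, tolerance = 1e-12)
    expect_equal(p_pkg, p_or, tolerance = 1e-12)
  }
})

test_that("enrich behaves at equal proportions and respects Bonferroni", {
  fg <- matrix(c(rep(1L, 30), rep(0L, 20)), ncol = 1,
               dimnames = list(NULL, "M1"))
  bg <- fg
  r <- enrich(fg, bg)
  expect_equal(r$odds_ratio, 1)
  expect_gte(r$p_value, 0.5)
  expect_false(r$enriched)
  # a strong signal with the documented 2x2 arithmetic
  fg2 <- matrix(c(rep(1L, 40), rep(0L, 10)), ncol = 1,
                dimnames = list(NULL, "M1"))
  bg2 <- matrix(c(rep(1L, 10), rep(0L, 40)), ncol = 1,
                dimnames = list(NULL, "M1"))
  r2 <- enrich(fg2, bg2)
  expect_equal(r2$p_value, oracle_fisher_greater(40, 50, 10, 50),
               tolerance = 1e-12)
  expect_equal(r2$p_bonferroni, min(1, r2$p_value * 1))
  expect_true(r2$enriched)
})

test_that("enriched set shrinks monotonically as alpha decreases", {
  set.seed(13)
  fg <- matrix(rbinom(50 * 10, 1, 0.6), 50, 10,
               dimnames = list(NULL, sprintf("M%02d", 1:10)))
  bg <- matrix(rbinom(50 * 10, 1, 0.3), 50, 10,
               dimnames = list(NULL, sprintf("M%02d", 1:10)))
  sets <- lapply(c(0.1, 0.01, 0.001), function(al) {
    r <- enrich(fg, bg, alpha = al)
    r$matrix_id[r$enriched]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})
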