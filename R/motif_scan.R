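# MATCH-style PWM scanning. Scores are matrix similarity scores (MSS):
# information-vector-weighted, min-max normalized to [0,1], where 1 means
# the word maximizes the PWM at every position and 0 means it minimizes it.

encode_dna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  codes <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
  codes  # NA for N or any non-ACGT character
}

#' Per-position information vector of a PWM
#'
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))`: zero for a uniform column and
#' approaching `ln 4` as a column becomes fully conserved. Used to weight
#' positions in the matrix similarity score.
#'
#' @param pwm A `pwm` object with strictly positive frequencies.
#' @return Numeric vector of length `pwm_length(pwm)`; all entries in
#'   `[0, ln 4]`.
#' @export
information_vector <- function(pwm) {
  f <- pwm$freqs
  iv <- colSums(f * log(4 * f))
  pmax(iv, 0)  # clip tiny negative rounding at uniform columns
}

#' Matrix similarity score of a word against a PWM
#'
#' `MSS = (Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) f(i, w_i)` and `Min`/`Max` the per-position
#' minimum/maximum attainable weighted frequencies. The per-position argmax
#' word (consensus) scores exactly 1 and the per-position argmin word
#' exactly 0.
#'
#' @param pwm A `pwm` object.
#' @param word Character string over `A/C/G/T` of length `pwm_length(pwm)`.
#' @return Score in `[0, 1]`.
#' @export
mss <- function(pwm, word) {
  codes <- encode_dna(word)
  L <- pwm_length(pwm)
  if (length(codes) != L)
    stop("word length ", length(codes), " != motif length ", L,
         call. = FALSE)
  if (anyNA(codes))
    stop("word contains non-ACGT characters", call. = FALSE)
  iv <- information_vector(pwm)
  f <- pwm$freqs
  cur <- sum(iv * f[cbind(codes, seq_len(L))])
  mn <- sum(iv * apply(f, 2L, min))
  mx <- sum(iv * apply(f, 2L, max))
  if (mx <= mn)
    stop("PWM '", pwm$matrix_id,
         "' is unscorable: all columns uniform (Max = Min)", call. = FALSE)
  (cur - mn) / (mx - mn)
}

#' Consensus word of a PWM
#'
#' Per-position argmax base; ties broken in A < C < G < T order. By
#' construction `mss(pwm, consensus_word(pwm)) == 1`.
#'
#' @param pwm A `pwm` object.
#' @return Character string of length `pwm_length(pwm)`.
#' @export
consensus_word <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs, 2L, which.max)], collapse = "")
}

#' Anti-consensus word of a PWM
#'
#' Per-position argmin base (ties A < C < G < T); scores exactly 0.
#'
#' @param pwm A `pwm` object.
#' @return Character string of length `pwm_length(pwm)`.
#' @export
anti_consensus_word <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs, 2L, which.min)], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param sequence Character string over `A/C/G/T/N`.
#' @return The reverse complement, 5' to 3'.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
}

scan_one_strand <- function(pwm, codes, threshold) {
  L <- ncol(pwm$freqs)
  n <- length(codes)
  n_off <- n - L + 1L
  if (n_off < 1L) return(integer(0))
  iv <- information_vector(pwm)
  f <- pwm$freqs
  mn <- sum(iv * apply(f, 2L, min))
  mx <- sum(iv * apply(f, 2L, max))
  if (mx <= mn)
    stop("PWM '", pwm$matrix_id,
         "' is unscorable: all columns uniform (Max = Min)", call. = FALSE)
  w <- sweep(f, 2L, iv, "*")  # 4 x L position weights
  # windows as an n_off x L index matrix into the coded sequence
  idx <- outer(seq_len(n_off), 0:(L - 1L), "+")
  win <- matrix(codes[idx], nrow = n_off)
  ok <- !apply(is.na(win), 1L, any)  # windows containing N are skipped
  score <- rep(NA_real_, n_off)
  if (any(ok)) {
    pos <- matrix(rep(seq_len(L), each = sum(ok)), ncol = L)
    cur <- rowSums(matrix(w[cbind(as.vector(win[ok, , drop = FALSE]),
                                  as.vector(pos))], ncol = L))
    score[ok] <- (cur - mn) / (mx - mn)
  }
  list(score = score, keep = which(ok & score >= threshold))
}

#' Scan a sequence for PWM matches above an MSS threshold
#'
#' Slides the PWM over every offset of `sequence` (and of its reverse
#' complement when `strands = "both"`), computes the MSS at each window, and
#' returns all sites at or above `threshold`. Windows containing `N` are
#' skipped. Minus-strand sites are reported in the coordinates of the input
#' sequence: a minus site starting at 0-based `start` covers
#' `[start, start + L)` of `sequence`, matched on its reverse complement.
#'
#' @param pwm A `pwm` object, or a list of them.
#' @param sequence Character string over `A/C/G/T/N`.
#' @param threshold Minimum MSS; sites scoring below it are removed
#'   (default 0.85).
#' @param strands `"both"` (default), `"+"`, or `"-"`.
#' @return A data.frame with columns `matrix_id`, `tf_name`, `start`
#'   (0-based offset in `sequence`), `length`, `strand`, `mss`.
#' @export
scan_sequence <- function(pwm, sequence, threshold = 0.85,
                          strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (!methods::is(pwm, "pwm")) {
    out <- lapply(pwm, scan_sequence, sequence = sequence,
                  threshold = threshold, strands = strands)
    return(do.call(rbind, out))
  }
  L <- pwm_length(pwm)
  n <- nchar(sequence)
  res <- list()
  if (strands %in% c("both", "+")) {
    codes <- encode_dna(sequence)
    sc <- scan_one_strand(pwm, codes, threshold)
    if (length(sc$keep))
      res[["+"]] <- data.frame(
        matrix_id = pwm$matrix_id, tf_name = pwm$tf_name,
        start = sc$keep - 1L, length = L, strand = "+",
        mss = sc$score[sc$keep], stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "-")) {
    codes_rc <- encode_dna(revcomp(sequence))
    sc <- scan_one_strand(pwm, codes_rc, threshold)
    if (length(sc$keep))
      # offset j (1-based) on the revcomp covers original [n-L-j+1, n-j+1)
      res[["-"]] <- data.frame(
        matrix_id = pwm$matrix_id, tf_name = pwm$tf_name,
        start = n - L - (sc$keep - 1L), length = L, strand = "-",
        mss = sc$score[sc$keep], stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(matrix_id = character(), tf_name = character(),
                      start = integer(), length = integer(),
                      strand = character(), mss = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
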