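#' Construct a position weight matrix object
#'
#' @param matrix_id Matrix identifier (e.g. a JASPAR accession).
#' @param tf_name Transcription-factor name.
#' @param freqs 4 x L numeric matrix of per-position base frequencies, rows
#'   in A, C, G, T order; every column must sum to 1 (within 1e-9) and all
#'   entries must be strictly positive (apply a pseudocount first).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(matrix_id, tf_name, freqs) {
  freqs <- as.matrix(freqs)
  stopifnot(nrow(freqs) == 4L, ncol(freqs) >= 1L, is.numeric(freqs))
  rownames(freqs) <- DNA_BASES
  if (any(freqs <= 0))
    stop("PWM '", matrix_id, "': all frequencies must be > 0 ",
         "(apply a pseudocount)", call. = FALSE)
  if (any(abs(colSums(freqs) - 1) > 1e-9))
    stop("PWM '", matrix_id, "': column sums differ from 1", call. = FALSE)
  structure(list(matrix_id = matrix_id, tf_name = tf_name, freqs = freqs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$matrix_id, "(", x$tf_name, "), length",
      ncol(x$freqs), "\n")
  print(round(x$freqs, 3))
  invisible(x)
}

#' Motif length of a PWM
#' @param pwm A `pwm` object.
#' @return Integer motif length L.
#' @export
pwm_length <- function(pwm) ncol(pwm$freqs)

pfm_to_pwm <- function(matrix_id, tf_name, counts, pseudocount = 1e-4) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    stop("PFM '", matrix_id, "': negative counts", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("PFM '", matrix_id, "': empty column", call. = FALSE)
  # counts -> frequencies, then add the pseudocount to each frequency and
  # renormalize so that log terms in the information vector stay finite
  f <- sweep(counts, 2L, cs, "/")
  f <- (f + pseudocount) / (1 + 4 * pseudocount)
  new_pwm(matrix_id, tf_name, f)
}

#' Read transcription-factor motifs from a JASPAR PFM file
#'
#' Parses JASPAR-style PFM text: a header line `>ID name` followed by four
#' base rows, either bracketed (`A [ 4 19 0 ]`) or bare numbers. Counts are
#' converted to frequencies per column, then a pseudocount is added to each
#' frequency and the column renormalized, guaranteeing strictly positive
#' frequencies.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Frequency pseudocount; default `1e-4`.
#' @return A list of `pwm` objects, named by `matrix_id`.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 1e-4) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  starts <- grep("^>", lines)
  if (length(starts) == 0L)
    stop("no '>' header found in '", path, "'", call. = FALSE)
  pwms <- lapply(seq_along(starts), function(k) {
    i <- starts[k]
    last <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    block <- lines[(i + 1L):last]
    if (length(block) != 4L)
      stop("PFM record at line ", i, " of '", path,
           "' does not have exactly 4 base rows", call. = FALSE)
    hdr <- sub("^>\\s*", "", lines[i])
    toks <- strsplit(hdr, "\\s+")[[1]]
    matrix_id <- toks[1]
    tf_name <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else toks[1]
    rows <- lapply(block, parse_pfm_row)
    bases <- vapply(rows, `[[`, character(1), "base")
    if (all(bases %in% DNA_BASES)) {
      ord <- match(DNA_BASES, bases)
      if (anyNA(ord))
        stop("PFM '", matrix_id, "': base rows are not A/C/G/T", call. = FALSE)
      rows <- rows[ord]
    }
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1L)
      stop("PFM '", matrix_id, "': rows of unequal length", call. = FALSE)
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    pfm_to_pwm(matrix_id, tf_name, counts, pseudocount)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "matrix_id")
  pwms
}

parse_pfm_row <- function(line) {
  base <- NA_character_
  m <- regmatches(line, regexec("^([ACGTacgt])\\s*[:\\[]?", line))[[1]]
  if (length(m) == 3L && m[2] != "") base <- toupper(m[2])
  nums <- gsub("^[ACGTacgt]?\\s*\\[?|\\]\\s*$", "", line)
  counts <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
  if (anyNA(counts))
    stop("unparseable PFM row: '", line, "'", call. = FALSE)
  list(base = base, counts = counts)
}

#' Write motifs as JASPAR PFM text
#'
#' Writes integer count matrices in the bracketed JASPAR layout. Frequencies
#' are scaled by `depth` and rounded; reading the file back with
#' [read_jaspar_pfm()] recovers the frequencies up to rounding.
#'
#' @param pwms A list of `pwm` objects or of `list(matrix_id, tf_name,
#'   counts)` records with 4 x L count matrices.
#' @param path Output path.
#' @param depth Total count per column used when converting frequencies.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pwms, path, depth = 10000L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- if (!is.null(p$counts)) as.matrix(p$counts)
              else round(p$freqs * depth)
    writeLines(sprintf(">%s %s", p$matrix_id, p$tf_name), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}
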