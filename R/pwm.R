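# Position weight matrices and motif scanning. PWMs hold raw position
# frequency counts; scoring is log2 odds against a background distribution,
# with N scoring as background (zero log-odds contribution).

DNA_BASES <- c("A", "C", "G", "T")

#' Position frequency matrix constructor
#'
#' @param tf_name Transcription factor name.
#' @param counts 4 x L numeric matrix of position frequency counts; rows in
#'   A, C, G, T order (row names optional but checked if present).
#' @param pseudocount Positive pseudocount added to every cell before
#'   converting to probabilities.
#' @return Object of class `pwm`.
#' @export
pwm <- function(tf_name, counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop_usage("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop_usage("PWM must have length >= 4")
  if (any(counts < 0)) stop_usage("PWM counts must be >= 0")
  if (pseudocount <= 0) stop_usage("pseudocount must be > 0")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), DNA_BASES)) {
    stop_usage("PWM rows must be in A, C, G, T order")
  }
  rownames(counts) <- DNA_BASES
  structure(list(tf_name = tf_name, counts = counts,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d\n", x$tf_name, ncol(x$counts)))
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @export
consensus_sequence <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

pwm_log_odds <- function(x, background = rep(0.25, 4)) {
  probs <- sweep(x$counts + x$pseudocount, 2,
                 colSums(x$counts) + 4 * x$pseudocount, "/")
  log2(probs / background)
}

#' Read or write a JASPAR-format PFM motif library
#'
#' Text format: a `>identifier name` header line followed by four rows of
#' counts (A, C, G, T), with or without the bracketed JASPAR row style.
#'
#' @param path Motif file.
#' @param pseudocount Pseudocount attached to each parsed motif.
#' @return A named list of [pwm()] objects (names = TF names).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop_format("no '>' headers in motif file")
  out <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    stop_at <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    block <- lines[(h + 1):stop_at]
    if (length(block) < 4) stop_format("motif block with fewer than 4 rows")
    parts <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    tf_name <- if (length(parts) >= 2) parts[2] else parts[1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][ACGTacgt]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop_format(sprintf("ragged count rows for motif '%s'", tf_name))
    }
    out[[tf_name]] <- pwm(tf_name, do.call(rbind, rows),
                          pseudocount = pseudocount)
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pwms Named list of [pwm()] objects.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$tf_name, p$tf_name),
      vapply(seq_len(4), function(r) {
        sprintf("%s  [ %s ]", DNA_BASES[r],
                paste(format(p$counts[r, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stop_usage("sequence must be over the alphabet {A, C, G, T, N}")
  }
  match(chars, DNA_BASES)  # N -> NA
}

scan_one_strand <- function(lo, code) {
  L <- ncol(lo)
  n <- length(code)
  if (n < L) return(numeric(0))
  scores <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    contrib <- unname(lo[code[j:(j + n - L)], j])
    contrib[is.na(contrib)] <- 0  # N contributes background odds
    scores <- scores + contrib
  }
  scores
}

#' Scan a DNA sequence for PWM hits
#'
#' Scores every position on both strands with log2-odds against a background
#' distribution and reports positions whose score reaches a fraction of the
#' maximum achievable score. `N` bases score as background.
#'
#' @param x A [pwm()].
#' @param sequence DNA string over A/C/G/T/N.
#' @param score_fraction Hit threshold as a fraction of the maximum
#'   achievable log-odds score (default 0.8).
#' @param background Length-4 base probabilities (A, C, G, T).
#' @return Tibble `position` (1-based start on the forward strand), `strand`
#'   (`+`/`-`), `score`; empty if the sequence is shorter than the motif.
#' @export
scan_motifs <- function(x, sequence, score_fraction = 0.8,
                        background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pwm"))
  lo <- pwm_log_odds(x, background)
  L <- ncol(lo)
  code <- encode_dna(sequence)
  n <- length(code)
  if (n < L) {
    return(tibble(position = integer(0), strand = character(0),
                  score = numeric(0)))
  }
  max_score <- sum(apply(lo, 2, max))
  threshold <- score_fraction * max_score
  fwd <- scan_one_strand(lo, code)
  # reverse strand: scan with the reverse-complement matrix so reported
  # positions stay on the forward coordinate system
  lo_rc <- lo[4:1, L:1, drop = FALSE]
  rev_scores <- scan_one_strand(lo_rc, code)
  hits <- bind_rows(
    tibble(position = which(fwd >= threshold),
           strand = "+", score = fwd[fwd >= threshold]),
    tibble(position = which(rev_scores >= threshold),
           strand = "-", score = rev_scores[rev_scores >= threshold])
  )
  arrange(hits, .data$position, .data$strand)
}
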