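# Readers and writers for the external tabular formats the pipeline touches.
# All genomic intervals are 0-based half-open internally, matching BED.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# Parse the sample columns of a wide table as numerics, reporting the first
# offending cell by row and column; NaN and NA cells are rejected.
parse_numeric_columns <- function(tbl, path) {
  for (j in seq(2, ncol(tbl))) {
    v <- suppressWarnings(as.numeric(tbl[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop_format(sprintf(
        "non-numeric or missing value in %s at row %d, column '%s'",
        path, bad[1], names(tbl)[j]
      ))
    }
    tbl[[j]] <- v
  }
  tbl
}

#' Read a normalized expression matrix
#'
#' Reads a TSV with a header row into the package's canonical wide layout:
#' a `gene_id` column followed by one numeric column per sample. Input may
#' have genes in rows (identifier column first) or samples in rows, declared
#' via `orientation`; the result is always genes-in-rows.
#'
#' @param path Path to a TSV file with a header row.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A wide tibble: `gene_id` plus one numeric column per sample.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (ncol(tbl) < 2) stop_format("expression table needs id plus >= 1 sample column")
  tbl <- parse_numeric_columns(tbl, path)
  names(tbl)[1] <- if (orientation == "genes_in_rows") "gene_id" else "sample_id"
  check_no_duplicates(tbl[[1]], names(tbl)[1])
  check_no_duplicates(names(tbl)[-1], "column")
  if (orientation == "samples_in_rows") {
    m <- as_feature_matrix(tbl)
    tbl <- as_feature_tibble(t(m), id_name = "gene_id")
  }
  tbl
}

#' @rdname read_expression
#' @param expr Wide expression tibble as returned by [read_expression()].
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Peak set constructor
#'
#' Bundles peak intervals (0-based half-open) with a per-ATAC-sample signal
#' table keyed by `peak_id`.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param signal Wide tibble: `peak_id` plus one numeric column per ATAC
#'   sample.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(peaks, signal) {
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)))
  check_no_duplicates(peaks$peak_id, "peak")
  if (any(peaks$start >= peaks$end)) {
    bad <- peaks$peak_id[peaks$start >= peaks$end][1]
    stop_format(sprintf("peak '%s' has start >= end", bad))
  }
  if (!setequal(signal$peak_id, peaks$peak_id) ||
      nrow(signal) != nrow(peaks)) {
    stop_format("signal table must cover exactly the peaks in the interval table")
  }
  signal <- signal[match(peaks$peak_id, signal$peak_id), ]
  structure(list(peaks = as_tibble(peaks), signal = as_tibble(signal)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "<peak_set> %d peaks x %d ATAC samples\n",
    nrow(x$peaks), ncol(x$signal) - 1L
  ))
  invisible(x)
}

#' Read ATAC-seq peaks (narrowPeak/BED) with a signal matrix
#'
#' The interval file is a headerless narrowPeak (BED6+4) or any BED dialect
#' with at least chrom/start/end/name; the signal TSV has a header and is
#' keyed by peak name. Peaks absent from the signal table are dropped with a
#' warning reporting the count.
#'
#' @param path narrowPeak/BED file.
#' @param signal_path Signal TSV (header `peak_id` then sample columns).
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, signal_path) {
  raw <- read_tsv_quiet(path, col_names = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 4) stop_format("narrowPeak needs >= 4 columns (chrom/start/end/name)")
  peaks <- tibble(
    peak_id = as.character(raw[[4]]),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (any(is.na(peaks$start) | is.na(peaks$end))) {
    stop_format("non-integer start/end in narrowPeak file")
  }
  if (any(peaks$start >= peaks$end)) {
    bad <- peaks$peak_id[peaks$start >= peaks$end][1]
    stop_format(sprintf("peak '%s' has start >= end", bad))
  }
  signal <- read_tsv_quiet(signal_path,
                           col_types = readr::cols(.default = "c"))
  names(signal)[1] <- "peak_id"
  signal <- parse_numeric_columns(signal, signal_path)
  missing <- setdiff(peaks$peak_id, signal$peak_id)
  if (length(missing) > 0) {
    warn(sprintf(
      "dropping %d peak(s) without a signal row", length(missing)
    ))
    peaks <- filter(peaks, !.data$peak_id %in% missing)
  }
  signal <- filter(signal, .data$peak_id %in% peaks$peak_id)
  peak_set(peaks, signal)
}

#' Read a gene-level copy-number matrix
#'
#' @param path TSV with header: `gene_id` then one numeric column per sample.
#' @return A wide tibble, genes in rows.
#' @export
read_gene_level_cnv <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(tbl)[1] <- "gene_id"
  tbl <- parse_numeric_columns(tbl, path)
  check_no_duplicates(tbl$gene_id, "gene")
  tbl
}

#' Read a clinical survival table
#'
#' @param path TSV with columns `sample_id`, `time` (days, > 0) and `event`
#'   (0 = censored, 1 = death).
#' @return A tibble with those three columns.
#' @export
read_survival <- function(path) {
  tbl <- read_tsv_quiet(path)
  stopifnot(all(c("sample_id", "time", "event") %in% names(tbl)))
  tbl <- select(tbl, "sample_id", "time", "event")
  if (any(!is.finite(tbl$time)) || any(tbl$time <= 0)) {
    stop_format("survival time must be finite and > 0")
  }
  if (!all(tbl$event %in% c(0, 1))) stop_format("event must be 0 or 1")
  check_no_duplicates(tbl$sample_id, "sample")
  tbl
}

#' Read TF-gene interaction scores
#'
#' STRING-export style table of confidence scores in \[0, 1\] used both to
#' verify candidate regulations and to weight edges.
#'
#' @param path TSV with header columns `tf`, `target`, `score`.
#' @return Tibble `tf`, `target`, `score`.
#' @export
read_interaction_scores <- function(path) {
  tbl <- read_tsv_quiet(path)
  stopifnot(all(c("tf", "target", "score") %in% names(tbl)))
  tbl <- select(tbl, "tf", "target", "score")
  if (any(!is.finite(tbl$score)) || any(tbl$score < 0 | tbl$score > 1)) {
    stop_format("interaction scores must lie in [0, 1]")
  }
  check_no_duplicates(paste(tbl$tf, tbl$target, sep = "\r"), "tf-target pair")
  tbl
}

#' Read curated immune gene lists
#'
#' @param ir_path TSV with a `gene_id` column: the immune-related candidates.
#' @param cycle_path Optional TSV `gene_id`, `step` mapping signature genes
#'   to the seven steps of the cancer-immunity cycle.
#' @param class_path Optional TSV `gene_id`, `class` with class
#'   `stimulatory` or `inhibitory`.
#' @return List with `ir_genes` (character), `cycle_steps`, `classes`.
#' @export
read_gene_lists <- function(ir_path, cycle_path = NULL, class_path = NULL) {
  ir <- read_tsv_quiet(ir_path)
  stopifnot("gene_id" %in% names(ir))
  out <- list(
    ir_genes = unique(as.character(ir$gene_id)),
    cycle_steps = NULL, classes = NULL
  )
  if (!is.null(cycle_path)) {
    cyc <- read_tsv_quiet(cycle_path)
    stopifnot(all(c("gene_id", "step") %in% names(cyc)))
    if (!all(cyc$step %in% 1:7)) {
      stop_format("immune cycle steps must be integers in 1..7")
    }
    out$cycle_steps <- select(cyc, "gene_id", "step")
  }
  if (!is.null(class_path)) {
    cls <- read_tsv_quiet(class_path)
    stopifnot(all(c("gene_id", "class") %in% names(cls)))
    if (!all(cls$class %in% c("stimulatory", "inhibitory"))) {
      stop_format("regulator class must be 'stimulatory' or 'inhibitory'")
    }
    out$classes <- select(cls, "gene_id", "class")
  }
  out
}

#' Read gene annotation with TSS coordinates
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @return Tibble with those columns.
#' @export
read_gene_annotation <- function(path) {
  tbl <- read_tsv_quiet(path)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tbl)))
  if (any(tbl$tss < 0)) stop_format("tss must be >= 0")
  if (!all(tbl$strand %in% c("+", "-"))) stop_format("strand must be '+' or '-'")
  check_no_duplicates(tbl$gene_id, "gene")
  select(tbl, "gene_id", "chrom", "tss", "strand")
}

#' Read or write peak DNA sequences (FASTA)
#'
#' @param path FASTA file; record names are peak ids.
#' @return Tibble `peak_id`, `seq`.
#' @export
read_peak_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(peak_id = names(x), seq = unname(as.character(x)))
}

#' @rdname read_peak_sequences
#' @param seqs Tibble `peak_id`, `seq`.
#' @export
write_peak_sequences <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$peak_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a regulatory edge list
#'
#' Writes edges as a TSV (columns `scope`, `tf`, `target`, `sign`, `weight`,
#' `p_value`, `evidence`) or as GraphML. Duplicate (scope, tf, target) keys
#' are collapsed keeping the maximum weight; rows are ordered by scope, then
#' target, then TF, so output is deterministic.
#'
#' @param edges Edge tibble as produced by the network builders.
#' @param path Output file.
#' @param format `"tsv_edge_list"` or `"graphml"`.
#' @export
write_network <- function(edges, path, format = c("tsv_edge_list", "graphml")) {
  if (!format[1] %in% c("tsv_edge_list", "graphml")) {
    stop_usage(sprintf("unknown network format '%s'", format[1]))
  }
  format <- match.arg(format)
  cols <- c("scope", "tf", "target", "sign", "weight", "p_value", "evidence")
  for (cl in setdiff(cols, names(edges))) {
    edges[[cl]] <- if (cl == "weight") numeric(nrow(edges)) else NA
  }
  edges <- edges |>
    select(dplyr::all_of(cols)) |>
    group_by(.data$scope, .data$tf, .data$target) |>
    slice_max(.data$weight, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$scope, .data$target, .data$tf)
  if (format == "tsv_edge_list") {
    readr::write_tsv(edges, path)
  } else {
    g <- igraph::graph_from_data_frame(
      select(edges, "tf", "target", "scope", "sign", "weight", "p_value",
             "evidence"),
      directed = TRUE
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  read_tsv_quiet(path)
}
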