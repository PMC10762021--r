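#' Write a per-exon call set to a TSV file
#'
#' Columns: `chrom`, `start`, `end`, `call` (DEL/DUP/NOCALL), `p_del`,
#' `p_dup`, `p_nocall`, `imputed`. Imputed records (3-nearest-neighbour
#' votes) carry `NA` probabilities.
#'
#' @param calls A call tibble as produced by [call_exons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_file <- function(calls, path) {
  cols <- intersect(c("chrom", "chrom_index", "start", "end", "id", "call",
                      "p_del", "p_dup", "p_nocall", "imputed"), names(calls))
  readr::write_tsv(calls[cols], path, progress = FALSE)
  invisible(path)
}

#' Read a per-exon call set written by [write_call_file()]
#'
#' Round-trips the records exactly. Unknown call tokens are an error naming
#' the offending token; an empty file yields an empty call set.
#'
#' @param path Path to the TSV file.
#' @return A call tibble.
#' @export
read_call_file <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), chrom_index = integer(),
                          start = numeric(), end = numeric(), id = character(),
                          call = character(), p_del = numeric(),
                          p_dup = numeric(), p_nocall = numeric(),
                          imputed = logical()))
  }
  call_to_code(df$call)  # validates tokens
  df
}

#' Read a truth/semi-truth CNV call set (BED-like)
#'
#' Accepts `chrom start end class` rows where the class column is either a
#' DEL/DUP (or NOCALL) token or an integer copy number. Integer copy numbers
#' are discretized by [discretize_copy_number()] (the convention used to
#' compare exact-copy-number callers): >2 duplication, <2 deletion,
#' =2 no-call; the raw copy number is kept in column `cn`.
#'
#' @param path Path to the BED-like file, or a character vector of lines.
#' @return A tibble `chrom, chrom_index, start, end, call` (plus `cn` when
#'   the input used integer copy numbers), sorted by `(chrom_index, start)`,
#'   NOCALL rows dropped (absence of a call means no-call).
#' @export
read_truth_calls <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), chrom_index = integer(),
                          start = numeric(), end = numeric(), call = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("truth line ", which(lengths(fields) < 4L)[1L],
         ": need chrom, start, end and a call/copy-number column",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  cls <- vapply(fields, `[[`, character(1), 4L)
  out <- tibble::tibble(chrom = chrom,
                        chrom_index = chrom_name_to_index(chrom),
                        start = start, end = end)
  if (all(grepl("^[0-9]+$", cls))) {
    out$cn <- as.integer(cls)
    out$call <- discretize_copy_number(out$cn)
  } else {
    call_to_code(cls)  # validates; errors name the token
    out$call <- cls
  }
  out <- out[!is.na(out$chrom_index) & out$call != "NOCALL", ]
  dplyr::arrange(out, .data$chrom_index, .data$start)
}

#' Discretize integer copy numbers into DEL/DUP/NOCALL
#'
#' The comparison convention for callers that report exact copy numbers:
#' a predicted copy number above 2 is a duplication, below 2 a deletion and
#' exactly 2 (the diploid expectation) a no-call.
#'
#' @param cn Integer vector of copy numbers (>= 0).
#' @return Character vector of DEL/DUP/NOCALL.
#' @export
#' @examples
#' discretize_copy_number(c(0, 1, 2, 3, 4))
discretize_copy_number <- function(cn) {
  if (any(cn < 0)) stop("negative copy number", call. = FALSE)
  dplyr::case_when(cn > 2 ~ "DUP", cn < 2 ~ "DEL", TRUE ~ "NOCALL")
}

#' Write merged CNV segments as BED with a call column
#'
#' @param segments Segment tibble from [merge_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_file <- function(segments, path) {
  readr::write_tsv(segments, path, progress = FALSE)
  invisible(path)
}
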