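#' Read exon capture targets from a BED file
#'
#' Parses a 3+ column BED file of exon target intervals into a tibble sorted
#' by `(chrom_index, start)`. Chromosome names `chr1`..`chr22`, `chrX`, `chrY`
#' (with or without the `chr` prefix) are mapped to integer indices 1..24,
#' with X = 23 and Y = 24 — the chromosome vocabulary of the classification
#' token matrix. Records on any other contig (e.g. `chrM`, alt or decoy
#' contigs) are skipped with a message, because the model defines no token
#' for them.
#'
#' @param path Path to a BED file (tab-separated, no header), or a character
#'   vector of BED lines. Coordinates are kept 0-based half-open as in BED.
#' @param id_prefix Prefix used to build identifiers when the BED has no
#'   name column.
#' @return A tibble with columns `chrom` (original name), `chrom_index`
#'   (integer 1..24), `start`, `end` (0-based half-open) and `id`, sorted by
#'   `(chrom_index, start)`. The number of skipped records is attached as
#'   attribute `"skipped"`.
#' @export
#' @examples
#' bed <- c("chr1\t100\t250\te1", "chrX\t10\t20\te2")
#' read_exon_targets(bed)
read_exon_targets <- function(path, id_prefix = "exon") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(structure(empty_targets(), skipped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    stop("malformed BED line ", which(n_fields < 3L)[1L],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         ": non-numeric coordinates", call. = FALSE)
  }
  if (any(start >= end)) {
    stop("malformed BED line ", which(start >= end)[1L],
         ": start must be < end", call. = FALSE)
  }
  id <- ifelse(n_fields >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                      character(1)),
               paste0(id_prefix, "_", seq_along(fields)))
  chrom_index <- chrom_name_to_index(chrom)
  keep <- !is.na(chrom_index)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " target(s) on unrecognised contigs skipped (",
            paste(unique(chrom[!keep]), collapse = ", "), ")")
  }
  out <- tibble::tibble(
    chrom = chrom[keep],
    chrom_index = chrom_index[keep],
    start = start[keep],
    end = end[keep],
    id = id[keep]
  ) |>
    dplyr::arrange(.data$chrom_index, .data$start)
  structure(out, skipped = n_skipped)
}

empty_targets <- function() {
  tibble::tibble(chrom = character(), chrom_index = integer(),
                 start = numeric(), end = numeric(), id = character())
}

#' Map chromosome names to model indices
#'
#' `1`..`22` map to themselves, `X` to 23 and `Y` to 24; a `chr` prefix is
#' accepted. Anything else maps to `NA`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Integer vector of the same length, `NA` for unknown contigs.
#' @export
chrom_name_to_index <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  idx <- match(stripped, c(as.character(1:22), "X", "Y"))
  as.integer(idx)
}

# validate a targets tibble (shared precondition of downstream ops)
check_targets <- function(targets) {
  stopifnot(is.data.frame(targets),
            all(c("chrom_index", "start", "end", "id") %in% names(targets)))
  if (nrow(targets) > 0) {
    stopifnot(all(targets$start < targets$end),
              all(targets$chrom_index >= 1L & targets$chrom_index <= 24L))
  }
  invisible(targets)
}
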