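#' Read a per-base depth table
#'
#' Reads the tab-separated output of a depth tool run over a BAM: one row per
#' covered base with columns chromosome, 1-based position and read depth.
#' Bases absent from the table are treated as depth 0 downstream.
#'
#' @param path Path to a TSV file with three columns (no header expected;
#'   a `chrom/pos/depth`-style header line is tolerated).
#' @return A tibble with columns `chrom`, `pos` (1-based) and `depth`.
#' @export
read_depth_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                        col_types = "cdd", progress = FALSE,
                        show_col_types = FALSE)
  # tolerate a header row
  if (nrow(df) > 0 && is.na(df$pos[1]) && is.na(df$depth[1])) {
    df <- df[-1, ]
    df$pos <- as.numeric(df$pos)
    df$depth <- as.numeric(df$depth)
  }
  if (any(df$depth < 0, na.rm = TRUE)) {
    stop("negative depth value in depth table", call. = FALSE)
  }
  df
}

#' Extract raw per-base depth vectors for each exon target
#'
#' Maps the sparse per-base depth table onto each target interval: the result
#' for a target `[start, end)` is a vector of length `end - start` holding the
#' depth at each base, 0 where the table has no row. Table positions are
#' 1-based (the usual depth-tool dialect) and target coordinates 0-based
#' half-open, so table position `p` lands in slot `p - start` of its target.
#' Targets whose whole vector is zero are flagged `no_depth`; they get no
#' model input and are later resolved by the 3-nearest-neighbour vote.
#'
#' @param depth A depth tibble as from [read_depth_table()].
#' @param targets A targets tibble as from [read_exon_targets()].
#' @return The targets tibble with list-column `depth` (numeric vector per
#'   exon) and logical column `no_depth`.
#' @export
extract_depth_vectors <- function(depth, targets) {
  check_targets(targets)
  if (any(depth$depth < 0, na.rm = TRUE)) {
    stop("negative depth value in depth table", call. = FALSE)
  }
  depth <- dplyr::mutate(depth, chrom_index = chrom_name_to_index(.data$chrom))
  by_chrom <- split(depth, depth$chrom_index)
  vecs <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    s <- targets$start[i]; e <- targets$end[i]
    v <- numeric(e - s)
    d <- by_chrom[[as.character(targets$chrom_index[i])]]
    if (!is.null(d)) {
      # 1-based table position p covers 0-based base p-1
      hit <- d$pos > s & d$pos <= e
      if (any(hit)) v[d$pos[hit] - s] <- d$depth[hit]
    }
    vecs[[i]] <- v
  }
  targets$depth <- vecs
  targets$no_depth <- vapply(vecs, function(v) all(v == 0), logical(1))
  targets
}

#' Global read-depth standardization statistics
#'
#' Computes the global mean and standard deviation of per-base read depth over
#' a set of extracted depth vectors (the training corpus). Zero-depth bases
#' inside covered exons are included; exons flagged `no_depth` contribute
#' nothing. These statistics are persisted with a trained model and reused
#' verbatim at inference.
#'
#' @param depth_vectors A tibble from [extract_depth_vectors()], or a list of
#'   numeric vectors.
#' @return A list with elements `mean` and `sd` (`sd` > 0 enforced).
#' @export
depth_stats <- function(depth_vectors) {
  vecs <- if (is.data.frame(depth_vectors)) {
    depth_vectors$depth[!depth_vectors$no_depth]
  } else depth_vectors
  all_depth <- unlist(vecs, use.names = FALSE)
  if (length(all_depth) < 2) stop("need at least 2 depth values", call. = FALSE)
  s <- stats::sd(all_depth)
  if (!is.finite(s) || s <= 0) stop("depth standard deviation must be > 0",
                                    call. = FALSE)
  list(mean = mean(all_depth), sd = s)
}

#' Standardize and left-pad one raw depth vector
#'
#' Each per-base value `v` becomes `(v - mean) / sd` using the global training
#' statistics; the standardized vector is then left-padded with the sentinel
#' -1 to `max_len`, with a logical mask marking real positions (the padding
#' sentinel is a marker, not a depth: padded positions are excluded from
#' attention, so its numeric value never reaches the model). Vectors longer
#' than `max_len` fall back to their nonzero-depth positions in genomic
#' order; if those still number >= `max_len` the exon cannot be encoded and
#' `NULL` is returned (callers flag it `no_depth` and resolve it by the
#' 3-nearest-neighbour vote).
#'
#' @param raw Numeric vector of raw per-base depths (length >= 1).
#' @param stats List with `mean` and `sd` as from [depth_stats()].
#' @param max_len Maximum encoded length (default 1000).
#' @return A list with `depth` (length `max_len`), `mask` (logical,
#'   `max_len`), `n_real`, and `keep_idx` (indices of the raw positions that
#'   were encoded), or `NULL` when the exon cannot be encoded.
#' @export
standardize_and_pad <- function(raw, stats, max_len = 1000L) {
  if (length(raw) == 0) stop("empty depth vector", call. = FALSE)
  if (stats$sd <= 0) stop("stats$sd must be > 0", call. = FALSE)
  keep_idx <- seq_along(raw)
  if (length(raw) > max_len) {
    keep_idx <- which(raw != 0)
    if (length(keep_idx) == 0 || length(keep_idx) >= max_len) return(NULL)
  }
  std <- (raw[keep_idx] - stats$mean) / stats$sd
  n_real <- length(std)
  depth <- c(rep(-1, max_len - n_real), std)
  mask <- c(rep(FALSE, max_len - n_real), rep(TRUE, n_real))
  list(depth = depth, mask = mask, n_real = n_real, keep_idx = keep_idx)
}

#' Encode extracted depth vectors into model inputs
#'
#' Applies [standardize_and_pad()] to every exon with depth, producing the
#' standardized, left-padded, masked per-exon vectors the classifier
#' consumes. Exons flagged `no_depth` — and over-long exons whose nonzero
#' positions do not fit `max_len` — are carried through with `no_depth =
#' TRUE` and empty encodings.
#'
#' @param depth_vectors Tibble from [extract_depth_vectors()].
#' @param stats Standardization statistics from [depth_stats()] (for
#'   inference, the statistics stored in the trained model).
#' @param max_len Maximum encoded length.
#' @return The input tibble with list-columns `depth` (standardized padded
#'   vector), `mask`, integer `n_real` and updated `no_depth`; the `stats`
#'   used are attached as attribute `"stats"` and `max_len` as `"max_len"`.
#' @export
encode_exons <- function(depth_vectors, stats, max_len = 1000L) {
  enc <- purrr::map(seq_len(nrow(depth_vectors)), function(i) {
    if (depth_vectors$no_depth[i]) return(NULL)
    standardize_and_pad(depth_vectors$depth[[i]], stats, max_len)
  })
  out <- depth_vectors
  out$depth <- purrr::map(enc, function(e) if (is.null(e)) numeric(0) else e$depth)
  out$mask <- purrr::map(enc, function(e) if (is.null(e)) logical(0) else e$mask)
  out$n_real <- vapply(enc, function(e) if (is.null(e)) 0L else e$n_real,
                       integer(1))
  out$keep_idx <- purrr::map(enc, function(e) if (is.null(e)) integer(0) else e$keep_idx)
  out$no_depth <- vapply(enc, is.null, logical(1))
  attr(out, "stats") <- stats
  attr(out, "max_len") <- as.integer(max_len)
  out
}
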