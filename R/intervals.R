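# Interval arithmetic shared by label assignment, segment intersection and
# consensus labelling. All coordinates are 0-based half-open; overlaps are
# counted in bases. These are the semantics the brute-force per-base oracles
# in the test suite recount.

# union of possibly-overlapping intervals, per (chrom_index, call)
union_intervals <- function(calls) {
  if (nrow(calls) == 0) return(calls[c("chrom_index", "start", "end", "call")])
  calls |>
    dplyr::arrange(.data$chrom_index, .data$call, .data$start) |>
    dplyr::group_by(.data$chrom_index, .data$call) |>
    dplyr::group_modify(function(df, key) {
      s <- df$start; e <- df$end
      grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
      tibble::tibble(start = tapply(s, grp, min)[unique(grp)],
                     end = tapply(e, grp, max)[unique(grp)])
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom_index", "start", "end", "call")
}

# majority-base call for each query interval against a DEL/DUP call set:
# the class covering the most bases of the query wins; no overlap or an
# exact tie in covered bases yields NOCALL (the conservative tie rule).
overlap_majority <- function(queries, calls, tie_log = FALSE) {
  stopifnot(all(c("chrom_index", "start", "end") %in% names(queries)))
  qid <- seq_len(nrow(queries))
  out <- rep("NOCALL", nrow(queries))
  ties <- 0L
  if (nrow(calls) > 0 && nrow(queries) > 0) {
    calls <- union_intervals(calls[calls$call != "NOCALL", , drop = FALSE])
    cover <- dplyr::inner_join(
      dplyr::mutate(queries[c("chrom_index", "start", "end")], .q = qid),
      calls, by = "chrom_index", suffix = c("", ".c"),
      relationship = "many-to-many") |>
      dplyr::mutate(bases = pmin(.data$end, .data$end.c) -
                      pmax(.data$start, .data$start.c)) |>
      dplyr::filter(.data$bases > 0) |>
      dplyr::group_by(.data$.q, .data$call) |>
      dplyr::summarise(bases = sum(.data$bases), .groups = "drop")
    if (nrow(cover) > 0) {
      ov <- cover |>
        dplyr::group_by(.data$.q) |>
        dplyr::summarise(
          tie = dplyr::n() > 1 && sum(.data$bases == max(.data$bases)) > 1,
          call = if (tie) "NOCALL" else .data$call[which.max(.data$bases)],
          .groups = "drop")
      out[ov$.q] <- ov$call
      ties <- sum(ov$tie)
    }
  }
  if (tie_log && ties > 0) {
    message(ties, " interval(s) with exactly tied conflicting coverage -> NOCALL")
  }
  out
}
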