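#' Score merged CNV segments against an interval truth set
#'
#' Evaluation at merged-segment resolution: per-exon calls are merged into
#' segments, each predicted segment receives the consensus label of the
#' truth calls it covers (majority bases, tie or no overlap NOCALL), and
#' precision per class is the fraction of predicted segments of that class
#' whose consensus label agrees. Recall per class takes each truth interval
#' as the unit and asks whether the predicted segments covering it give it
#' back as its majority label. Overall values aggregate with the same macro
#' rules as the exon-level suite; NPA/NPV are undefined at this resolution
#' (there is no finite no-call universe) and reported as `NA`.
#'
#' @param calls Per-exon call tibble (as from [call_exons()] /
#'   [impute_no_depth_calls()]).
#' @param truth Truth call tibble (`chrom_index`, `start`, `end`, `call`).
#' @param gap_cap Optional merge gap cap forwarded to [merge_segments()].
#' @return A `cnv_metrics` object over segment units.
#' @export
segment_metrics <- function(calls, truth, gap_cap = NULL) {
  segs <- merge_segments(calls, gap_cap = gap_cap)
  segs <- consensus_truth_for_segment(segs, truth)
  truth_back <- truth
  truth_back$recovered <- overlap_majority(
    truth, dplyr::rename(segs, call = "call")[c("chrom_index", "start",
                                                "end", "call")])
  confusion <- purrr::map_dfr(c("DEL", "DUP"), function(cls) {
    tibble::tibble(
      class = cls,
      tp = sum(segs$call == cls & segs$truth_label == cls),
      fp = sum(segs$call == cls & segs$truth_label != cls),
      fn = sum(truth_back$call == cls & truth_back$recovered != cls),
      tn = NA_integer_,
      truth_total = sum(truth_back$call == cls))
  })
  per_class <- confusion |>
    dplyr::mutate(
      precision = safe_div(.data$tp, .data$tp + .data$fp, "precision"),
      recall = safe_div(.data$truth_total - .data$fn, .data$truth_total,
                        "recall"),
      f1 = harmonic_mean(.data$precision, .data$recall),
      npa = NA_real_, npv = NA_real_) |>
    dplyr::select("class", "precision", "recall", "f1", "npa", "npv")
  overall <- aggregate_metrics(per_class)
  structure(list(confusion = confusion, per_class = per_class,
                 overall = overall, n_exons = nrow(segs)),
            class = "cnv_metrics")
}
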