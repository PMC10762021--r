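#' Project segment calls onto exon targets
#'
#' Brings segment-level call sets (merged bins, CNV segments, integer-CN
#' regions already discretized) to the fixed per-exon evaluation unit: an
#' exon overlapping a segment by at least one base takes that segment's
#' call; an exon overlapping segments of different classes takes the class
#' covering the most of its bases, with an exact tie resolved to NOCALL; an
#' exon in a gap is NOCALL.
#'
#' @param segments Segment tibble with `chrom_index`, `start`, `end`, `call`
#'   (non-overlapping per chromosome within a class; overlapping same-class
#'   segments are merged silently, different-class overlaps are logged via
#'   the tie message when they tie on a target).
#' @param targets Targets tibble.
#' @return `targets` with a per-exon `call` column.
#' @export
intersect_segments_to_exons <- function(segments, targets) {
  check_targets(targets)
  targets$call <- overlap_majority(targets, segments, tie_log = TRUE)
  targets
}

#' Consensus truth label for merged call segments
#'
#' A merged exome segment can span several shorter truth calls; the segment
#' is compared against the consensus of what it covers: the truth class
#' covering the most bases of the segment wins, no overlap or an exact base
#' tie gives NOCALL.
#'
#' @param segments Segment tibble from [merge_segments()].
#' @param truth Truth call tibble (`chrom_index`, `start`, `end`, `call`),
#'   sorted.
#' @return `segments` with a `truth_label` column.
#' @export
consensus_truth_for_segment <- function(segments, truth) {
  segments$truth_label <- overlap_majority(segments, truth)
  segments
}

#' Score a call set against truth at exon resolution
#'
#' Builds the per-class confusion table over a shared exon universe and the
#' macro-averaged metric suite: per-class precision (`TP/(TP+FP)`), recall
#' with the truth totals as denominators (`TP/T`), F1 as their harmonic
#' mean; overall precision and recall as the unweighted DEL/DUP means and
#' overall F1 as the harmonic mean of overall precision and overall recall;
#' per-class and macro NPA (specificity, `TN/(TN+FP)`) and NPV
#' (`TN/(TN+FN)`), with true negatives being the exons for which neither
#' side makes that call. Empty denominators yield 0 with a warning so
#' reports stay comparable.
#'
#' @param predicted Tibble with `id` and `call` (per-exon predictions).
#' @param truth Tibble with `id` and `label` (or `call`) — per-exon truth.
#' @return A `cnv_metrics` object: `$confusion` (per-class counts),
#'   `$per_class`, `$overall`, `$n_exons`.
#' @export
compute_metrics <- function(predicted, truth) {
  truth_lab <- if ("label" %in% names(truth)) truth$label else truth$call
  missing_in_truth <- setdiff(predicted$id, truth$id)
  missing_in_pred <- setdiff(truth$id, predicted$id)
  if (length(missing_in_truth) || length(missing_in_pred)) {
    stop("prediction/truth exon universes differ; missing: ",
         paste(utils::head(c(missing_in_truth, missing_in_pred), 5),
               collapse = ", "), call. = FALSE)
  }
  m <- match(predicted$id, truth$id)
  pred <- predicted$call
  tru <- truth_lab[m]
  confusion <- purrr::map_dfr(c("DEL", "DUP"), function(cls) {
    tibble::tibble(
      class = cls,
      tp = sum(pred == cls & tru == cls),
      fp = sum(pred == cls & tru != cls),
      fn = sum(pred != cls & tru == cls),
      tn = sum(pred != cls & tru != cls),
      truth_total = sum(tru == cls))
  })
  per_class <- confusion |>
    dplyr::mutate(
      precision = safe_div(.data$tp, .data$tp + .data$fp, "precision"),
      recall = safe_div(.data$tp, .data$truth_total, "recall"),
      f1 = harmonic_mean(.data$precision, .data$recall),
      npa = safe_div(.data$tn, .data$tn + .data$fp, "NPA"),
      npv = safe_div(.data$tn, .data$tn + .data$fn, "NPV")) |>
    dplyr::select("class", "precision", "recall", "f1", "npa", "npv")
  overall <- aggregate_metrics(per_class)
  structure(list(confusion = confusion, per_class = per_class,
                 overall = overall, n_exons = length(pred)),
            class = "cnv_metrics")
}

safe_div <- function(num, den, what) {
  out <- num / den
  if (any(den == 0)) {
    warning("empty denominator in ", what, "; reporting 0", call. = FALSE)
    out[den == 0] <- 0
  }
  out
}

harmonic_mean <- function(a, b) ifelse(a + b == 0, 0, 2 * a * b / (a + b))

#' Aggregate per-class precision/recall into the overall metric suite
#'
#' The macro-averaging rules of the exon-level benchmark: overall precision
#' and recall are the unweighted means of the DEL and DUP values; each
#' class's F1 is the harmonic mean of its own precision and recall; the
#' overall F1 is the harmonic mean of the overall precision and overall
#' recall (not the mean of per-class F1 scores). NPA/NPV aggregate the same
#' way when present.
#'
#' @param per_class Tibble with `class` (`"DEL"`, `"DUP"`), `precision` and
#'   `recall` (optionally `npa`, `npv`), e.g. per-class values as printed in
#'   a benchmark table.
#' @return Named list `precision`, `recall`, `f1`, `del_f1`, `dup_f1` (plus
#'   `npa`, `npv` when supplied).
#' @export
#' @examples
#' aggregate_metrics(tibble::tibble(class = c("DEL", "DUP"),
#'                                  precision = c(0.834, 0.679),
#'                                  recall = c(0.541, 0.500)))
aggregate_metrics <- function(per_class) {
  stopifnot(all(c("DEL", "DUP") %in% per_class$class))
  del <- per_class[per_class$class == "DEL", ]
  dup <- per_class[per_class$class == "DUP", ]
  out <- list(
    precision = (del$precision + dup$precision) / 2,
    recall = (del$recall + dup$recall) / 2,
    del_f1 = harmonic_mean(del$precision, del$recall),
    dup_f1 = harmonic_mean(dup$precision, dup$recall))
  out$f1 <- harmonic_mean(out$precision, out$recall)
  if (all(c("npa", "npv") %in% names(per_class))) {
    out$npa <- (del$npa + dup$npa) / 2
    out$npv <- (del$npv + dup$npv) / 2
  }
  out
}

#' @export
print.cnv_metrics <- function(x, ...) {
  cat(sprintf("<cnv_metrics> %d exons\n", x$n_exons))
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 3)
  cat(sprintf("overall: precision %.3f, recall %.3f, F1 %.3f, NPA %.3f, NPV %.3f\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$npa, x$overall$npv))
  invisible(x)
}

#' @describeIn compute_metrics Per-class metrics as a tibble.
#' @param x A `cnv_metrics` object.
#' @param ... Unused.
#' @export
tidy.cnv_metrics <- function(x, ...) x$per_class

#' @describeIn compute_metrics One-row tibble of the overall (macro) metrics.
#' @export
glance.cnv_metrics <- function(x, ...) {
  tibble::as_tibble(x$overall[c("precision", "recall", "f1", "del_f1",
                                "dup_f1", "npa", "npv")])
}

#' Macro F1 over the DEL and DUP classes
#'
#' Convenience accessor used as the principal summary of label-recovery
#' experiments: the unweighted mean of the DEL F1 and DUP F1 scores.
#'
#' @param metrics A `cnv_metrics` object.
#' @return A single number in \[0, 1\].
#' @export
macro_f1 <- function(metrics) {
  (metrics$overall$del_f1 + metrics$overall$dup_f1) / 2
}
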