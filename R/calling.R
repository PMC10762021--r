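#' Call CNVs for every encodable exon of a sample
#'
#' Runs the classifier over an encoded exon set and returns one call record
#' per encodable exon with its class pseudo-probabilities. The encoding must
#' have been produced with the model's own standardization statistics
#' (checked by hash); exons flagged `no_depth` are left out and can be
#' resolved afterwards with [impute_no_depth_calls()].
#'
#' @param model A trained `cnv_model`.
#' @param encoded Encoded exon tibble from [encode_exons()].
#' @param min_call_prob Optional confidence gate passed to [predict_label()].
#' @return A call tibble sorted by `(chrom_index, start)`: target columns
#'   plus `call`, `p_del`, `p_dup`, `p_nocall`, `imputed = FALSE`.
#' @export
call_exons <- function(model, encoded, min_call_prob = NULL) {
  enc_stats <- attr(encoded, "stats")
  if (!is.null(enc_stats) &&
      !identical(rlang::hash(enc_stats[c("mean", "sd")]),
                 rlang::hash(model$stats[c("mean", "sd")]))) {
    stop("encoding standardization statistics do not match the model's ",
         "(re-encode with the model's stats)", call. = FALSE)
  }
  probs <- predict_proba(model, encoded)
  keep <- encoded[!encoded$no_depth,
                  intersect(c("chrom", "chrom_index", "start", "end", "id"),
                            names(encoded))]
  out <- dplyr::bind_cols(keep, probs[c("p_del", "p_dup", "p_nocall")])
  out$call <- predict_label(out$p_del, out$p_dup, out$p_nocall, min_call_prob)
  out$imputed <- FALSE
  dplyr::arrange(out, .data$chrom_index, .data$start)
}

#' Impute calls for exons without read depth by 3-nearest-neighbour vote
#'
#' Roughly a fifth of capture targets carry no read depth in a typical
#' exome; each such exon receives the majority call among the 3 genomically
#' nearest model-called exons on the same chromosome (distance between
#' interval midpoints; distance ties broken toward the lower start
#' coordinate). A 2-of-3 or 3-of-3 majority wins; a 1/1/1 split resolves to
#' NOCALL. Chromosomes with fewer than 3 called exons vote among what is
#' available, ties again NOCALL. Only model calls vote — never other imputed
#' records — so existing records are not altered.
#'
#' @param calls Call tibble from [call_exons()] (sorted).
#' @param no_depth_targets Targets tibble rows for the depth-less exons.
#' @return The augmented call tibble, sorted, imputed records carrying
#'   `imputed = TRUE` and `NA` probabilities.
#' @export
impute_no_depth_calls <- function(calls, no_depth_targets) {
  if (nrow(no_depth_targets) == 0) return(calls)
  voted <- vapply(seq_len(nrow(no_depth_targets)), function(i) {
    chrom <- no_depth_targets$chrom_index[i]
    mid <- (no_depth_targets$start[i] + no_depth_targets$end[i]) / 2
    cand <- calls[calls$chrom_index == chrom, ]
    if (nrow(cand) == 0) return("NOCALL")
    d <- abs((cand$start + cand$end) / 2 - mid)
    ord <- order(d, cand$start)
    nn <- cand$call[ord[seq_len(min(3L, nrow(cand)))]]
    majority_vote(nn)
  }, character(1))
  imputed <- no_depth_targets[intersect(c("chrom", "chrom_index", "start",
                                          "end", "id"),
                                        names(no_depth_targets))]
  imputed$p_del <- NA_real_
  imputed$p_dup <- NA_real_
  imputed$p_nocall <- NA_real_
  imputed$call <- voted
  imputed$imputed <- TRUE
  dplyr::bind_rows(calls, imputed) |>
    dplyr::arrange(.data$chrom_index, .data$start)
}

# strict-majority vote over DEL/DUP/NOCALL labels; any tie -> NOCALL
majority_vote <- function(labels) {
  tab <- table(factor(labels, levels = CALL_LEVELS))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1L) "NOCALL" else winners
}

#' Merge consecutive same-call exons into CNV segments
#'
#' Maximal runs of consecutive exons (in sorted target order on one
#' chromosome) sharing the same DEL or DUP call become one segment spanning
#' from the first exon's start to the last exon's end. NOCALL exons break
#' runs and emit nothing. With `gap_cap` set, a genomic gap larger than
#' `gap_cap` bases between consecutive exons also breaks the run.
#'
#' @param calls Call tibble sorted by `(chrom_index, start)`.
#' @param gap_cap Optional maximum gap (bases) bridged within one segment.
#' @return A tibble `chrom_index, start, end, call, n_exons`, sorted and
#'   non-overlapping per chromosome.
#' @export
merge_segments <- function(calls, gap_cap = NULL) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(chrom_index = integer(), start = numeric(),
                          end = numeric(), call = character(),
                          n_exons = integer()))
  }
  if (!identical(order(calls$chrom_index, calls$start),
                 seq_len(nrow(calls)))) {
    stop("call records must be sorted by (chrom_index, start)", call. = FALSE)
  }
  new_run <- c(TRUE, calls$call[-1] != calls$call[-nrow(calls)] |
                 calls$chrom_index[-1] != calls$chrom_index[-nrow(calls)])
  if (!is.null(gap_cap)) {
    gap <- c(0, calls$start[-1] - calls$end[-nrow(calls)])
    new_run <- new_run | gap > gap_cap
  }
  calls$run <- cumsum(new_run)
  calls |>
    dplyr::filter(.data$call %in% c("DEL", "DUP")) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom_index = .data$chrom_index[1],
                     start = min(.data$start), end = max(.data$end),
                     call = .data$call[1], n_exons = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom_index, .data$start) |>
    dplyr::select(-"run")
}
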