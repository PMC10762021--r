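#' Per-base relevance map for one exon call
#'
#' Gradient-weighted attention relevance (the generic attention
#' explainability construction for softmax attention): within each encoder
#' block the post-softmax attention maps are weighted by their gradients
#' with respect to the target-class score, negative parts clipped, averaged
#' over heads (gradient weighting rather than a plain head average, which
#' produces noisy maps), and accumulated multiplicatively across blocks with
#' the identity added; the classification-token row then scores every depth
#' position. Padded positions score exactly 0 and the map is max-normalised
#' to \[0, 1\] over the real positions.
#'
#' @param model A trained `cnv_model`.
#' @param encoded_exon One row of an encoded exon tibble (with `no_depth ==
#'   FALSE`).
#' @param target_class Class the relevance is computed for (`"DEL"`,
#'   `"DUP"`, `"NOCALL"`); defaults to the model's own prediction.
#' @param from_block First encoder block whose attention enters the
#'   accumulation (1 = all blocks; `model$config$L` = last block only).
#' @return A `cnv_relevance` tibble with one row per encoded position:
#'   `position` (1..max_len in the padded layout), `mask`, `depth`
#'   (standardized), `score`. The predicted call, target class and a
#'   `degenerate` flag (all-zero map) are attached as attributes.
#' @export
relevance_map <- function(model, encoded_exon, target_class = NULL,
                          from_block = 1L) {
  stopifnot(nrow(encoded_exon) == 1L, !encoded_exon$no_depth)
  probs <- predict_proba(model, encoded_exon)
  predicted <- predict_label(probs$p_del, probs$p_dup, probs$p_nocall)
  if (is.null(target_class)) target_class <- predicted
  x <- encoded_exon$depth[[1]][encoded_exon$mask[[1]]]
  locs <- exon_locs(encoded_exon$start, encoded_exon$end, encoded_exon$n_real)
  raw <- cpp_relevance(model$params, unclass(model$config), x, locs,
                       as.integer(encoded_exon$chrom_index),
                       call_to_code(target_class), as.integer(from_block))
  raw <- pmax(raw, 0)
  degenerate <- max(raw) == 0
  if (!degenerate) raw <- raw / max(raw)
  max_len <- length(encoded_exon$mask[[1]])
  scores <- numeric(max_len)
  scores[encoded_exon$mask[[1]]] <- raw
  out <- tibble::tibble(position = seq_len(max_len),
                        mask = encoded_exon$mask[[1]],
                        depth = encoded_exon$depth[[1]],
                        score = scores)
  structure(out, class = c("cnv_relevance", class(out)),
            predicted = predicted, target_class = target_class,
            degenerate = degenerate, exon_id = encoded_exon$id)
}

#' @export
autoplot.cnv_relevance <- function(object, ...) {
  df <- object[object$mask, ]
  df$base <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$base)) +
    ggplot2::geom_col(ggplot2::aes(y = max(.data$depth) * .data$score),
                      fill = "firebrick", alpha = 0.35, width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$depth), linewidth = 0.4) +
    ggplot2::labs(x = "position in exon (bp)",
                  y = "standardized depth (line) / scaled relevance (bars)",
                  title = paste0("Relevance map (", attr(object, "target_class"),
                                 "), exon ", attr(object, "exon_id"))) +
    ggplot2::theme_minimal()
}
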