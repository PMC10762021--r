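#' Transformer classifier configuration
#'
#' Hyperparameters of the per-exon classifier. The full-scale defaults are an
#' embedding width of 192, 3 pre-norm encoder blocks with 8 attention heads,
#' a maximum encoded exon length of 1000 bp, one classification token per
#' chromosome (24) and a positional-encoding base of 1e9 so absolute genomic
#' coordinates up to ~290 Mb map to distinct phases.
#'
#' @param H Embedding width (even; `heads` must divide it).
#' @param L Number of encoder blocks.
#' @param heads Attention heads per block.
#' @param max_len Maximum encoded exon length in bases.
#' @param mlp_hidden Hidden width of the encoder MLPs and the 2-layer
#'   classification head; defaults to `H`.
#' @param n_chrom_tokens Number of chromosome classification tokens.
#' @param pe_constant Positional-encoding base constant.
#' @param n_classes Number of output classes (DEL, DUP, NOCALL).
#' @return A `cnv_model_config` list.
#' @export
model_config <- function(H = 192L, L = 3L, heads = 8L, max_len = 1000L,
                         mlp_hidden = H, n_chrom_tokens = 24L,
                         pe_constant = 1e9, n_classes = 3L) {
  stopifnot(H %% 2L == 0L, H %% heads == 0L, max_len >= 1L, L >= 1L)
  structure(list(H = as.integer(H), L = as.integer(L),
                 heads = as.integer(heads), max_len = as.integer(max_len),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_chrom_tokens = as.integer(n_chrom_tokens),
                 pe_constant = pe_constant, n_classes = as.integer(n_classes)),
            class = "cnv_model_config")
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize an untrained model
#'
#' Xavier-uniform initialization for all projection matrices, zero biases,
#' unit layer-norm gains, and small-normal chromosome tokens. The global
#' depth-standardization statistics travel with the model so inference always
#' encodes with the statistics of the corpus the model was trained on.
#'
#' @param config A [model_config()].
#' @param stats Standardization statistics (list with `mean`, `sd`) from
#'   [depth_stats()].
#' @param seed Integer seed for the weight draw.
#' @return A `cnv_model` object.
#' @export
init_model <- function(config = model_config(), stats = list(mean = 0, sd = 1),
                       seed = 1L) {
  stopifnot(inherits(config, "cnv_model_config"), stats$sd > 0)
  H <- config$H; M <- config$mlp_hidden
  withr::with_seed(as.integer(seed), {
    blocks <- purrr::map(seq_len(config$L), function(l) {
      list(ln1_g = rep(1, H), ln1_b = rep(0, H),
           Wq = xavier(H, H), bq = rep(0, H),
           Wk = xavier(H, H), bk = rep(0, H),
           Wv = xavier(H, H), bv = rep(0, H),
           Wo = xavier(H, H), bo = rep(0, H),
           ln2_g = rep(1, H), ln2_b = rep(0, H),
           W1 = xavier(H, M), b1 = rep(0, M),
           W2 = xavier(M, H), b2 = rep(0, H))
    })
    params <- list(
      embed_w = xavier(1L, H)[1, ], embed_b = rep(0, H),
      C = matrix(rnorm(H * config$n_chrom_tokens, sd = 0.02), H,
                 config$n_chrom_tokens),
      blocks = blocks,
      head = list(W1 = xavier(H, M), b1 = rep(0, M),
                  W2 = xavier(M, 3L), b2 = rep(0, 3L)))
  })
  structure(list(config = config, params = params, stats = stats,
                 history = NULL,
                 provenance = list(init_seed = as.integer(seed))),
            class = "cnv_model")
}

#' @export
print.cnv_model <- function(x, ...) {
  cfg <- x$config
  cat("<cnv_model> transformer exon classifier\n")
  cat(sprintf("  H=%d, L=%d, heads=%d, max_len=%d, mlp_hidden=%d\n",
              cfg$H, cfg$L, cfg$heads, cfg$max_len, cfg$mlp_hidden))
  cat(sprintf("  depth standardization: mean=%.4g, sd=%.4g\n",
              x$stats$mean, x$stats$sd))
  if (!is.null(x$history)) {
    cat(sprintf("  trained: %d epoch(s), final loss %.5f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  } else cat("  untrained\n")
  invisible(x)
}

# genomic location values for the encoded (unpadded) positions of one exon:
# absolute coordinates spaced linearly from start to end over n_real columns
exon_locs <- function(start, end, n_real) {
  if (n_real == 1L) return(start)
  seq(start, end, length.out = n_real)
}

# build the C++ batch representation from encoded rows (real positions only)
exon_batch <- function(encoded) {
  enc <- encoded[!encoded$no_depth, , drop = FALSE]
  list(
    xs = purrr::map(seq_len(nrow(enc)),
                    function(i) enc$depth[[i]][enc$mask[[i]]]),
    locs = purrr::map(seq_len(nrow(enc)),
                      function(i) exon_locs(enc$start[i], enc$end[i],
                                            enc$n_real[i])),
    chroms = as.integer(enc$chrom_index),
    rows = enc
  )
}

#' Per-position depth embedding
#'
#' The position-wise affine map lifting each standardized depth value into
#' the embedding space: column `j` of the result is
#' `embed_w * depth[j] + embed_b`. Exposed mainly for inspection and testing;
#' the compiled forward pass computes it internally.
#'
#' @param depth Numeric vector of standardized depth values.
#' @param model A `cnv_model`.
#' @return An `H x length(depth)` matrix.
#' @export
embed_depth <- function(depth, model) {
  outer(model$params$embed_w, depth) + model$params$embed_b
}

#' Exon-specific sinusoidal positional encoding
#'
#' Encodes absolute genomic position: column 0 (the classification-token
#' slot) gets location 0, and the `n_real` rightmost depth columns get
#' locations spaced linearly from the exon start to its end; left-padded
#' columns also receive location 0 (their content is attention-masked and
#' never reaches the model). Feature rows interleave
#' `sin(loc / 10^(9*2j/H))` and `cos(loc / 10^(9*2j/H))` for
#' `j = 0..H/2-1`; the 1e9 base keeps coordinates up to ~290 Mb on distinct
#' phases.
#'
#' @param target One-row tibble (or list) with `start`, `end`.
#' @param config A [model_config()].
#' @param n_real Number of unpadded positions (defaults to full `max_len`).
#' @return An `H x (max_len + 1)` matrix (token column first).
#' @export
positional_encoding <- function(target, config, n_real = config$max_len) {
  if (target$start >= target$end) stop("start must be < end", call. = FALSE)
  H <- config$H
  locs <- c(0, rep(0, config$max_len - n_real),
            exon_locs(target$start, target$end, n_real))
  j <- 0:(H / 2 - 1)
  denom <- 10^(9 * 2 * j / H)
  ang <- outer(1 / denom, locs)        # H/2 x (max_len + 1)
  out <- matrix(0, H, config$max_len + 1L)
  out[2 * j + 1, ] <- sin(ang)
  out[2 * j + 2, ] <- cos(ang)
  out
}

#' Class pseudo-probabilities for encoded exons
#'
#' Runs the transformer forward pass in evaluation mode: the chromosome
#' token is prepended, positional encoding added, the pre-norm encoder
#' blocks applied with padded positions excluded from attention, and the
#' token state passed through the 2-layer head with softmax. Deterministic
#' given (model, input).
#'
#' @param model A `cnv_model`.
#' @param encoded Encoded exon tibble from [encode_exons()]; `no_depth` rows
#'   are skipped.
#' @return A tibble with one row per encodable exon: `id`, `p_del`, `p_dup`,
#'   `p_nocall`.
#' @export
predict_proba <- function(model, encoded) {
  bad <- encoded$chrom_index < 1L | encoded$chrom_index > model$config$n_chrom_tokens
  if (any(bad)) stop("chrom_index outside 1..", model$config$n_chrom_tokens,
                     call. = FALSE)
  batch <- exon_batch(encoded)
  if (length(batch$xs) == 0) {
    return(tibble::tibble(id = character(), p_del = numeric(),
                          p_dup = numeric(), p_nocall = numeric()))
  }
  probs <- cpp_forward_batch(model$params, unclass(model$config),
                             batch$xs, batch$locs, batch$chroms)
  tibble::tibble(id = batch$rows$id, p_del = probs[, 1], p_dup = probs[, 2],
                 p_nocall = probs[, 3])
}

#' Turn class probabilities into a DEL/DUP/NOCALL label
#'
#' The prediction is the arg-max class. With `min_call_prob` set, a DEL or
#' DUP arg-max whose probability falls below the threshold is demoted to
#' NOCALL (a confidence gate; off by default, pure arg-max).
#'
#' @param p_del,p_dup,p_nocall Numeric vectors of class probabilities.
#' @param min_call_prob Optional minimum probability for a DEL/DUP call.
#' @return Character vector of calls.
#' @export
#' @examples
#' predict_label(0.1, 0.2, 0.7)
#' predict_label(0.34, 0.33, 0.33, min_call_prob = 0.4)
predict_label <- function(p_del, p_dup, p_nocall, min_call_prob = NULL) {
  pm <- cbind(p_del, p_dup, p_nocall)
  idx <- max.col(pm, ties.method = "first")
  call <- code_to_call(idx)
  if (!is.null(min_call_prob)) {
    pmax_val <- pm[cbind(seq_len(nrow(pm)), idx)]
    call[call != "NOCALL" & pmax_val < min_call_prob] <- "NOCALL"
  }
  call
}

#' Save a trained model bundle
#'
#' Writes a directory bundle: `config.json` (architecture, standardization
#' statistics, provenance, parameter shapes) and `weights.bin` (all
#' parameters as a flat little-endian double vector, bit-exact round trip),
#' plus the loss trace as CSV when present.
#'
#' @param model A `cnv_model`.
#' @param path Bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  flat <- flatten_params(model$params)
  shapes <- purrr::map(flat, dim_or_len)
  jsonlite::write_json(
    list(config = unclass(model$config), stats = model$stats,
         provenance = model$provenance, shapes = shapes,
         package_version = as.character(utils::packageVersion("cnvformer"))),
    file.path(path, "config.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(unlist(purrr::map(flat, as.numeric)), con, size = 8,
           endian = "little")
  if (!is.null(model$history)) {
    readr::write_csv(model$history, file.path(path, "loss_trace.csv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#'
#' @param path Bundle directory.
#' @return A `cnv_model`, bit-identical to the one saved.
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[c("H", "L", "heads", "max_len",
                                             "mlp_hidden", "n_chrom_tokens",
                                             "pe_constant", "n_classes")])
  n_total <- sum(vapply(meta$shapes, prod, numeric(1)))
  con <- file(file.path(path, "weights.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_total, size = 8, endian = "little")
  params <- unflatten_params(vals, meta$shapes, cfg)
  hist_path <- file.path(path, "loss_trace.csv")
  history <- if (file.exists(hist_path)) {
    readr::read_csv(hist_path, progress = FALSE, show_col_types = FALSE)
  } else NULL
  structure(list(config = cfg, params = params,
                 stats = list(mean = meta$stats$mean, sd = meta$stats$sd),
                 history = history, provenance = as.list(meta$provenance)),
            class = "cnv_model")
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)

# deterministic flat ordering of the parameter tree (used by serialization
# and the Adam optimizer)
flatten_params <- function(params) {
  out <- list(embed_w = params$embed_w, embed_b = params$embed_b, C = params$C)
  for (l in seq_along(params$blocks)) {
    b <- params$blocks[[l]]
    names(b) <- paste0("block", l, ".", names(b))
    out <- c(out, b)
  }
  h <- params$head
  names(h) <- paste0("head.", names(h))
  c(out, h)
}

unflatten_params <- function(vals, shapes, config) {
  offset <- 0L
  flat <- purrr::imap(shapes, function(shp, nm) {
    n <- prod(shp)
    v <- vals[(offset + 1L):(offset + n)]
    offset <<- offset + as.integer(n)
    if (length(shp) == 2L) matrix(v, shp[1], shp[2]) else v
  })
  rebuild_param_tree(flat, config$L)
}

rebuild_param_tree <- function(flat, L) {
  blocks <- purrr::map(seq_len(L), function(l) {
    pre <- paste0("block", l, ".")
    b <- flat[startsWith(names(flat), pre)]
    names(b) <- sub(pre, "", names(b), fixed = TRUE)
    b
  })
  head_p <- flat[startsWith(names(flat), "head.")]
  names(head_p) <- sub("head.", "", names(head_p), fixed = TRUE)
  list(embed_w = flat$embed_w, embed_b = flat$embed_b, C = flat$C,
       blocks = blocks, head = head_p)
}
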