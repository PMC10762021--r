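# Shared fixtures and independent brute-force oracles. Everything is built
# in code at test time; oracles deliberately use naive per-base loops so they
# share no logic with the implementation they check.

tiny_config <- function(max_len = 60L) {
  model_config(H = 16L, L = 1L, heads = 2L, max_len = max_len,
               mlp_hidden = 16L)
}

# one-row encoded-exon tibble built directly from a raw depth vector
encode_one <- function(raw, stats, max_len, chrom_index = 1L,
                       start = 20000, end = start + length(raw), id = "e1") {
  enc <- standardize_and_pad(raw, stats, max_len)
  out <- tibble::tibble(chrom = paste0("chr", chrom_index),
                        chrom_index = as.integer(chrom_index),
                        start = start, end = end, id = id,
                        depth = list(enc$depth), mask = list(enc$mask),
                        n_real = enc$n_real, no_depth = FALSE)
  attr(out, "stats") <- stats
  attr(out, "max_len") <- as.integer(max_len)
  out
}

# random small target set with non-overlapping exons on a few chromosomes
random_targets <- function(n, n_chrom = 2, exon_len = c(10L, 40L),
                           gap = c(5L, 60L)) {
  per <- ceiling(n / n_chrom)
  purrr::map_dfr(seq_len(n_chrom), function(ch) {
    k <- min(per, n - (ch - 1) * per)
    if (k <= 0) return(NULL)
    len <- sample(exon_len[1]:exon_len[2], k, replace = TRUE)
    g <- sample(gap[1]:gap[2], k, replace = TRUE)
    start <- 1000 + cumsum(g) + c(0, cumsum(len[-k]))
    tibble::tibble(chrom = paste0("chr", ch), chrom_index = ch,
                   start = start, end = start + len,
                   id = sprintf("t%d_%03d", ch, seq_len(k)))
  })
}

# random DEL/DUP interval set over the coordinate span of the targets
random_calls <- function(targets, n_calls) {
  purrr::map_dfr(seq_len(n_calls), function(i) {
    ch <- sample(unique(targets$chrom_index), 1)
    span <- range(targets$start[targets$chrom_index == ch],
                  targets$end[targets$chrom_index == ch])
    a <- sample(span[1]:span[2], 1)
    b <- a + sample(5:150, 1)
    tibble::tibble(chrom_index = ch, start = a, end = b,
                   call = sample(c("DEL", "DUP"), 1))
  })
}

# ---- brute-force oracles -----------------------------------------------------

# per-base majority label for each query interval (naive base loop)
bf_majority <- function(queries, calls) {
  vapply(seq_len(nrow(queries)), function(i) {
    bases <- seq(queries$start[i], queries$end[i] - 1)
    cnt <- c(DEL = 0, DUP = 0)
    for (cls in c("DEL", "DUP")) {
      cv <- calls[calls$chrom_index == queries$chrom_index[i] &
                    calls$call == cls, , drop = FALSE]
      if (nrow(cv) == 0) next
      covered <- vapply(bases, function(b)
        any(b >= cv$start & b < cv$end), logical(1))
      cnt[cls] <- sum(covered)
    }
    if (all(cnt == 0)) return("NOCALL")
    if (cnt["DEL"] == cnt["DUP"]) return("NOCALL")
    names(cnt)[which.max(cnt)]
  }, character(1))
}

# naive depth extraction: scan the whole table for every base of each target
bf_extract <- function(depth, targets) {
  depth$ci <- chrom_name_to_index(depth$chrom)
  lapply(seq_len(nrow(targets)), function(i) {
    vapply(seq(targets$start[i] + 1, targets$end[i]), function(p) {
      hit <- depth$ci == targets$chrom_index[i] & depth$pos == p
      if (any(hit)) depth$depth[hit][1] else 0
    }, numeric(1))
  })
}

# naive 3-NN vote for one depth-less exon
bf_vote <- function(calls, chrom_index, start, end) {
  cand <- calls[calls$chrom_index == chrom_index, , drop = FALSE]
  if (nrow(cand) == 0) return("NOCALL")
  d <- abs((cand$start + cand$end) / 2 - (start + end) / 2)
  ord <- order(d, cand$start)
  nn <- cand$call[ord[seq_len(min(3, nrow(cand)))]]
  tab <- table(factor(nn, levels = c("DEL", "DUP", "NOCALL")))
  if (sum(tab == max(tab)) > 1) "NOCALL" else names(tab)[which.max(tab)]
}

# naive run-length segment merge
bf_merge <- function(calls) {
  out <- list()
  for (ch in unique(calls$chrom_index)) {
    cc <- calls[calls$chrom_index == ch, ]
    r <- rle(cc$call)
    stop_idx <- cumsum(r$lengths)
    start_idx <- stop_idx - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] %in% c("DEL", "DUP")) next
      out[[length(out) + 1]] <- tibble::tibble(
        chrom_index = ch, start = cc$start[start_idx[k]],
        end = cc$end[stop_idx[k]], call = r$values[k],
        n_exons = r$lengths[k])
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom_index, start)
}

# naive confusion recount
bf_metrics <- function(pred, tru) {
  count <- function(cls) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cls && tru[i] == cls) tp <- tp + 1
      else if (pred[i] == cls) fp <- fp + 1
      else if (tru[i] == cls) fn <- fn + 1
      else tn <- tn + 1
    }
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  list(DEL = count("DEL"), DUP = count("DUP"))
}

# ---- cached trained tiny model (shared across test files) -------------------

.fixture_env <- new.env(parent = emptyenv())

# a small model trained on two clearly separable simulated samples sharing a
# capture design — one with heterozygous (0.5x) and one with strong (0.2x)
# deletions, so the training support covers near-zero depth; cached so several
# test files can reuse one training run
trained_tiny <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  params <- sim_params(n_chromosomes = 2L, exons_per_chromosome = 150L,
                       exon_length_meanlog = log(40), exon_length_sdlog = 0.3,
                       exon_length_range = c(20, 58), gap_meanlog = log(400),
                       no_depth_fraction = 0.1, seed = 404L)
  sim <- simulate_sample(params)
  params2 <- params
  params2$del_multiplier <- 0.2
  params2$seed <- 405L
  sim2 <- simulate_sample(params2, targets = sim$targets)
  vec <- extract_depth_vectors(sim$depth, sim$targets)
  st <- depth_stats(vec)
  enc <- encode_exons(vec, st, max_len = 60L)
  lab <- assign_exon_labels(enc, sim$truth)
  lab2 <- assign_exon_labels(
    encode_exons(extract_depth_vectors(sim2$depth, sim2$targets), st,
                 max_len = 60L), sim2$truth)
  model <- init_model(tiny_config(60L), st, seed = 2L)
  model <- train_model(model, dplyr::bind_rows(lab, lab2),
                       train_config(epochs = 8L, lr_initial = 2e-3,
                                    batch_size = 32L, seed = 3L))
  .fixture_env$tiny <- list(model = model, sim = sim, stats = st,
                            encoded = enc, labeled = lab)
  .fixture_env$tiny
}
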