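# Desk-scale benchmark experiments: the package's own end-to-end evaluation
# harness. Each experiment simulates its inputs, runs the full pipeline
# (encode -> train -> call -> impute -> evaluate) and returns the measured
# quantities. All randomness derives from one integer seed.

scaled_sim_params <- function(seed, ...) {
  defaults <- list(n_chromosomes = 2L, exons_per_chromosome = 1000L,
                   exon_length_meanlog = log(120), exon_length_sdlog = 0.3,
                   exon_length_range = c(50, 180),
                   base_coverage = 50, dispersion = 10,
                   del_rate = 0.05, dup_rate = 0.05,
                   del_multiplier = 0.5, dup_multiplier = 1.5,
                   seed = seed)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

scaled_model_config <- function() {
  model_config(H = 32L, L = 2L, heads = 4L, max_len = 200L)
}

scaled_train_config <- function(seed, epochs = 15L) {
  train_config(epochs = epochs, lr_initial = 1e-3, batch_size = 32L,
               seed = seed)
}

prep_sample <- function(sample, stats = NULL, max_len = 200L) {
  vec <- extract_depth_vectors(sample$depth, sample$targets)
  if (is.null(stats)) stats <- depth_stats(vec)
  enc <- encode_exons(vec, stats, max_len = max_len)
  list(encoded = enc, stats = stats,
       labeled = assign_exon_labels(enc, sample$truth))
}

evaluate_on_sample <- function(model, sample, stats, max_len = 200L) {
  prep <- prep_sample(sample, stats, max_len)
  calls <- call_exons(model, prep$encoded)
  calls <- impute_no_depth_calls(calls,
                                 prep$encoded[prep$encoded$no_depth, ])
  truth <- assign_exon_labels(sample$targets, sample$truth)
  suppressWarnings(compute_metrics(calls, truth[c("id", "label")]))
}

#' Synthetic label-recovery benchmark
#'
#' The package's principal end-to-end experiment: a two-sample cohort (two
#' chromosomes, 1000 exons each, 50x coverage, heterozygous 0.5x deletions
#' and 1.5x duplications at 5% per-exon rates, negative-binomial dispersion
#' 10) shares one capture design; a scaled-down classifier (H = 32, L = 2,
#' 4 heads, 200 bp maximum exon length) is trained on the first sample's
#' labels and scored on the held-out second sample at exon resolution,
#' depth-less exons resolved by the 3-nearest-neighbour vote.
#'
#' @param seed Integer seed driving simulation, initialization and training.
#' @param epochs Training epoch budget.
#' @return A list: `model`, `stats`, `metrics` (a `cnv_metrics` for the
#'   held-out sample), `macro_f1`, and the simulated `cohort`.
#' @export
benchmark_label_recovery <- function(seed = 7L, epochs = 15L) {
  cohort <- simulate_cohort(scaled_sim_params(seed), 2L)
  prep <- prep_sample(cohort$samples[[1]])
  model <- init_model(scaled_model_config(), prep$stats, seed = seed + 1L)
  model <- train_model(model, prep$labeled,
                       scaled_train_config(seed + 2L, epochs))
  metrics <- evaluate_on_sample(model, cohort$samples[[2]], prep$stats)
  list(model = model, stats = prep$stats, metrics = metrics,
       macro_f1 = macro_f1(metrics), cohort = cohort)
}

#' Fine-tuning transfer benchmark
#'
#' Takes a trained base model and measures what 5 epochs of fine-tuning on
#' 100 labelled exons from a distribution-shifted regime (3.0x duplications
#' at a 15% per-exon rate — a somatic-like call distribution) do to held-out
#' performance on that regime, compared with the unadapted base model.
#'
#' @param base Result of [benchmark_label_recovery()] (or a list with
#'   `model` and `stats`).
#' @param seed Integer seed for the shifted cohort, exon subsample and
#'   fine-tuning.
#' @param n_finetune Number of labelled exons in the fine-tuning set.
#' @param epochs Fine-tuning epoch budget.
#' @return A list: `base_f1`, `tuned_f1`, `gain`, `tuned` (the fine-tuned
#'   model) and the per-model `cnv_metrics`.
#' @export
benchmark_finetune_gain <- function(base, seed = 7L, n_finetune = 100L,
                                    epochs = 5L) {
  shifted <- simulate_cohort(
    scaled_sim_params(seed + 10L, dup_multiplier = 3.0, dup_rate = 0.15), 2L)
  prep_ft <- prep_sample(shifted$samples[[1]], base$stats)
  small <- withr::with_seed(seed + 11L, {
    prep_ft$labeled[sample(which(!prep_ft$labeled$no_depth), n_finetune), ]
  })
  tuned <- finetune_model(base$model, small,
                          scaled_train_config(seed + 12L, epochs))
  base_metrics <- evaluate_on_sample(base$model, shifted$samples[[2]],
                                     base$stats)
  tuned_metrics <- evaluate_on_sample(tuned, shifted$samples[[2]], base$stats)
  list(base_f1 = macro_f1(base_metrics), tuned_f1 = macro_f1(tuned_metrics),
       gain = macro_f1(tuned_metrics) - macro_f1(base_metrics),
       tuned = tuned, base_metrics = base_metrics,
       tuned_metrics = tuned_metrics)
}

#' Breakpoint-localization benchmark for relevance maps
#'
#' Trains the scaled-down classifier on a regime whose event boundaries fall
#' inside the boundary exons (so within-exon depth steps are part of the
#' training signal), then probes it with fresh 200 bp exons carrying a
#' single 0.5x step at a random position and measures how often the
#' relevance argmax lands within a window of the step.
#'
#' @param seed Integer seed.
#' @param n_cases Number of probe exons.
#' @param window Localization window in bases (each side).
#' @param epochs Training epoch budget.
#' @return A list: `rate` (fraction localized), `offsets` (argmax minus true
#'   step position per case) and the trained `model`.
#' @export
benchmark_breakpoint_localization <- function(seed = 7L, n_cases = 50L,
                                              window = 25L, epochs = 15L) {
  params <- scaled_sim_params(seed + 20L, breakpoint_mode = "exon",
                              event_span_mean = 2)
  sim <- simulate_sample(params)
  prep <- prep_sample(sim)
  model <- init_model(scaled_model_config(), prep$stats, seed = seed + 21L)
  model <- train_model(model, prep$labeled,
                       scaled_train_config(seed + 22L, epochs))
  offsets <- withr::with_seed(seed + 23L, {
    vapply(seq_len(n_cases), function(i) {
      len <- 200L
      p <- sample(40:160, 1)
      d <- c(rnbinom(p, size = params$dispersion,
                     mu = params$base_coverage),
             rnbinom(len - p, size = params$dispersion,
                     mu = params$base_coverage * params$del_multiplier))
      enc <- standardize_and_pad(d, prep$stats, 200L)
      row <- tibble::tibble(chrom = "chr1", chrom_index = 1L, start = 1e6,
                            end = 1e6 + len, id = sprintf("probe%02d", i),
                            depth = list(enc$depth), mask = list(enc$mask),
                            n_real = enc$n_real, no_depth = FALSE)
      attr(row, "stats") <- prep$stats
      rel <- relevance_map(model, row, target_class = "DEL")
      which.max(rel$score[rel$mask]) - p
    }, numeric(1))
  })
  list(rate = mean(abs(offsets) <= window), offsets = offsets, model = model)
}
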