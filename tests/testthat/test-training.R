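test_that("exon labels follow the majority-base rule", {
  targets <- read_exon_targets(c("chr1\t100\t200\ta", "chr1\t300\t400\tb",
                                 "chr1\t500\t600\tc"))
  truth <- tibble::tibble(chrom_index = 1L,
                          start = c(50, 300, 330), end = c(250, 360, 340),
                          call = c("DEL", "DUP", "DEL"))
  lab <- assign_exon_labels(targets, truth)
  expect_equal(lab$label, c("DEL",    # fully contained
                            "DUP",    # 60 bp DUP vs 10 bp DEL
                            "NOCALL"))# no overlap
  # exactly tied conflicting coverage -> NOCALL
  tie <- tibble::tibble(chrom_index = 1L, start = c(100, 150),
                        end = c(150, 200), call = c("DEL", "DUP"))
  expect_message(l2 <- assign_exon_labels(targets[1, ], tie), "tied")
  expect_equal(l2$label, "NOCALL")
})

test_that("label assignment matches the per-base brute-force oracle", {
  set.seed(42)
  for (rep in 1:8) {
    targets <- random_targets(sample(10:30, 1))
    truth <- random_calls(targets, sample(3:12, 1))
    got <- assign_exon_labels(targets, truth)$label
    expect_identical(got, bf_majority(targets, truth))
  }
})

test_that("a single training epoch satisfies the smoke contract", {
  cfg <- tiny_config(30L)
  st <- list(mean = 10, sd = 4)
  set.seed(10)
  enc <- purrr::map_dfr(1:12, function(i)
    encode_one(runif(sample(5:30, 1), 0, 30), st, 30L, id = paste0("e", i),
               start = 1000 * i, end = 1000 * i + 30))
  attr(enc, "stats") <- st
  enc$label <- sample(c("DEL", "DUP", "NOCALL"), 12, replace = TRUE)
  m <- train_model(init_model(cfg, st, seed = 1), enc,
                   train_config(epochs = 1L, lr_initial = 1e-3,
                                batch_size = 4L, seed = 2))
  expect_equal(nrow(m$history), 1L)
  expect_true(all(vapply(cnvformer:::flatten_params(m$params),
                         function(p) all(is.finite(p)), logical(1))))
})

test_that("training is deterministic given the seed", {
  fx <- trained_tiny()
  cfg <- tiny_config(60L)
  run <- function() {
    train_model(init_model(cfg, fx$stats, seed = 2),
                utils::head(fx$labeled[!fx$labeled$no_depth, ], 40),
                train_config(epochs = 2L, lr_initial = 1e-3, batch_size = 16L,
                             seed = 31))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
})

test_that("the epoch budget is honoured exactly", {
  fx <- trained_tiny()
  tuned <- finetune_model(fx$model,
                          utils::head(fx$labeled[!fx$labeled$no_depth, ], 20),
                          train_config(epochs = 11L, lr_initial = 1e-4,
                                       batch_size = 10L, seed = 5))
  expect_equal(nrow(tuned$history), 11L)
  expect_equal(tuned$history$epoch, 1:11)
  expect_true(!is.null(tuned$provenance$finetune$base_hash))
})

test_that("fine-tuning with zero learning rate leaves weights unchanged", {
  fx <- trained_tiny()
  tuned <- finetune_model(fx$model,
                          utils::head(fx$labeled[!fx$labeled$no_depth, ], 20),
                          train_config(epochs = 2L, lr_initial = 0,
                                       batch_size = 10L, seed = 5))
  expect_identical(tuned$params, fx$model$params)
})

test_that("a 20-exon memorization set is driven below 0.1 loss", {
  fx <- trained_tiny()
  set.seed(77)
  small <- utils::head(fx$labeled[!fx$labeled$no_depth, ], 20)
  m <- init_model(tiny_config(60L), fx$stats, seed = 8)
  m <- train_model(m, small, train_config(epochs = 200L, lr_initial = 3e-3,
                                          batch_size = 20L, seed = 9))
  expect_lt(min(m$history$loss), 0.1)
})

test_that("a strongly separable regime is learned within 10 epochs", {
  params <- sim_params(n_chromosomes = 2L, exons_per_chromosome = 150L,
                       exon_length_meanlog = log(40), exon_length_sdlog = 0.3,
                       exon_length_range = c(20, 58), gap_meanlog = log(400),
                       del_multiplier = 0.3, dup_multiplier = 2.5,
                       dispersion = 50, no_depth_fraction = 0, seed = 55L)
  sim <- simulate_sample(params)
  vec <- extract_depth_vectors(sim$depth, sim$targets)
  st <- depth_stats(vec)
  enc <- encode_exons(vec, st, max_len = 60L)
  lab <- assign_exon_labels(enc, sim$truth)
  m <- init_model(tiny_config(60L), st, seed = 2)
  m <- train_model(m, lab, train_config(epochs = 10L, lr_initial = 2e-3,
                                        batch_size = 32L, seed = 3))
  calls <- call_exons(m, lab)
  met <- compute_metrics(calls, lab[!lab$no_depth, c("id", "label")])
  expect_gte(macro_f1(met), 0.95)
})

test_that("fine-tuning adapts the decision boundary to a shifted regime", {
  # base regime: heterozygous deletions at 0.5x; shifted regime: 0.7x, which
  # straddles the base model's learned DEL/NOCALL boundary
  fx <- trained_tiny()
  shift_params <- sim_params(n_chromosomes = 2L, exons_per_chromosome = 150L,
                             exon_length_meanlog = log(40),
                             exon_length_sdlog = 0.3,
                             exon_length_range = c(20, 58),
                             gap_meanlog = log(400), del_multiplier = 0.7,
                             del_rate = 0.1, no_depth_fraction = 0,
                             seed = 991L)
  cohort <- simulate_cohort(shift_params, 2L)
  prep <- function(s) {
    enc <- encode_exons(extract_depth_vectors(s$depth, s$targets), fx$stats,
                        max_len = 60L)
    assign_exon_labels(enc, s$truth)
  }
  ft <- prep(cohort$samples[[1]])
  set.seed(12)
  ft_small <- ft[sample(which(!ft$no_depth), 50), ]
  held <- prep(cohort$samples[[2]])
  held_truth <- held[!held$no_depth, c("id", "label")]
  f1_of <- function(m) suppressWarnings(
    macro_f1(compute_metrics(call_exons(m, held), held_truth)))
  base_f1 <- f1_of(fx$model)
  tuned <- finetune_model(fx$model, ft_small,
                          train_config(epochs = 5L, lr_initial = 1e-3,
                                       batch_size = 16L, seed = 6))
  expect_gt(f1_of(tuned), base_f1)
})
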