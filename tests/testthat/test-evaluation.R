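test_that("integer copy numbers discretize around the diploid state", {
  expect_equal(discretize_copy_number(c(0, 1, 2, 3, 4)),
               c("DEL", "DEL", "NOCALL", "DUP", "DUP"))
  expect_error(discretize_copy_number(-1), "negative")
})

test_that("segment calls project onto exons by majority base", {
  targets <- read_exon_targets(c("chr1\t100\t200\ta", "chr1\t300\t400\tb",
                                 "chr1\t500\t600\tc"))
  segs <- tibble::tibble(chrom_index = 1L, start = c(50, 320),
                         end = c(250, 340), call = c("DUP", "DEL"))
  out <- intersect_segments_to_exons(segs, targets)
  expect_equal(out$call, c("DUP",     # fully inside
                           "DEL",     # >= 1 bp overlap takes the call
                           "NOCALL")) # gap
  # straddling different-call segments: 80 bp DEL vs 20 bp DUP
  segs2 <- tibble::tibble(chrom_index = 1L, start = c(100, 180),
                          end = c(180, 200), call = c("DEL", "DUP"))
  expect_equal(intersect_segments_to_exons(segs2, targets)$call[1], "DEL")
  # randomized agreement with the per-base oracle
  set.seed(99)
  for (rep in 1:8) {
    tg <- random_targets(sample(8:25, 1))
    sg <- random_calls(tg, sample(2:10, 1))
    expect_identical(intersect_segments_to_exons(sg, tg)$call,
                     bf_majority(tg, sg))
  }
})

test_that("consensus labels for segments follow base coverage", {
  seg <- tibble::tibble(chrom_index = 1L, start = 1000, end = 2000,
                        call = "DEL", n_exons = 3L)
  truth <- tibble::tibble(chrom_index = 1L,
                          start = c(900, 1950), end = c(1700, 2000),
                          call = c("DEL", "DUP"))
  expect_equal(consensus_truth_for_segment(seg, truth)$truth_label, "DEL")
  expect_equal(consensus_truth_for_segment(seg, truth[0, ])$truth_label,
               "NOCALL")
  half <- tibble::tibble(chrom_index = 1L, start = c(1000, 1500),
                         end = c(1500, 2000), call = c("DEL", "DUP"))
  expect_equal(consensus_truth_for_segment(seg, half)$truth_label, "NOCALL")
})

test_that("the metric suite reproduces hand-checkable aggregates", {
  # benchmark-table worked example: DEL precision 0.834 and DUP precision
  # 0.679 give overall precision 0.757 under macro averaging
  agg <- aggregate_metrics(tibble::tibble(class = c("DEL", "DUP"),
                                          precision = c(0.834, 0.679),
                                          recall = c(0.541, 0.500)))
  # half-ulp of the printed 3-decimal values
  expect_equal(agg$precision, 0.757, tolerance = 1.5e-3)
  expect_equal(agg$recall, 0.520, tolerance = 1.5e-3)
  expect_equal(agg$del_f1, 0.656, tolerance = 1.5e-3)
  expect_equal(agg$f1, 0.617, tolerance = 1.5e-3)
})

test_that("perfect prediction scores 1 everywhere", {
  set.seed(3)
  truth <- tibble::tibble(id = paste0("e", 1:60),
                          label = sample(c("DEL", "DUP", "NOCALL"), 60,
                                         replace = TRUE))
  pred <- tibble::tibble(id = truth$id, call = truth$label)
  met <- compute_metrics(pred, truth)
  expect_equal(unname(unlist(met$overall)), rep(1, 7))
  expect_equal(met$per_class$f1, c(1, 1))
})

test_that("metrics equal an independent per-exon recount on random inputs", {
  set.seed(1234)
  for (rep in 1:10) {
    n <- sample(c(50, 200, 1000), 1)
    truth <- tibble::tibble(id = paste0("e", seq_len(n)),
                            label = sample(c("DEL", "DUP", "NOCALL"), n,
                                           replace = TRUE,
                                           prob = c(0.2, 0.2, 0.6)))
    pred <- tibble::tibble(id = truth$id,
                           call = sample(c("DEL", "DUP", "NOCALL"), n,
                                         replace = TRUE))
    met <- compute_metrics(pred, truth)
    bf <- bf_metrics(pred$call, truth$label)
    for (cls in c("DEL", "DUP")) {
      row <- met$confusion[met$confusion$class == cls, ]
      expect_equal(unname(unlist(row[c("tp", "fp", "fn", "tn")])),
                   unname(bf[[cls]]))
      pc <- met$per_class[met$per_class$class == cls, ]
      expect_equal(pc$precision, bf[[cls]]["tp"] / (bf[[cls]]["tp"] + bf[[cls]]["fp"]),
                   ignore_attr = TRUE)
      expect_equal(pc$recall, bf[[cls]]["tp"] / (bf[[cls]]["tp"] + bf[[cls]]["fn"]),
                   ignore_attr = TRUE)
      expect_equal(pc$npa, bf[[cls]]["tn"] / (bf[[cls]]["tn"] + bf[[cls]]["fp"]),
                   ignore_attr = TRUE)
      expect_equal(pc$npv, bf[[cls]]["tn"] / (bf[[cls]]["tn"] + bf[[cls]]["fn"]),
                   ignore_attr = TRUE)
    }
    # macro identities
    expect_equal(met$overall$precision, mean(met$per_class$precision))
    expect_equal(met$overall$recall, mean(met$per_class$recall))
    expect_equal(met$overall$f1,
                 2 * met$overall$precision * met$overall$recall /
                   (met$overall$precision + met$overall$recall))
  }
})

test_that("degenerate denominators yield 0 with a warning, not NaN", {
  truth <- tibble::tibble(id = c("a", "b"), label = c("NOCALL", "NOCALL"))
  pred <- tibble::tibble(id = c("a", "b"), call = c("NOCALL", "NOCALL"))
  expect_warning(met <- compute_metrics(pred, truth), "denominator")
  expect_equal(met$overall$precision, 0)
  expect_equal(met$overall$f1, 0)
})

test_that("mismatched exon universes are rejected with the missing ids", {
  truth <- tibble::tibble(id = c("a", "b"), label = c("DEL", "DUP"))
  pred <- tibble::tibble(id = c("a", "zzz"), call = c("DEL", "DUP"))
  expect_error(compute_metrics(pred, truth), "zzz")
})

test_that("exon-resolution truth round-trips through merge and consensus", {
  set.seed(8)
  targets <- random_targets(40)
  targets$call <- sample(c("DEL", "DUP", "NOCALL"), 40, replace = TRUE)
  segs <- merge_segments(targets[c("chrom_index", "start", "end", "call")])
  # each merged segment's consensus against the original exon truth is itself
  exon_truth <- dplyr::filter(targets, call != "NOCALL")[
    c("chrom_index", "start", "end", "call")]
  cons <- consensus_truth_for_segment(segs, exon_truth)
  expect_identical(cons$truth_label, cons$call)
  # and re-intersection returns the original exon calls
  back <- intersect_segments_to_exons(segs, targets)
  expect_identical(back$call, targets$call)
})

test_that("tidy and glance expose the metric suite as tibbles", {
  truth <- tibble::tibble(id = paste0("e", 1:20),
                          label = rep(c("DEL", "DUP", "NOCALL", "NOCALL"), 5))
  pred <- tibble::tibble(id = truth$id,
                         call = rep(c("DEL", "NOCALL", "NOCALL", "DUP"), 5))
  met <- compute_metrics(pred, truth)
  expect_s3_class(tidy(met), "tbl_df")
  expect_equal(nrow(glance(met)), 1L)
  expect_named(glance(met),
               c("precision", "recall", "f1", "del_f1", "dup_f1", "npa", "npv"))
})

test_that("segment-resolution scoring matches its definitions", {
  calls <- tibble::tibble(chrom_index = 1L,
                          start = c(100, 300, 500, 900),
                          end = c(200, 400, 600, 1000),
                          call = c("DEL", "DEL", "NOCALL", "DUP"))
  truth <- tibble::tibble(chrom_index = 1L, start = c(100, 2000),
                          end = c(400, 2100), call = c("DEL", "DUP"))
  met <- segment_metrics(calls, truth)
  # predicted: DEL segment [100,400] (consensus DEL, TP), DUP [900,1000]
  # (consensus NOCALL, FP); truth DUP at [2000,2100] never recovered
  expect_equal(met$per_class$precision, c(1, 0))
  expect_equal(met$per_class$recall, c(1, 0))
  expect_true(is.na(met$overall$npa))
})
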