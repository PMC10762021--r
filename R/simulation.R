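#' Exome depth simulation parameters
#'
#' Describes a WES-like capture design and depth regime: exon lengths are
#' log-normal (median ~150 bp, clamped to a configurable range covering the
#' 50–4000 bp span of real capture targets), inter-exon gaps log-normal,
#' per-base depth negative-binomial around 50x mean coverage (real exome
#' depth is overdispersed; Poisson is the `dispersion = Inf` limit), CNV
#' events start at an exon with the given per-exon rates and span a
#' geometric number of consecutive exons (mean `event_span_mean`, single-exon
#' events included). Heterozygous deletions and duplications shift the depth
#' mean multiplicatively (0.5x / 1.5x); a `hom_fraction` of events are
#' homozygous (0x / 2x). A `no_depth_fraction` of exons are emitted with no
#' depth rows at all, emulating the ~20% of real capture targets without
#' read depth. Per-base noise can be smoothed with a short moving average so
#' event breakpoints appear as sharp shifts over a locally correlated
#' signal.
#'
#' @param n_chromosomes Number of chromosomes (<= 24).
#' @param exons_per_chromosome Exons per chromosome.
#' @param exon_length_meanlog,exon_length_sdlog Log-normal exon length
#'   parameters.
#' @param exon_length_range Length clamp `c(min, max)` in bp.
#' @param gap_meanlog,gap_sdlog Log-normal inter-exon gap parameters.
#' @param chrom_offset Genomic coordinate at which each chromosome's first
#'   exon may start (the low end of real capture coordinates).
#' @param base_coverage Mean per-base depth of the diploid state.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param del_rate,dup_rate Per-exon event initiation probabilities.
#' @param event_span_mean Mean exons spanned by one event (geometric).
#' @param del_multiplier,dup_multiplier Heterozygous depth multipliers.
#' @param hom_fraction Fraction of events that are homozygous (0x or 2x).
#' @param no_depth_fraction Fraction of exons emitted without depth rows.
#' @param smooth_window Moving-average window for per-base depth (1 = off).
#' @param breakpoint_mode Where event boundaries fall: `"gap"` (default)
#'   places them in the intergenic gaps flanking the first and last event
#'   exon, so events cover whole exons — the situation of interval truth
#'   sets reported at capture resolution; `"exon"` draws each boundary
#'   uniformly inside its boundary exon, so those exons are partially
#'   covered and their depth shows a sharp within-exon step at the
#'   breakpoint (per-exon labels then follow the majority-base rule).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cnv_sim_params` list.
#' @export
sim_params <- function(n_chromosomes = 2L, exons_per_chromosome = 1000L,
                       exon_length_meanlog = log(150), exon_length_sdlog = 0.45,
                       exon_length_range = c(50, 4000),
                       gap_meanlog = log(3000), gap_sdlog = 0.8,
                       chrom_offset = 14600,
                       base_coverage = 50, dispersion = 10,
                       del_rate = 0.05, dup_rate = 0.05,
                       event_span_mean = 3, del_multiplier = 0.5,
                       dup_multiplier = 1.5, hom_fraction = 0.05,
                       no_depth_fraction = 0.2, smooth_window = 5L,
                       breakpoint_mode = c("gap", "exon"), seed = 1L) {
  breakpoint_mode <- match.arg(breakpoint_mode)
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            exons_per_chromosome = as.integer(exons_per_chromosome),
            exon_length_meanlog = exon_length_meanlog,
            exon_length_sdlog = exon_length_sdlog,
            exon_length_range = exon_length_range,
            gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
            chrom_offset = chrom_offset,
            base_coverage = base_coverage, dispersion = dispersion,
            del_rate = del_rate, dup_rate = dup_rate,
            event_span_mean = event_span_mean,
            del_multiplier = del_multiplier, dup_multiplier = dup_multiplier,
            hom_fraction = hom_fraction,
            no_depth_fraction = no_depth_fraction,
            smooth_window = as.integer(smooth_window),
            breakpoint_mode = breakpoint_mode, seed = as.integer(seed))
  stopifnot(p$n_chromosomes >= 1L, p$n_chromosomes <= 24L,
            p$exons_per_chromosome >= 1L,
            p$del_rate >= 0, p$del_rate <= 1, p$dup_rate >= 0, p$dup_rate <= 1,
            p$del_rate + p$dup_rate <= 1,
            p$del_multiplier >= 0, p$dup_multiplier >= 0,
            p$hom_fraction >= 0, p$hom_fraction <= 1,
            p$no_depth_fraction >= 0, p$no_depth_fraction < 1,
            p$base_coverage > 0, p$dispersion > 0, p$event_span_mean >= 1,
            p$smooth_window >= 1L)
  structure(p, class = "cnv_sim_params")
}

# draw a shared capture design (targets BED) from the params
sim_targets <- function(params) {
  purrr::map_dfr(seq_len(params$n_chromosomes), function(ch) {
    n <- params$exons_per_chromosome
    len <- round(pmin(pmax(
      rlnorm(n, params$exon_length_meanlog, params$exon_length_sdlog),
      params$exon_length_range[1]), params$exon_length_range[2]))
    gap <- round(rlnorm(n, params$gap_meanlog, params$gap_sdlog))
    start <- params$chrom_offset + cumsum(gap) + c(0, cumsum(len[-n]))
    tibble::tibble(chrom = paste0("chr", ch), chrom_index = ch,
                   start = start, end = start + len,
                   id = sprintf("chr%d_exon%04d", ch, seq_len(n)))
  })
}

# implant events: returns the truth interval table, the per-exon event index
# (NA when diploid) and each event's depth multiplier
sim_events <- function(targets, params) {
  n <- nrow(targets)
  ev_id <- rep(NA_integer_, n)
  ev_mult <- numeric(0)
  truth <- list()
  p_span <- 1 / params$event_span_mean
  for (ch in unique(targets$chrom_index)) {
    idx <- which(targets$chrom_index == ch)
    i <- 1L
    while (i <= length(idx)) {
      u <- runif(1)
      type <- if (u < params$del_rate) "DEL"
              else if (u < params$del_rate + params$dup_rate) "DUP"
              else NA_character_
      if (is.na(type)) { i <- i + 1L; next }
      span <- min(1L + rgeom(1, p_span), length(idx) - i + 1L)
      hom <- runif(1) < params$hom_fraction
      m <- if (type == "DEL") {
        if (hom) 0 else params$del_multiplier
      } else {
        if (hom) 2 * params$dup_multiplier - 1 else params$dup_multiplier
      }
      rows <- idx[i:(i + span - 1L)]
      first <- rows[1]; last <- rows[length(rows)]
      if (params$breakpoint_mode == "exon") {
        # boundary breakpoints fall inside the boundary exons, so those
        # exons carry a within-exon depth step and a majority-base label
        ev_start <- floor(runif(1, targets$start[first], targets$end[first]))
        ev_end <- ceiling(runif(1, targets$start[last] + 1, targets$end[last]))
        if (ev_end <= ev_start) ev_end <- ev_start + 1
      } else {
        ev_start <- targets$start[first]
        ev_end <- targets$end[last]
      }
      k <- length(truth) + 1L
      ev_id[rows] <- k
      ev_mult <- c(ev_mult, m)
      truth[[k]] <- tibble::tibble(
        chrom = targets$chrom[first], chrom_index = ch,
        start = ev_start, end = ev_end, call = type)
      i <- i + span
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(chrom = character(), chrom_index = integer(),
                   start = numeric(), end = numeric(), call = character())
  list(truth = truth, ev_id = ev_id, ev_mult = ev_mult)
}

# per-base depth draw for one exon; mu is a per-base mean vector
sim_exon_depth <- function(len, mu, params) {
  if (all(mu <= 0)) return(integer(len))
  d <- if (is.finite(params$dispersion)) {
    rnbinom(len, size = params$dispersion, mu = mu)
  } else stats::rpois(len, mu)
  w <- params$smooth_window
  if (w > 1L && len > 1L) {
    # centered moving average with shrinking edge windows; preserves the mean
    cs <- cumsum(c(0, d))
    half <- w %/% 2L
    lo <- pmax(seq_len(len) - half, 1L)
    hi <- pmin(seq_len(len) + half, len)
    d <- round((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  }
  as.integer(d)
}

#' Simulate one WES sample
#'
#' Draws a capture design (unless `targets` is supplied), implants DEL/DUP
#' events, and emits the three files a real run starts from: the target BED,
#' a sparse per-base depth table (1-based positions, zero-depth bases
#' omitted), and the truth call intervals — plus the per-exon truth labels
#' they induce. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()].
#' @param targets Optional pre-drawn targets tibble (a cohort's shared
#'   capture design).
#' @return A `cnv_sim` list: `targets`, `depth` (tibble `chrom, pos,
#'   depth`), `truth`, `labels` (targets + `label`, `multiplier`,
#'   `no_depth`), `params`.
#' @export
simulate_sample <- function(params = sim_params(), targets = NULL) {
  stopifnot(inherits(params, "cnv_sim_params"))
  withr::with_seed(params$seed, {
    if (is.null(targets)) targets <- sim_targets(params)
    ev <- sim_events(targets, params)
    n <- nrow(targets)
    no_depth <- rep(FALSE, n)
    k <- floor(params$no_depth_fraction * n)
    if (k > 0) no_depth[sample.int(n, k)] <- TRUE
    depth <- purrr::map_dfr(seq_len(n), function(i) {
      if (no_depth[i]) return(NULL)
      len <- targets$end[i] - targets$start[i]
      mu <- rep(params$base_coverage, len)
      if (!is.na(ev$ev_id[i])) {
        tr <- ev$truth[ev$ev_id[i], ]
        a <- max(tr$start, targets$start[i]) - targets$start[i]
        b <- min(tr$end, targets$end[i]) - targets$start[i]
        if (b > a) mu[(a + 1):b] <- mu[(a + 1):b] * ev$ev_mult[ev$ev_id[i]]
      }
      d <- sim_exon_depth(len, mu, params)
      keep <- d > 0
      if (!any(keep)) return(NULL)
      tibble::tibble(chrom = targets$chrom[i],
                     pos = targets$start[i] + which(keep),  # 1-based
                     depth = d[keep])
    })
    labels <- targets
    labels$label <- overlap_majority(targets, ev$truth)
    labels$multiplier <- ifelse(is.na(ev$ev_id), 1, ev$ev_mult[ev$ev_id])
    labels$no_depth <- no_depth
    structure(list(targets = targets, depth = depth, truth = ev$truth,
                   labels = labels, params = params),
              class = "cnv_sim")
  })
}

#' Simulate a cohort sharing one capture design
#'
#' All samples share the target BED (the same "capture kit"); event
#' placement and depth noise are independent per sample, each driven by a
#' seed derived from `params$seed` by a fixed offset.
#'
#' @param params A [sim_params()].
#' @param n_samples Number of samples (>= 1).
#' @return A list with `targets` (shared) and `samples` (list of `cnv_sim`).
#' @export
simulate_cohort <- function(params = sim_params(), n_samples = 2L) {
  stopifnot(n_samples >= 1L)
  targets <- withr::with_seed(params$seed, sim_targets(params))
  samples <- purrr::map(seq_len(n_samples), function(i) {
    p_i <- params
    p_i$seed <- params$seed + 1000L * i
    simulate_sample(p_i, targets = targets)
  })
  list(targets = targets, samples = samples)
}

#' Write a simulated sample to disk
#'
#' Emits `targets.bed`, `depth.tsv` and `truth.bed` in the standard formats
#' consumed by [read_exon_targets()], [read_depth_table()] and
#' [read_truth_calls()].
#'
#' @param sim A `cnv_sim` from [simulate_sample()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$targets$chrom, sim$targets$start,
                     sim$targets$end, sim$targets$id),
             file.path(dir, "targets.bed"))
  readr::write_tsv(sim$depth, file.path(dir, "depth.tsv"),
                   col_names = FALSE, progress = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$truth$chrom,
                     as.integer(sim$truth$start), as.integer(sim$truth$end),
                     sim$truth$call),
             file.path(dir, "truth.bed"))
  invisible(dir)
}
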