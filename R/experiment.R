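BAR_WIDTHS_DEG <- c(0.13, 0.26, 0.39, 0.53)
EXP1_SPEEDS <- c(2.6, 13.2)
EXP2_SPEEDS <- c(2.6, 5.3, 7.9, 10.5, 13.2)
EXP2_SPACINGS <- seq(0.2, 2.0, by = 0.2)

#' Experiment designs
#'
#' Trial lists for the two width-matching / rating experiments.
#' Experiment 1: four bar widths (0.13, 0.26, 0.39, 0.53 deg) x two speeds
#' (2.6, 13.2 deg/s) x 15 repetitions at a fixed 0.4 deg spacing = 120
#' trials. Experiment 2: the same four widths x five speeds (2.6-13.2
#' deg/s) x ten spacings (0.2-2.0 deg) x 10 repetitions = 2000 trials,
#' i.e. 50 (speed x spacing) condition cells. Trial order is shuffled by
#' `seed`; the multiset of conditions is seed-invariant.
#'
#' @param seed Integer seed for the trial-order shuffle.
#' @return A tibble with columns `trial`, `width_deg`, `speed_deg_s`,
#'   `spacing_deg`, `rep`.
#' @examples
#' nrow(design_experiment1(1))  # 120
#' nrow(design_experiment2(1))  # 2000
#' @export
design_experiment1 <- function(seed = 1) {
  grid <- tidyr::expand_grid(width_deg = BAR_WIDTHS_DEG,
                             speed_deg_s = EXP1_SPEEDS,
                             rep = 1:15)
  grid$spacing_deg <- 0.4
  shuffle_design(grid, seed)
}

#' @rdname design_experiment1
#' @export
design_experiment2 <- function(seed = 1) {
  grid <- tidyr::expand_grid(width_deg = BAR_WIDTHS_DEG,
                             speed_deg_s = EXP2_SPEEDS,
                             spacing_deg = EXP2_SPACINGS,
                             rep = 1:10)
  shuffle_design(grid, seed)
}

shuffle_design <- function(grid, seed) {
  ord <- withr::with_seed(seed, sample.int(nrow(grid)))
  out <- grid[ord, ]
  out$trial <- seq_len(nrow(out))
  dplyr::relocate(out, "trial")
}

#' Simulated-observer parameters
#'
#' The observer is a minimal mechanistic chain
#' display -> noise -> temporal gate -> edge recovery -> decision. Detection
#' is a soft SOA threshold: the probability of integrating the events into
#' an illusory bar is `plogis((soa_threshold_ms - SOA) / threshold_softness_ms)`
#' (a hard step when `threshold_softness_ms = 0`), with SOA taken at
#' millisecond precision (the display clock). On detection the event
#' schedule (perturbed by Gaussian position/time noise) is gated and the bar
#' estimated; the width response is the candidate width nearest the
#' estimate (ties to the lower index) and the rating is
#' `round(1 + 6 * p_detect)` — a monotone decreasing map of SOA onto 1..7.
#' On failure the observer defaults to the narrowest width and a rating
#' of 1. With probability `lapse_rate` the width choice is uniform at
#' random.
#'
#' @param soa_threshold_ms Detection threshold on SOA (default 76 ms).
#' @param threshold_softness_ms Logistic softness; 0 = hard step.
#' @param time_noise_sd_ms,position_noise_sd_deg Gaussian perturbations of
#'   event times and positions.
#' @param lapse_rate Probability of a uniform random width choice.
#' @param n_dots Dots in the simulated array per trial.
#' @return A list of class `sbf_observer`.
#' @export
observer_params <- function(soa_threshold_ms = 76, threshold_softness_ms = 0,
                            time_noise_sd_ms = 0, position_noise_sd_deg = 0,
                            lapse_rate = 0, n_dots = 9) {
  stopifnot(soa_threshold_ms > 0, threshold_softness_ms >= 0,
            time_noise_sd_ms >= 0, position_noise_sd_deg >= 0,
            lapse_rate >= 0, lapse_rate <= 1, n_dots >= 5)
  structure(list(soa_threshold_ms = soa_threshold_ms,
                 threshold_softness_ms = threshold_softness_ms,
                 time_noise_sd_ms = time_noise_sd_ms,
                 position_noise_sd_deg = position_noise_sd_deg,
                 lapse_rate = lapse_rate, n_dots = n_dots),
            class = "sbf_observer")
}

#' Simulate observer responses for a trial list
#'
#' Runs the mechanistic observer of [observer_params()] on every trial of a
#' design: the display's event schedule is generated from its (spacing,
#' speed, width) condition, perturbed by noise, gated, and fed to
#' [estimate_bar()]; the 4AFC width choice and the 1-7 illusory-strength
#' rating are derived from the outcome. Timing covariates (SOA, ISI, EOD)
#' are attached to every trial.
#'
#' @param design A design tibble from [design_experiment1()] or
#'   [design_experiment2()].
#' @param params An [observer_params()].
#' @param seed Integer seed for the observer's noise and lapses.
#' @param config A [recovery_config()] used by the gating/recovery stage.
#' @return The design tibble with added columns `soa_ms`, `isi_ms`,
#'   `eod_ms`, `p_detect`, `detected`, `estimated_width_deg`,
#'   `chosen_width_index`, `chosen_width_deg`, `rating`.
#' @export
simulate_observer <- function(design, params = observer_params(), seed = 1,
                              config = recovery_config()) {
  timing <- timing_from_bar(design$spacing_deg,
                            width_deg = design$width_deg,
                            speed_deg_s = design$speed_deg_s)
  soa_clock <- round(timing$soa_ms)
  p <- if (params$threshold_softness_ms > 0) {
    stats::plogis((params$soa_threshold_ms - soa_clock) /
                    params$threshold_softness_ms)
  } else {
    as.numeric(soa_clock <= params$soa_threshold_ms)
  }

  withr::with_seed(seed, {
    detected <- stats::runif(nrow(design)) < p
    lapses <- stats::runif(nrow(design)) < params$lapse_rate
    lapse_choice <- sample.int(4L, nrow(design), replace = TRUE)

    est_width <- rep(NA_real_, nrow(design))
    # schedules are deterministic per condition; only noise varies per trial
    for (i in which(detected)) {
      geom <- build_sawtooth(design$spacing_deg[i], n_dots = params$n_dots)
      bar <- virtual_bar(width_deg = design$width_deg[i],
                         speed_deg_s = design$speed_deg_s[i])
      sched <- schedule_bar_events(geom, bar)
      if (params$time_noise_sd_ms > 0)
        sched$time_ms <- sched$time_ms +
          stats::rnorm(nrow(sched), sd = params$time_noise_sd_ms)
      if (params$position_noise_sd_deg > 0) {
        sched$x_deg <- sched$x_deg +
          stats::rnorm(nrow(sched), sd = params$position_noise_sd_deg)
        sched$y_deg <- sched$y_deg +
          stats::rnorm(nrow(sched), sd = params$position_noise_sd_deg)
      }
      sched$time_ms <- sched$time_ms - min(sched$time_ms)
      est <- estimate_bar(sched, config)
      if (est$percept == "sbf" && !is.na(est$width_deg))
        est_width[i] <- est$width_deg
    }
  })

  got_width <- !is.na(est_width)
  choice <- rep(1L, nrow(design))  # default to the narrowest width
  choice[got_width] <- vapply(est_width[got_width], function(w) {
    which.min(abs(BAR_WIDTHS_DEG - w))  # ties resolve to the lower index
  }, integer(1))
  choice[lapses] <- lapse_choice[lapses]
  rating <- ifelse(got_width, pmin(7, pmax(1, round(1 + 6 * p))), 1L)

  out <- dplyr::bind_cols(design, timing)
  out$p_detect <- p
  out$detected <- detected
  out$estimated_width_deg <- est_width
  out$chosen_width_index <- choice
  out$chosen_width_deg <- BAR_WIDTHS_DEG[choice]
  out$rating <- as.integer(rating)
  out
}

#' Analyze simulated (or recorded) trial results
#'
#' Reproduces the published analysis pipeline: within every
#' (speed x spacing) cell, the judged width (the degree value of the chosen
#' alternative) is regressed on the true width — the slope is the size
#' perception accuracy, 1 for veridical width perception and 0 when
#' responses carry no width information — and ratings are averaged across
#' widths; the concordance between the two measures is the Spearman rank
#' correlation between the per-cell slopes and mean ratings.
#'
#' @param results Trial tibble from [simulate_observer()] (needs
#'   `speed_deg_s`, `spacing_deg`, `width_deg`, `chosen_width_deg`,
#'   `rating`).
#' @return An object of class `sbf_analysis`: list with `cells` (tibble of
#'   `speed_deg_s`, `spacing_deg`, `soa_ms`, `slope`, `mean_rating`, `n`)
#'   and `spearman_rho`.
#' @export
analyze_results <- function(results) {
  cells <- results |>
    dplyr::group_by(.data$speed_deg_s, .data$spacing_deg) |>
    dplyr::summarise(
      soa_ms = 1000 * .data$spacing_deg[1] / .data$speed_deg_s[1],
      slope = cell_slope(.data$width_deg, .data$chosen_width_deg),
      mean_rating = mean(.data$rating),
      n = dplyr::n(),
      .groups = "drop"
    )
  rho <- if (nrow(cells) >= 2 && !anyNA(cells$slope) &&
             stats::sd(cells$slope) > 0 && stats::sd(cells$mean_rating) > 0)
    stats::cor(cells$slope, cells$mean_rating, method = "spearman")
  else NA_real_  # concordance undefined for a constant measure
  structure(list(cells = cells, spearman_rho = rho),
            class = "sbf_analysis")
}

cell_slope <- function(true_width, judged_width) {
  if (length(unique(true_width)) < 2) return(NA_real_)  # degenerate cell
  stats::cov(judged_width, true_width) / stats::var(true_width)
}

#' Replot trial results by display timing
#'
#' Annotates every condition with its (SOA, EOD, ISI) triple via the timing
#' identities and aggregates mean rating and width-choice accuracy over
#' timing bins (nearest millisecond), the representation in which the
#' temporal limit of SBF is visible: ratings collapse onto a declining
#' function of SOA with EOD modulating intermediate SOAs, and rows with
#' `EOD > SOA` are exactly the overlapping-occlusion conditions `w > h`.
#'
#' @param results Trial tibble from [simulate_observer()].
#' @return A tibble keyed by (`soa_bin_ms`, `eod_bin_ms`) with `isi_bin_ms`,
#'   `mean_rating`, `prop_correct_width`, `n`.
#' @export
replot_by_timing <- function(results) {
  if (nrow(results) == 0)
    return(tibble::tibble(soa_bin_ms = double(), eod_bin_ms = double(),
                          isi_bin_ms = double(), mean_rating = double(),
                          prop_correct_width = double(), n = integer()))
  results |>
    dplyr::mutate(soa_bin_ms = round(.data$soa_ms),
                  eod_bin_ms = round(.data$eod_ms),
                  isi_bin_ms = .data$soa_bin_ms - .data$eod_bin_ms) |>
    dplyr::group_by(.data$soa_bin_ms, .data$eod_bin_ms, .data$isi_bin_ms) |>
    dplyr::summarise(
      mean_rating = mean(.data$rating),
      prop_correct_width = mean(.data$chosen_width_deg == .data$width_deg),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$soa_bin_ms, .data$eod_bin_ms)
}

#' Estimate the SOA threshold from per-cell slopes (change-point fit)
#'
#' Fits a step function `slope = a` for `SOA <= tau`, `slope = b` otherwise,
#' over candidate change points midway between consecutive distinct cell
#' SOAs, and returns the `tau` minimizing the residual sum of squares. Used
#' to recover the observer's temporal threshold from the slope-vs-SOA
#' pattern.
#'
#' @param analysis An `sbf_analysis` (or its `cells` tibble).
#' @return The estimated threshold (ms).
#' @export
estimate_soa_threshold <- function(analysis) {
  cells <- if (inherits(analysis, "sbf_analysis")) analysis$cells
           else analysis
  soa <- cells$soa_ms
  slope <- cells$slope
  us <- sort(unique(soa))
  if (length(us) < 2) return(NA_real_)
  cands <- (us[-1] + us[-length(us)]) / 2
  sse <- vapply(cands, function(tau) {
    lo <- soa <= tau
    sum((slope[lo] - mean(slope[lo]))^2) +
      sum((slope[!lo] - mean(slope[!lo]))^2)
  }, numeric(1))
  cands[which.min(sse)]
}
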