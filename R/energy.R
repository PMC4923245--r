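#' Build a bank of spatiotemporal motion-energy filters
#'
#' Constructs oriented quadrature-pair filters (even/odd spatial Gabor under
#' a Gaussian envelope, complex-exponential temporal carrier under an even
#' Gaussian temporal envelope). The default scales pair small filters at the
#' inter-element scale with a large detector whose envelope spans the full
#' height of the sawtooth pattern — the configuration in which a motion
#' filter can act as a spatiotemporal edge detector for sparse
#' transformation events.
#'
#' @param geometry Element geometry the filters will view.
#' @param orientations_deg Preferred spatial (edge) orientations.
#' @param speeds_deg_s Preferred drift speeds along the filter normal.
#' @param scales_deg Envelope extents (deg); default
#'   `c(spacing, max(sawtooth height, spacing))`.
#' @param sf_cpd Spatial frequencies (cycles/deg); default `1 / (2 * scale)`
#'   per scale (one cycle across the envelope), giving broad tuning.
#' @param temporal_scale_ms Temporal envelope sigma-extent (default 50 ms).
#' @param directions Preferred directions along the normal (`+1`, `-1`).
#' @return A tibble of class `sbf_filter_bank`, one row per filter
#'   (quadrature pair implied): `filter_id`, `center_x`, `center_y`,
#'   `orientation_deg`, `scale_deg`, `sf_cpd`, `temporal_scale_ms`,
#'   `speed_deg_s`, `direction`.
#' @export
build_filter_bank <- function(geometry, orientations_deg = c(90, 60),
                              speeds_deg_s = 10, scales_deg = NULL,
                              sf_cpd = NULL, temporal_scale_ms = 50,
                              directions = c(1, -1)) {
  if (!length(orientations_deg) || !length(speeds_deg_s))
    stop("Orientation and speed lists must be non-empty.", call. = FALSE)
  height <- diff(range(geometry$y_deg))
  width <- diff(range(geometry$x_deg))
  spacing <- attr(geometry, "spacing_deg") %||%
    min(diff(sort(unique(geometry$x_deg))))
  if (is.null(scales_deg))
    scales_deg <- unique(c(spacing, max(height, spacing)))
  field_max <- max(width, height, spacing)
  if (any(scales_deg > field_max)) {
    warning("Filter envelope larger than the element field; clipping.",
            call. = FALSE)
    scales_deg <- pmin(scales_deg, field_max)
  }
  grid <- tidyr::expand_grid(
    orientation_deg = orientations_deg %% 180,
    scale_deg = scales_deg,
    speed_deg_s = speeds_deg_s,
    direction = directions
  )
  grid$sf_cpd <- if (is.null(sf_cpd)) 1 / (2 * grid$scale_deg) else sf_cpd
  out <- tibble::tibble(
    filter_id = seq_len(nrow(grid)),
    center_x = mean(range(geometry$x_deg)),
    center_y = mean(range(geometry$y_deg)),
    grid,
    temporal_scale_ms = temporal_scale_ms
  )
  structure(out, class = c("sbf_filter_bank", class(out)))
}

#' Apply a motion-energy filter bank to a movie
#'
#' For each filter, the movie's frames are projected onto the even and odd
#' spatial kernels (the quadrature pair), giving a complex spatial response
#' per frame; this time series is convolved (full convolution, zero-padded)
#' with a complex temporal kernel `gaussian(t) * exp(i * direction * w * t)`
#' whose frequency `w` matches the filter's preferred speed; the energy is
#' the sum over all time lags of the squared modulus. The even spatial
#' kernel is made mean-zero, so a uniform movie yields exactly zero energy,
#' and the even temporal envelope makes time reversal of the movie swap the
#' energies of direction-paired filters.
#'
#' @param movie An `sbf_movie` from [rasterize_schedule()].
#' @param bank An `sbf_filter_bank`.
#' @return The bank tibble with an added `energy` column (class
#'   `sbf_energy`).
#' @export
apply_energy <- function(movie, bank) {
  dims <- dim(movie$frames)
  ny <- dims[1]; nx <- dims[2]; nt <- dims[3]
  px <- movie$x0_deg + (seq_len(nx) - 1) / movie$px_per_deg
  py <- movie$y0_deg + (seq_len(ny) - 1) / movie$px_per_deg
  flat <- matrix(movie$frames, nrow = ny * nx, ncol = nt)
  dt <- movie$frame_duration_ms

  energies <- purrr::map_dbl(seq_len(nrow(bank)), function(i) {
    f <- bank[i, ]
    th <- f$orientation_deg * pi / 180
    n <- c(sin(th), -cos(th))   # unit normal to the preferred orientation
    ax <- c(cos(th), sin(th))   # along the preferred orientation
    X <- outer(rep(1, ny), px - f$center_x)
    Y <- outer(py - f$center_y, rep(1, nx))
    u <- n[1] * X + n[2] * Y
    w <- ax[1] * X + ax[2] * Y
    sigma <- f$scale_deg / 4
    env <- exp(-(u^2 + w^2) / (2 * sigma^2))
    # mean-center both kernels: discrete clipping breaks exact (anti)symmetry
    even <- env * cos(2 * pi * f$sf_cpd * u)
    even <- even - mean(even)
    odd <- env * sin(2 * pi * f$sf_cpd * u)
    odd <- odd - mean(odd)
    z <- as.vector(crossprod(flat, as.vector(even) + 1i * as.vector(odd)))

    sig_t <- f$temporal_scale_ms / 4
    half <- max(1L, ceiling(3 * sig_t / dt))
    tk <- (-half:half) * dt
    if (nt * dt < 2 * half * dt)
      warning("Movie shorter than the filter's temporal support; ",
              "zero-padding.", call. = FALSE)
    w_ms <- 2 * pi * f$speed_deg_s * f$sf_cpd / 1000  # rad per ms
    kern <- exp(-tk^2 / (2 * sig_t^2)) *
      exp(1i * f$direction * w_ms * tk)
    # full (zero-padded) complex convolution
    nL <- nt + length(kern) - 1L
    L <- complex(nL)
    for (j in seq_along(kern)) {
      idx <- seq_len(nt) + (j - 1L)
      L[idx] <- L[idx] + z * kern[j]
    }
    sum(Mod(L)^2)
  })
  out <- dplyr::mutate(tibble::as_tibble(bank), energy = energies)
  structure(out, class = c("sbf_energy", class(out)))
}

#' Constant-velocity readout over candidate orientations
#'
#' The testable form of the population-readout conjecture: a moving straight
#' edge of the correct orientation crosses the event positions at times that
#' are a perfectly linear function of the position projected onto the edge
#' normal. For each candidate orientation the event times are regressed on
#' the projected coordinate; the linearity score is `1 - RSS/TSS` (the R^2
#' of that regression) and the winning candidate is the one whose space-time
#' points lie closest to a straight line. The recovered speed is the inverse
#' regression slope.
#'
#' @param events Data frame of >= 3 same-kind events (`x_deg`, `y_deg`,
#'   `time_ms`).
#' @param candidate_orientations_deg Candidate edge orientations (deg).
#' @return A tibble of class `sbf_readout` with columns `orientation_deg`,
#'   `speed_deg_s`, `linearity`, `winner` (logical); attribute `winner`
#'   holds the winning row. With fewer than three events, a zero-row tibble
#'   with attribute `status = "insufficient"`.
#' @export
constant_velocity_readout <- function(events, candidate_orientations_deg) {
  empty <- tibble::tibble(orientation_deg = double(), speed_deg_s = double(),
                          linearity = double(), winner = logical())
  if (nrow(events) < 3)
    return(structure(empty, class = c("sbf_readout", class(empty)),
                     status = "insufficient"))
  t <- events$time_ms
  tss <- sum((t - mean(t))^2)
  rows <- purrr::map_dfr(candidate_orientations_deg, function(theta) {
    th <- theta * pi / 180
    proj <- sin(th) * events$x_deg - cos(th) * events$y_deg
    if (stats::sd(proj) == 0)
      return(tibble::tibble(orientation_deg = theta %% 180,
                            speed_deg_s = NA_real_, linearity = -Inf))
    fit <- stats::.lm.fit(cbind(1, proj), t)
    lin <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
    slope <- fit$coefficients[2]
    tibble::tibble(orientation_deg = theta %% 180,
                   speed_deg_s = 1000 / abs(slope), linearity = lin)
  })
  rows$winner <- seq_len(nrow(rows)) == which.max(rows$linearity)
  structure(rows, class = c("sbf_readout", class(rows)),
            status = "ok", winner = rows[rows$winner, ])
}
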