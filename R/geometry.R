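#' Build a sawtooth element array
#'
#' Constructs the dot array used in the minimal SBF displays: dots spaced
#' evenly in x, with y following a triangle wave so that consecutive dots are
#' never collinear for more than a half-cycle. The y-offset cycle is
#' `0, s, 2s, s` repeating (period four columns), so a rise-fall excursion
#' touches five dots and the peak-to-trough extent of the dot centers is
#' `2 * vertical_step_deg`.
#'
#' @param spacing_deg Horizontal center-to-center dot spacing, degrees of
#'   visual angle. Must be positive.
#' @param n_dots Number of dots (>= 3).
#' @param vertical_step_deg Vertical step between consecutive dots; defaults
#'   to `spacing_deg` (equal horizontal and vertical separations).
#' @param dots_per_cycle Dots per rise-fall cycle, counting the closing dot;
#'   only 5 (the standard sawtooth) is supported.
#' @param dot_diameter_deg Dot diameter in degrees (default 7.9 arcmin).
#'
#' @return A tibble of class `sbf_geometry` with columns `element_id`,
#'   `x_deg`, `y_deg`, and attributes `spacing_deg`, `vertical_step_deg`,
#'   `dots_per_cycle`, `dot_diameter_deg`.
#'
#' @examples
#' geom <- build_sawtooth(0.4, n_dots = 33)
#' sawtooth_extent(geom)   # peak-to-trough extent: 0.8 deg
#' @export
build_sawtooth <- function(spacing_deg, n_dots,
                           vertical_step_deg = spacing_deg,
                           dots_per_cycle = 5,
                           dot_diameter_deg = 7.9 / 60) {
  if (!is.numeric(spacing_deg) || length(spacing_deg) != 1 || spacing_deg <= 0)
    stop("`spacing_deg` must be a single positive number.", call. = FALSE)
  if (!is.numeric(n_dots) || length(n_dots) != 1 || n_dots < 3 ||
      n_dots != round(n_dots))
    stop("`n_dots` must be an integer >= 3.", call. = FALSE)
  if (vertical_step_deg <= 0)
    stop("`vertical_step_deg` must be positive.", call. = FALSE)
  if (dots_per_cycle != 5)
    stop("Only the standard five-dots-per-cycle sawtooth is supported.",
         call. = FALSE)

  i <- seq_len(n_dots) - 1L
  # triangle wave 0, s, 2s, s, 0, s, 2s, ... (period 4 columns)
  phase <- i %% 4L
  y <- vertical_step_deg * ifelse(phase == 0L, 0,
                           ifelse(phase == 1L, 1,
                           ifelse(phase == 2L, 2, 1)))
  out <- tibble::tibble(
    element_id = seq_len(n_dots),
    x_deg = i * spacing_deg,
    y_deg = y
  )
  structure(out,
            class = c("sbf_geometry", class(out)),
            spacing_deg = spacing_deg,
            vertical_step_deg = vertical_step_deg,
            dots_per_cycle = dots_per_cycle,
            dot_diameter_deg = dot_diameter_deg)
}

#' Peak-to-trough vertical extent of a sawtooth geometry
#'
#' @param geometry A geometry tibble from [build_sawtooth()].
#' @return Vertical extent of the dot centers in degrees
#'   (`2 * vertical_step_deg` for any full cycle).
#' @export
sawtooth_extent <- function(geometry) {
  diff(range(geometry$y_deg))
}

#' Define a virtual bar
#'
#' The virtual bar is the unseen occluder whose passage over the element
#' array triggers the transformation events; it is never rendered by
#' luminance contrast. `orientation_deg` is the angle of the bar's long axis
#' from horizontal (90 = vertical); the bar translates along
#' `motion_direction` (default rightward).
#'
#' @param width_deg Bar width (degrees), > 0 (0 is allowed as the degenerate
#'   zero-width edge).
#' @param speed_deg_s Translation speed along `motion_direction`, deg/s, > 0.
#' @param orientation_deg Long-axis angle from horizontal, degrees. Must not
#'   be parallel to the motion direction.
#' @param motion_direction Length-2 numeric, direction of translation
#'   (normalized internally). Default `c(1, 0)`.
#' @param start_x_deg Position of the leading edge along the motion normal at
#'   time 0, expressed as the signed distance `n . p` (see
#'   [schedule_bar_events()]); `NA` (default) lets the scheduler start the
#'   bar just before the first element it will reach.
#'
#' @return A one-row tibble of class `sbf_bar`.
#' @examples
#' virtual_bar(width_deg = 0.53, speed_deg_s = 13.2)
#' @export
virtual_bar <- function(width_deg, speed_deg_s, orientation_deg = 90,
                        motion_direction = c(1, 0), start_x_deg = NA_real_) {
  if (!is.numeric(width_deg) || length(width_deg) != 1 || width_deg < 0 ||
      !is.finite(width_deg))
    stop("`width_deg` must be a single non-negative number.", call. = FALSE)
  if (!is.numeric(speed_deg_s) || length(speed_deg_s) != 1 ||
      speed_deg_s <= 0 || !is.finite(speed_deg_s))
    stop("`speed_deg_s` must be a single positive number.", call. = FALSE)
  if (length(motion_direction) != 2 || all(motion_direction == 0))
    stop("`motion_direction` must be a non-zero length-2 vector.",
         call. = FALSE)
  dir <- motion_direction / sqrt(sum(motion_direction^2))
  axis <- c(cos(orientation_deg * pi / 180), sin(orientation_deg * pi / 180))
  # normal component of motion; zero means the bar slides along itself
  if (abs(dir[1] * -axis[2] + dir[2] * axis[1]) < 1e-12)
    stop("Bar orientation must not be parallel to the motion direction.",
         call. = FALSE)
  out <- tibble::tibble(
    width_deg = width_deg,
    speed_deg_s = speed_deg_s,
    orientation_deg = orientation_deg %% 180,
    dir_x = dir[1],
    dir_y = dir[2],
    start_x_deg = start_x_deg
  )
  structure(out, class = c("sbf_bar", class(out)))
}

#' Timing triple (SOA, ISI, EOD) of a display condition
#'
#' The three temporal parameters of a sequential-transformation display:
#' element offset duration (EOD, how long an element stays invisible),
#' inter-stimulus interval (ISI, time between one element's reappearance and
#' the next element's disappearance; negative when occlusions overlap), and
#' stimulus onset asynchrony (SOA = ISI + EOD, time between successive
#' disappearances). Supply exactly two of the three; the identity
#' `soa = isi + eod` fills in the third and is enforced exactly.
#'
#' @param soa_ms,isi_ms,eod_ms Durations in milliseconds. `eod_ms >= 0`,
#'   `soa_ms > 0`; `isi_ms` may be negative.
#' @return A one-row tibble of class `sbf_timing` with columns `soa_ms`,
#'   `isi_ms`, `eod_ms`.
#' @examples
#' timing_triple(soa_ms = 40, isi_ms = 0)   # EOD = 40 ms
#' @export
timing_triple <- function(soa_ms = NULL, isi_ms = NULL, eod_ms = NULL) {
  given <- !vapply(list(soa_ms, isi_ms, eod_ms), is.null, logical(1))
  if (sum(given) < 2)
    stop("Supply at least two of `soa_ms`, `isi_ms`, `eod_ms`.",
         call. = FALSE)
  if (is.null(soa_ms)) soa_ms <- isi_ms + eod_ms
  if (is.null(isi_ms)) isi_ms <- soa_ms - eod_ms
  if (is.null(eod_ms)) eod_ms <- soa_ms - isi_ms
  if (abs(soa_ms - (isi_ms + eod_ms)) > 0)
    stop("Inconsistent timing: soa_ms must equal isi_ms + eod_ms exactly.",
         call. = FALSE)
  if (eod_ms < 0) stop("`eod_ms` must be >= 0.", call. = FALSE)
  if (soa_ms <= 0) stop("`soa_ms` must be > 0.", call. = FALSE)
  out <- tibble::tibble(soa_ms = soa_ms, isi_ms = isi_ms, eod_ms = eod_ms)
  structure(out, class = c("sbf_timing", class(out)))
}

#' Display timing from physical bar parameters
#'
#' Converts a virtual bar's width and speed, together with the horizontal
#' element separation `h`, into the display timing triple via the identities
#' `v = h / SOA` (the bar reaches the next element after travelling `h`) and
#' `w = v * EOD` (an element is occluded while the bar passes over it), with
#' `ISI = SOA - EOD`. ISI is negative when `w > h` (overlapping occlusions).
#'
#' @param h_deg Horizontal element separation, degrees, > 0.
#' @param bar An [virtual_bar()] object, or `NULL` if `width_deg` and
#'   `speed_deg_s` are given directly.
#' @param width_deg,speed_deg_s Bar width and speed, used when `bar` is NULL.
#'   Vectorized.
#' @return A tibble of class `sbf_timing` with columns `soa_ms`, `isi_ms`,
#'   `eod_ms` (one row per condition).
#' @examples
#' timing_from_bar(0.8, speed_deg_s = 10.5, width_deg = 0.26)  # SOA ~ 76 ms
#' @export
timing_from_bar <- function(h_deg, bar = NULL, width_deg = NULL,
                            speed_deg_s = NULL) {
  if (!is.null(bar)) {
    width_deg <- bar$width_deg
    speed_deg_s <- bar$speed_deg_s
  }
  if (any(h_deg <= 0)) stop("`h_deg` must be positive.", call. = FALSE)
  if (any(speed_deg_s <= 0))
    stop("Bar speed must be positive.", call. = FALSE)
  if (any(width_deg < 0))
    stop("Bar width must be non-negative.", call. = FALSE)
  soa <- 1000 * h_deg / speed_deg_s
  eod <- 1000 * width_deg / speed_deg_s
  out <- tibble::tibble(soa_ms = soa, isi_ms = soa - eod, eod_ms = eod)
  structure(out, class = c("sbf_timing", class(out)))
}

#' Physical bar parameters from display timing
#'
#' Inverse of [timing_from_bar()]: `v = h / SOA`, `w = v * EOD`.
#'
#' @param h_deg Horizontal element separation, degrees, > 0.
#' @param timing An `sbf_timing` tibble (or any data frame with `soa_ms`,
#'   `eod_ms`).
#' @return A tibble with columns `speed_deg_s`, `width_deg`.
#' @export
bar_from_timing <- function(h_deg, timing) {
  if (any(h_deg <= 0)) stop("`h_deg` must be positive.", call. = FALSE)
  if (any(timing$soa_ms <= 0))
    stop("`soa_ms` must be positive.", call. = FALSE)
  v <- 1000 * h_deg / timing$soa_ms
  tibble::tibble(speed_deg_s = v, width_deg = v * timing$eod_ms / 1000)
}
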