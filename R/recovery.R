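#' Recovery configuration
#'
#' Parameters of the temporal-integration gate and the numerical tolerances
#' of the edge solver.
#'
#' @param soa_gate_ms Maximum interval between consecutive transformation
#'   events for them to be integrable into one edge (default 80 ms: ratings
#'   and width accuracy decline steeply past ~76 ms and vanish by ~100 ms).
#' @param window_ms Length of the integration window that must capture at
#'   least three events (default 165 ms; three events at an 80 ms SOA span
#'   160 ms).
#' @param collinearity_tol Normalized triangle-area threshold below which
#'   event positions are treated as collinear (relative to the pairwise
#'   distance scale).
#' @param residual_tol Residual RMS (ms) above which a fit is no longer
#'   reported as a unique edge.
#' @param width_check_tol Relative tolerance for the agreement between the
#'   two bar-width routes (occlusion duration vs. edge-line separation).
#' @return A list of class `sbf_config`.
#' @export
recovery_config <- function(soa_gate_ms = 80, window_ms = 165,
                            collinearity_tol = 1e-9, residual_tol = 10,
                            width_check_tol = 0.25) {
  stopifnot(soa_gate_ms > 0, window_ms >= soa_gate_ms, collinearity_tol > 0,
            residual_tol > 0, width_check_tol > 0)
  structure(list(soa_gate_ms = soa_gate_ms, window_ms = window_ms,
                 collinearity_tol = collinearity_tol,
                 residual_tol = residual_tol,
                 width_check_tol = width_check_tol),
            class = "sbf_config")
}

# normalized area test: are the points collinear at tolerance `tol`?
points_collinear <- function(x, y, tol) {
  cx <- x - mean(x); cy <- y - mean(y)
  sv <- svd(cbind(cx, cy), nu = 0, nv = 0)$d
  scale <- max(sv[1], .Machine$double.xmin)
  (sv[2] / scale) <= tol
}

new_edge_estimate <- function(status, orientation_deg = NA_real_,
                              normal_speed_deg_s = NA_real_,
                              normal = c(NA_real_, NA_real_),
                              time_at_origin_ms = NA_real_,
                              residual_rms = NA_real_, n_events = 0L) {
  structure(list(status = status, orientation_deg = orientation_deg,
                 normal_speed_deg_s = normal_speed_deg_s, normal = normal,
                 time_at_origin_ms = time_at_origin_ms,
                 residual_rms = residual_rms, n_events = n_events),
            class = "sbf_edge")
}

# Core crossing-model fit. A straight edge moving at constant normal speed s
# (deg/ms) along unit normal n crosses position p at time
# t = t0 + (n . p) / s, which is linear in p. Regressing event time on
# position therefore recovers the edge: t = a + g . p with gradient
# g = n / s, so n = g / |g|, s = 1 / |g|, and residuals are in time units.
fit_crossing_model <- function(x, y, t, config) {
  ok <- is.finite(x) & is.finite(y) & is.finite(t)
  if (!all(ok)) stop("Event positions/times must be finite.", call. = FALSE)
  pos <- unique(cbind(x, y))
  if (nrow(pos) < 3) return(new_edge_estimate("insufficient",
                                              n_events = length(x)))
  if (points_collinear(x, y, config$collinearity_tol))
    return(new_edge_estimate("ambiguous_collinear", n_events = length(x)))
  fit <- stats::.lm.fit(cbind(1, x, y), t)
  g <- fit$coefficients[2:3]
  gn <- sqrt(sum(g^2))
  res <- fit$residuals
  rms <- sqrt(mean(res^2))
  # |g| -> 0 means all crossings simultaneous: no finite-speed edge
  tscale <- max(abs(t - mean(t)), 1)
  pscale <- max(abs(c(x - mean(x), y - mean(y))))
  if (gn <= 1e-12 * max(1, tscale / pscale))
    return(new_edge_estimate("inconsistent", residual_rms = rms,
                             n_events = length(x)))
  n <- g / gn
  orientation <- (atan2(n[1], -n[2]) * 180 / pi) %% 180
  status <- if (rms <= config$residual_tol) "unique" else "inconsistent"
  new_edge_estimate(status,
                    orientation_deg = orientation,
                    normal_speed_deg_s = 1000 / gn,
                    normal = n,
                    time_at_origin_ms = fit$coefficients[1],
                    residual_rms = rms,
                    n_events = length(x))
}

#' Recover a local edge from three transformation events
#'
#' Solves the crossing model for exactly three events of the same kind: a
#' straight edge with unit normal `n` moving at constant normal speed `s`
#' crosses each event position at the event time. Three non-collinear
#' events determine orientation (mod 180), normal speed, and direction
#' uniquely. Collinear positions leave the orientation unconstrained (the
#' point-aperture problem) and return status `ambiguous_collinear`;
#' simultaneous times over non-collinear positions admit no finite-speed
#' edge and return `inconsistent`.
#'
#' @param events Data frame with exactly three rows (columns `x_deg`,
#'   `y_deg`, `time_ms`, and optionally `kind`, which must be constant).
#' @param config A [recovery_config()].
#' @return An object of class `sbf_edge`; see [tidy.sbf_edge()].
#' @examples
#' ev <- tibble::tibble(x_deg = c(0, 0.4, 0.8), y_deg = c(0, 0.4, 0.8 - 0.8),
#'                      time_ms = c(0, 40, 80))
#' recover_edge_triple(ev)
#' @export
recover_edge_triple <- function(events, config = recovery_config()) {
  if (nrow(events) != 3)
    stop("`recover_edge_triple()` needs exactly three events.",
         call. = FALSE)
  if ("kind" %in% names(events) && length(unique(events$kind)) != 1)
    stop("The three events must be of the same kind.", call. = FALSE)
  fit_crossing_model(events$x_deg, events$y_deg, events$time_ms, config)
}

#' Recover a local edge from three or more events (least squares)
#'
#' Overdetermined extension of [recover_edge_triple()]: the crossing model is
#' linear in position, so any number of same-kind events is fit by least
#' squares of event time on position. For exactly three non-collinear events
#' the fit is exact and identical to the triple solver. `residual_rms` is
#' reported in milliseconds.
#'
#' @param events Data frame of >= 3 events of one kind (`x_deg`, `y_deg`,
#'   `time_ms`, optional constant `kind`).
#' @param config A [recovery_config()].
#' @return An `sbf_edge` object.
#' @export
recover_edge <- function(events, config = recovery_config()) {
  if (nrow(events) < 3)
    return(new_edge_estimate("insufficient", n_events = nrow(events)))
  if ("kind" %in% names(events) && length(unique(events$kind)) != 1)
    stop("Events must all be of the same kind; filter before fitting.",
         call. = FALSE)
  fit_crossing_model(events$x_deg, events$y_deg, events$time_ms, config)
}

#' Group events under the temporal-integration gate
#'
#' Chains same-kind events whose consecutive inter-event intervals are at
#' most `soa_gate_ms`, keeps chains of at least three events in which some
#' window of `window_ms` captures three consecutive events, and labels each
#' surviving chain with a `group` id. An empty result predicts the
#' apparent-motion percept: no edge can be integrated.
#'
#' @param schedule An event schedule (data frame with `time_ms`, `kind`).
#' @param config A [recovery_config()].
#' @return A tibble of the gated events with an added `group` column;
#'   zero rows when no group survives the gate.
#' @export
gate_events <- function(schedule, config = recovery_config()) {
  df <- tibble::as_tibble(schedule)
  out <- df[0, ]
  out$group <- integer()
  gid <- 0L
  for (kind in unique(df$kind)) {
    ev <- df[df$kind == kind, ]
    ev <- ev[order(ev$time_ms, ev$element_id), ]
    if (nrow(ev) == 0) next
    gaps <- diff(ev$time_ms)
    chain <- cumsum(c(0, gaps > config$soa_gate_ms))
    for (ch in split(ev, chain)) {
      if (nrow(ch) < 3) next
      spans <- ch$time_ms[-(1:2)] - ch$time_ms[seq_len(nrow(ch) - 2)]
      if (!any(spans <= config$window_ms)) next
      gid <- gid + 1L
      ch$group <- gid
      out <- dplyr::bind_rows(out, ch)
    }
  }
  out
}

#' Estimate the virtual bar from a full event schedule
#'
#' Applies the temporal gate, recovers the leading edge from the gated
#' disappearances (`offset`) and the trailing edge from the gated
#' reappearances (`onset`), and estimates the bar width as
#' `normal speed x mean occlusion duration` (the time each element stays
#' invisible is the time the bar takes to pass over it). The width is
#' cross-checked against the perpendicular separation of the two recovered
#' edge lines at a common time; a discrepancy beyond
#' `config$width_check_tol` (relative) flags the schedule as inconsistent.
#'
#' @param schedule An `sbf_schedule`.
#' @param config A [recovery_config()].
#' @return An object of class `sbf_bar_estimate` with fields
#'   `orientation_deg`, `speed_deg_s`, `width_deg` (NA when undefined),
#'   `leading`, `trailing` (both `sbf_edge`), `percept`
#'   (`"sbf"`/`"apparent_motion"`), `status`, `width_from_lines_deg`.
#' @export
estimate_bar <- function(schedule, config = recovery_config()) {
  gated <- gate_events(schedule, config)
  pick_edge <- function(kind) {
    ev <- gated[gated$kind == kind, ]
    if (nrow(ev) == 0) return(list(edge = NULL, events = ev))
    sizes <- table(ev$group)
    best <- as.integer(names(sizes)[which.max(sizes)])
    ev <- ev[ev$group == best, ]
    list(edge = recover_edge(ev, config), events = ev)
  }
  lead <- pick_edge("offset")
  trail <- pick_edge("onset")

  unique_edge <- function(e) !is.null(e) && e$status == "unique"
  if (!unique_edge(lead$edge) && !unique_edge(trail$edge)) {
    return(structure(list(orientation_deg = NA_real_, speed_deg_s = NA_real_,
                          width_deg = NA_real_, leading = lead$edge,
                          trailing = trail$edge, percept = "apparent_motion",
                          status = "no_edge",
                          width_from_lines_deg = NA_real_),
                     class = "sbf_bar_estimate"))
  }
  primary <- if (unique_edge(lead$edge)) lead$edge else trail$edge
  width <- NA_real_
  width_lines <- NA_real_
  status <- "width_undefined"
  if (unique_edge(lead$edge) && unique_edge(trail$edge)) {
    ids <- intersect(lead$events$element_id, trail$events$element_id)
    offs <- lead$events[match(ids, lead$events$element_id), "time_ms",
                        drop = TRUE]
    ons <- trail$events[match(ids, trail$events$element_id), "time_ms",
                        drop = TRUE]
    s_deg_ms <- lead$edge$normal_speed_deg_s / 1000
    if (length(ids) > 0) {
      width <- s_deg_ms * mean(ons - offs)
      width_lines <- s_deg_ms *
        (trail$edge$time_at_origin_ms - lead$edge$time_at_origin_ms)
      rel <- abs(width_lines - width) / max(abs(width), 1e-12)
      status <- if (rel > config$width_check_tol) "inconsistent" else "ok"
      if (status == "inconsistent") width <- NA_real_
    }
  }
  structure(list(orientation_deg = primary$orientation_deg,
                 speed_deg_s = primary$normal_speed_deg_s,
                 width_deg = width,
                 leading = lead$edge, trailing = trail$edge,
                 percept = "sbf", status = status,
                 width_from_lines_deg = width_lines),
            class = "sbf_bar_estimate")
}

#' Predict the percept of a display condition
#'
#' Deterministic SOA-only rule: an illusory bar (`"sbf"`) is predicted
#' exactly when the stimulus onset asynchrony `SOA = h / v` does not exceed
#' the temporal gate; otherwise element-to-element apparent motion is
#' predicted. Vectorized over conditions.
#'
#' @param h_deg Inter-element spacing(s), degrees.
#' @param speed_deg_s Bar speed(s), deg/s.
#' @param config A [recovery_config()].
#' @return Character vector, `"sbf"` or `"apparent_motion"`.
#' @examples
#' predict_percept(c(0.4, 0.4, 0.2), c(13.2, 2.6, 2.6))
#' @export
predict_percept <- function(h_deg, speed_deg_s, config = recovery_config()) {
  soa <- 1000 * h_deg / speed_deg_s
  ifelse(soa <= config$soa_gate_ms, "sbf", "apparent_motion")
}

#' @export
print.sbf_edge <- function(x, ...) {
  cat("<sbf_edge> status:", x$status, "\n")
  if (x$status == "unique")
    cat(sprintf("  orientation %.2f deg | normal speed %.3f deg/s | residual %.3g ms | n = %d\n",
                x$orientation_deg, x$normal_speed_deg_s, x$residual_rms,
                x$n_events))
  invisible(x)
}

#' @export
print.sbf_bar_estimate <- function(x, ...) {
  cat("<sbf_bar_estimate> percept:", x$percept, "| status:", x$status, "\n")
  if (x$percept == "sbf")
    cat(sprintf("  orientation %.2f deg | speed %.3f deg/s | width %.4f deg\n",
                x$orientation_deg, x$speed_deg_s, x$width_deg))
  invisible(x)
}
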