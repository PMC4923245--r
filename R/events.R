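#' @keywords internal
#' Unit normal of a bar's long axis, oriented along the motion direction.
bar_normal <- function(bar) {
  o <- bar$orientation_deg * pi / 180
  n <- c(sin(o), -cos(o))
  if (n[1] * bar$dir_x + n[2] * bar$dir_y < 0) n <- -n
  n
}

new_schedule <- function(events, geometry = NULL, duration_ms = NULL,
                         stimulus = NULL) {
  events <- dplyr::arrange(events, .data$time_ms, .data$element_id)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(events)) max(events$time_ms) else 0
  structure(events,
            class = c("sbf_schedule", setdiff(class(events), "sbf_schedule")),
            geometry = geometry,
            duration_ms = duration_ms,
            stimulus = stimulus)
}

#' Schedule the transformation events produced by a virtual bar
#'
#' Sweeps a virtual bar across an element array and records, for every
#' element the bar passes over, the exact times at which the bar's leading
#' edge reaches the element center (disappearance, `offset`) and its
#' trailing edge passes it (reappearance, `onset`). Times are continuous and
#' exact; quantization to a display refresh happens only in
#' [rasterize_schedule()].
#'
#' For a vertical bar over a sawtooth with horizontal spacing `h` moving at
#' speed `v`, consecutive offsets are separated by exactly `h / v` (the SOA)
#' and each element stays invisible for `w / v` (the EOD). Oblique bars
#' produce element-dependent intervals: shorter between elements on paths
#' parallel to the bar, longer between elements on paths perpendicular to
#' it. When `w > h` several elements are hidden simultaneously (negative
#' ISI).
#'
#' @param geometry Element array tibble (columns `element_id`, `x_deg`,
#'   `y_deg`), e.g. from [build_sawtooth()].
#' @param bar A [virtual_bar()].
#' @param duration_ms Optional truncation time; events after it are dropped.
#' @param reverse_at_edges If `TRUE`, after the sweep completes the bar
#'   reverses direction and sweeps back (events concatenated in time).
#' @return A tibble of class `sbf_schedule` with columns `element_id`,
#'   `x_deg`, `y_deg`, `time_ms`, `kind`; attributes `geometry`,
#'   `duration_ms`, `stimulus` (the generating bar).
#' @examples
#' geom <- build_sawtooth(0.4, n_dots = 9)
#' bar <- virtual_bar(width_deg = 0.53, speed_deg_s = 13.2)
#' sched <- schedule_bar_events(geom, bar)
#' head(sched)
#' @export
schedule_bar_events <- function(geometry, bar, duration_ms = NULL,
                                reverse_at_edges = FALSE) {
  n <- bar_normal(bar)
  proj <- n[1] * geometry$x_deg + n[2] * geometry$y_deg
  # deg per ms travelled along the bar normal
  sn <- bar$speed_deg_s * (n[1] * bar$dir_x + n[2] * bar$dir_y) / 1000
  c0 <- if (is.na(bar$start_x_deg)) min(proj) else bar$start_x_deg
  t_off <- (proj - c0) / sn
  t_on <- t_off + bar$width_deg / sn
  keep <- t_off >= 0
  ev <- tibble::tibble(
    element_id = rep(geometry$element_id[keep], 2L),
    x_deg = rep(geometry$x_deg[keep], 2L),
    y_deg = rep(geometry$y_deg[keep], 2L),
    time_ms = c(t_off[keep], t_on[keep]),
    kind = rep(c("offset", "onset"), each = sum(keep))
  )
  if (reverse_at_edges) {
    t_end <- if (nrow(ev)) max(ev$time_ms) else 0
    back <- bar
    back$dir_x <- -bar$dir_x
    back$dir_y <- -bar$dir_y
    back$start_x_deg <- NA_real_
    ev_back <- schedule_bar_events(geometry, back, reverse_at_edges = FALSE)
    ev_back$time_ms <- ev_back$time_ms + t_end
    ev <- dplyr::bind_rows(ev, as.data.frame(ev_back))
  }
  if (!is.null(duration_ms)) {
    if (duration_ms <= 0) ev <- ev[0, ] else ev <- ev[ev$time_ms <= duration_ms, ]
  }
  new_schedule(ev, geometry = geometry, duration_ms = duration_ms,
               stimulus = bar)
}

# all pairwise proper intersections between non-adjacent polygon edges
polygon_self_intersects <- function(vx, vy) {
  m <- length(vx)
  seg <- cbind(vx, vy, vx[c(2:m, 1)], vy[c(2:m, 1)])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(m - 2)) {
    for (j in (i + 2):m) {
      if (i == 1 && j == m) next  # adjacent through closure
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      denom <- cross2(r[1], r[2], s[1], s[2])
      if (abs(denom) < 1e-14) next
      t <- cross2(q[1] - p[1], q[2] - p[2], s[1], s[2]) / denom
      u <- cross2(q[1] - p[1], q[2] - p[2], r[1], r[2]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9) return(TRUE)
    }
  }
  FALSE
}

#' Schedule property-flip events from a moving virtual polygon
#'
#' Generalization of the bar display to an arbitrary simple polygon moving at
#' constant velocity over a field of point elements carrying a binary
#' property: an element flips one way (`flip_in`) the instant its center
#' enters the polygon and back (`flip_out`) when it exits. Crossing times
#' come from exact line-segment intersection of each element's relative path
#' with the polygon boundary.
#'
#' @param element_field Tibble with `element_id`, `x_deg`, `y_deg`.
#' @param polygon Two-column matrix or data frame of polygon vertices (deg),
#'   implicitly closed. Must be a simple (non-self-intersecting) polygon.
#' @param velocity_deg_s Length-2 velocity vector of the polygon, deg/s.
#' @param transformation_kind `"flip"` (events `flip_in`/`flip_out`) or
#'   `"occlude"` (events `offset`/`onset`).
#' @return An `sbf_schedule` tibble; elements whose centers never fall inside
#'   the polygon contribute no events. A stationary polygon yields an empty
#'   schedule.
#' @export
schedule_shape_events <- function(element_field, polygon, velocity_deg_s,
                                  transformation_kind = c("flip", "occlude")) {
  transformation_kind <- match.arg(transformation_kind)
  kinds <- if (transformation_kind == "flip") c("flip_in", "flip_out")
           else c("offset", "onset")
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("`polygon` must have >= 3 vertices and two columns.", call. = FALSE)
  if (polygon_self_intersects(polygon[, 1], polygon[, 2]))
    stop("`polygon` must be a simple (non-self-intersecting) polygon.",
         call. = FALSE)
  v <- as.numeric(velocity_deg_s) / 1000  # deg per ms
  empty <- tibble::tibble(element_id = integer(), x_deg = double(),
                          y_deg = double(), time_ms = double(),
                          kind = character())
  if (all(v == 0))
    return(new_schedule(empty, geometry = element_field, duration_ms = 0))

  m <- nrow(polygon)
  a <- polygon
  b <- polygon[c(2:m, 1), , drop = FALSE]
  ev <- purrr::map_dfr(seq_len(nrow(element_field)), function(i) {
    p <- c(element_field$x_deg[i], element_field$y_deg[i])
    # element is inside at time t iff (p - v t) is inside the static polygon;
    # intersect the relative path with every edge: v t + u (b - a) = p - a
    ts <- c()
    for (e in seq_len(m)) {
      d <- b[e, ] - a[e, ]
      det <- v[1] * d[2] - v[2] * d[1]
      if (abs(det) < 1e-14) next
      rhs <- p - a[e, ]
      t <- (rhs[1] * d[2] - rhs[2] * d[1]) / det
      u <- (v[1] * rhs[2] - v[2] * rhs[1]) / det
      if (u >= 0 && u < 1 && t >= 0) ts <- c(ts, t)
    }
    if (length(ts) < 2) return(NULL)
    ts <- sort(ts)
    # even-odd pairing: (entry, exit), (entry, exit), ...
    n_pairs <- floor(length(ts) / 2)
    tibble::tibble(
      element_id = element_field$element_id[i],
      x_deg = p[1], y_deg = p[2],
      time_ms = as.vector(t(matrix(ts[seq_len(2 * n_pairs)], ncol = 2,
                                   byrow = TRUE))),
      kind = rep(kinds, n_pairs)
    )
  })
  if (is.null(ev) || nrow(ev) == 0) ev <- empty
  new_schedule(ev, geometry = element_field,
               stimulus = list(polygon = polygon,
                               velocity_deg_s = velocity_deg_s))
}

#' Rasterize an event schedule into a frame-based movie
#'
#' Renders the element array as black dots on a white background (luminance
#' convention: background 1, dots 0 by default) and applies each hide
#' interval (`offset` to the matching `onset`, or `flip_in` to `flip_out`)
#' to every frame whose start time falls inside it. Event times are floor-
#' quantized to the frame grid: an event takes effect at the first frame
#' whose start time is `>=` the event time.
#'
#' @param schedule An `sbf_schedule`.
#' @param geometry Element geometry; defaults to the schedule's own.
#' @param refresh_hz Frame rate (default 100, a CRT-like refresh).
#' @param px_per_deg Spatial resolution (default 20).
#' @param background_luminance,element_luminance Luminances in `[0, 1]`.
#' @param duration_ms Movie duration; defaults to the schedule duration plus
#'   one frame.
#' @return An object of class `sbf_movie`: list with `frames` (array
#'   `ny x nx x nframes`), `frame_duration_ms`, `px_per_deg`, `x0_deg`,
#'   `y0_deg` (center of pixel \[1,1\]), `duration_ms`.
#' @export
rasterize_schedule <- function(schedule, geometry = NULL, refresh_hz = 100,
                               px_per_deg = 20, background_luminance = 1,
                               element_luminance = 0, duration_ms = NULL) {
  if (refresh_hz <= 0 || px_per_deg <= 0)
    stop("`refresh_hz` and `px_per_deg` must be positive.", call. = FALSE)
  if (is.null(geometry)) geometry <- attr(schedule, "geometry")
  if (is.null(geometry))
    stop("No geometry available: pass `geometry`.", call. = FALSE)
  dot_r <- (attr(geometry, "dot_diameter_deg") %||% (7.9 / 60)) / 2
  frame_ms <- 1000 / refresh_hz
  if (is.null(duration_ms))
    duration_ms <- (attr(schedule, "duration_ms") %||%
                      (if (nrow(schedule)) max(schedule$time_ms) else 0)) +
      frame_ms
  nframes <- max(1L, as.integer(ceiling(duration_ms / frame_ms)))

  margin <- dot_r + 1 / px_per_deg
  x0 <- min(geometry$x_deg) - margin
  y0 <- min(geometry$y_deg) - margin
  nx <- max(1L, as.integer(ceiling((diff(range(geometry$x_deg)) + 2 * margin) *
                                     px_per_deg)))
  ny <- max(1L, as.integer(ceiling((diff(range(geometry$y_deg)) + 2 * margin) *
                                     px_per_deg)))
  px_x <- x0 + (seq_len(nx) - 0.5) / px_per_deg
  px_y <- y0 + (seq_len(ny) - 0.5) / px_per_deg

  # pixel masks per dot
  masks <- lapply(seq_len(nrow(geometry)), function(i) {
    dx <- px_x - geometry$x_deg[i]
    dy <- px_y - geometry$y_deg[i]
    m <- outer(dy^2, dx^2, `+`) <= dot_r^2
    if (!any(m)) {
      warning("Resolution too coarse for dot diameter; rendering 1 pixel.",
              call. = FALSE)
      j <- which.min(abs(dx)); k <- which.min(abs(dy))
      m[k, j] <- TRUE
    }
    which(m)
  })

  # hide intervals per element (offset/flip_in -> onset/flip_out)
  hides <- vector("list", nrow(geometry))
  names(hides) <- as.character(geometry$element_id)
  if (nrow(schedule)) {
    by_el <- split(schedule[order(schedule$time_ms), ], schedule$element_id)
    for (nm in names(by_el)) {
      ev <- by_el[[nm]]
      starts <- ev$time_ms[ev$kind %in% c("offset", "flip_in")]
      ends <- ev$time_ms[ev$kind %in% c("onset", "flip_out")]
      iv <- cbind(starts, c(ends, rep(Inf, max(0, length(starts) -
                                                 length(ends))))[
        seq_along(starts)])
      hides[[nm]] <- iv
    }
  }

  base <- matrix(background_luminance, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(geometry))) base[masks[[i]]] <- element_luminance
  frames <- array(background_luminance, dim = c(ny, nx, nframes))
  frame_starts <- (seq_len(nframes) - 1) * frame_ms
  for (f in seq_len(nframes)) {
    fr <- base
    t0 <- frame_starts[f]
    for (i in seq_len(nrow(geometry))) {
      iv <- hides[[as.character(geometry$element_id[i])]]
      if (!is.null(iv) &&
          any(iv[, 1] <= t0 & t0 < iv[, 2]))
        fr[masks[[i]]] <- background_luminance
    }
    frames[, , f] <- fr
  }
  structure(list(frames = frames, frame_duration_ms = frame_ms,
                 px_per_deg = px_per_deg, x0_deg = px_x[1], y0_deg = px_y[1],
                 duration_ms = duration_ms),
            class = "sbf_movie")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
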