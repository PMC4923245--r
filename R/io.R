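#' Validate an event schedule
#'
#' Checks the structural invariants of an event table: required columns,
#' finite non-negative times, known event kinds, and per-element alternation
#' (each element's events alternate disappearance -> reappearance, or
#' `flip_in` -> `flip_out`, in time order; a trailing unmatched disappearance
#' is allowed).
#'
#' @param events A data frame of events.
#' @param sort If `TRUE`, sort by time (ties by `element_id`) before
#'   checking; if `FALSE`, unsorted input is an error.
#' @return The validated schedule (invisibly classed as `sbf_schedule`).
#' @export
validate_schedule <- function(events, sort = TRUE) {
  need <- c("element_id", "x_deg", "y_deg", "time_ms", "kind")
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop("Schedule is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(events)) {
    if (!all(is.finite(events$time_ms)) || any(events$time_ms < 0))
      stop("Event times must be finite and >= 0.", call. = FALSE)
    if (!all(events$kind %in% c("offset", "onset", "flip_in", "flip_out")))
      stop("Unknown event kind.", call. = FALSE)
    if (is.unsorted(events$time_ms)) {
      if (!sort) stop("Events are not time-sorted.", call. = FALSE)
      events <- events[order(events$time_ms, events$element_id), ]
    }
    opener <- c(offset = TRUE, flip_in = TRUE, onset = FALSE,
                flip_out = FALSE)
    for (ev in split(events, events$element_id)) {
      open <- opener[ev$kind]
      expected <- rep(c(TRUE, FALSE), length.out = length(open))
      if (!all(open == expected))
        stop("Element ", ev$element_id[1],
             ": events must alternate disappearance -> reappearance.",
             call. = FALSE)
    }
  }
  invisible(new_schedule(tibble::as_tibble(events)))
}

#' Write / read event schedules as CSV
#'
#' Lossless round-trip of an event schedule through the plain-text schema
#' `element_id,x_deg,y_deg,time_ms,kind` (UTF-8, times in milliseconds at
#' full double precision). `read_events()` validates the schedule invariants
#' on load.
#'
#' @param schedule An `sbf_schedule` (or compatible data frame).
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an `sbf_schedule` tibble.
#' @export
write_events <- function(schedule, path) {
  df <- tibble::as_tibble(schedule)[, c("element_id", "x_deg", "y_deg",
                                        "time_ms", "kind")]
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_events
#' @param sort Passed to [validate_schedule()].
#' @export
read_events <- function(path, sort = TRUE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    element_id = readr::col_integer(),
    x_deg = readr::col_double(),
    y_deg = readr::col_double(),
    time_ms = readr::col_double(),
    kind = readr::col_character()
  ))
  validate_schedule(df, sort = sort)
  new_schedule(df)
}

#' Serialize a sawtooth geometry to JSON
#'
#' @param geometry An `sbf_geometry`.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
write_geometry_json <- function(geometry, path = NULL) {
  obj <- list(
    spacing_deg = attr(geometry, "spacing_deg"),
    vertical_step_deg = attr(geometry, "vertical_step_deg"),
    dots_per_cycle = attr(geometry, "dots_per_cycle"),
    n_dots = nrow(geometry),
    dot_diameter_deg = attr(geometry, "dot_diameter_deg"),
    positions = unname(as.matrix(geometry[, c("x_deg", "y_deg")]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export a rasterized movie as a PNG sequence
#'
#' Writes each frame as a grayscale PNG plus a JSON metadata sidecar
#' (`refresh_hz`, `px_per_deg`, `duration_ms`).
#'
#' @param movie An `sbf_movie` from [rasterize_schedule()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_movie_png <- function(movie, dir, prefix = "frame") {
  if (!requireNamespace("png", quietly = TRUE))
    stop("Package `png` is required for PNG export.", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(movie$frames)[3]
  files <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_len(nf)))
  for (f in seq_len(nf)) {
    # flip so row 1 is the top of the image (y increases upward internally)
    png::writePNG(movie$frames[rev(seq_len(dim(movie$frames)[1])), , f],
                  files[f])
  }
  meta <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(refresh_hz = 1000 / movie$frame_duration_ms,
                            px_per_deg = movie$px_per_deg,
                            duration_ms = movie$duration_ms),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}
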