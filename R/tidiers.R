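#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an edge estimate
#'
#' @param x An `sbf_edge` from [recover_edge()] or [recover_edge_triple()].
#' @param ... Unused.
#' @return One-row tibble with `status`, `orientation_deg`,
#'   `normal_speed_deg_s`, `normal_x`, `normal_y`, `time_at_origin_ms`,
#'   `residual_rms_ms`, `n_events`.
#' @export
tidy.sbf_edge <- function(x, ...) {
  tibble::tibble(status = x$status,
                 orientation_deg = x$orientation_deg,
                 normal_speed_deg_s = x$normal_speed_deg_s,
                 normal_x = x$normal[1], normal_y = x$normal[2],
                 time_at_origin_ms = x$time_at_origin_ms,
                 residual_rms_ms = x$residual_rms,
                 n_events = x$n_events)
}

#' @rdname tidy.sbf_edge
#' @export
glance.sbf_edge <- function(x, ...) {
  tibble::tibble(status = x$status, residual_rms_ms = x$residual_rms,
                 n_events = x$n_events)
}

#' Tidy a bar estimate
#'
#' @param x An `sbf_bar_estimate` from [estimate_bar()].
#' @param ... Unused.
#' @return `tidy()`: one row per recovered edge; `glance()`: one-row summary
#'   with the bar-level quantities.
#' @export
tidy.sbf_bar_estimate <- function(x, ...) {
  edges <- list(leading = x$leading, trailing = x$trailing)
  purrr::imap_dfr(edges, function(e, nm) {
    if (is.null(e)) return(NULL)
    dplyr::mutate(tidy(e), edge = nm, .before = 1)
  })
}

#' @rdname tidy.sbf_bar_estimate
#' @export
glance.sbf_bar_estimate <- function(x, ...) {
  tibble::tibble(percept = x$percept, status = x$status,
                 orientation_deg = x$orientation_deg,
                 speed_deg_s = x$speed_deg_s,
                 width_deg = x$width_deg,
                 width_from_lines_deg = x$width_from_lines_deg)
}

#' Tidy an experiment analysis
#'
#' @param x An `sbf_analysis` from [analyze_results()].
#' @param ... Unused.
#' @return `tidy()`: the per-cell tibble (slope, mean rating, SOA);
#'   `glance()`: one row with the Spearman rank correlation and cell count.
#' @export
tidy.sbf_analysis <- function(x, ...) x$cells

#' @rdname tidy.sbf_analysis
#' @export
glance.sbf_analysis <- function(x, ...) {
  tibble::tibble(spearman_rho = x$spearman_rho, n_cells = nrow(x$cells))
}

#' @export
print.sbf_analysis <- function(x, ...) {
  cat("<sbf_analysis>", nrow(x$cells), "condition cells | Spearman rho =",
      format(x$spearman_rho, digits = 3), "\n")
  print(x$cells, n = 5)
  invisible(x)
}
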