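# Independent oracles used to cross-check the analytic solvers.

# Brute-force edge recovery: grid search over edge orientation, fitting the
# normal speed by least squares of the crossing residuals n.p = s*t + c at
# each candidate orientation, followed by a golden-section refinement around
# the best grid cell. Works in the (position-residual) formulation, which is
# a different parameterization from the package's time-on-position
# regression.
oracle_grid_edge <- function(events, step_deg = 0.1) {
  x <- events$x_deg; y <- events$y_deg; t <- events$time_ms
  rss_at <- function(theta) {
    th <- theta * pi / 180
    proj <- sin(th) * x - cos(th) * y
    fit <- stats::.lm.fit(cbind(t, 1), proj)
    sum(fit$residuals^2)
  }
  thetas <- seq(0, 180 - step_deg, by = step_deg)
  rss <- vapply(thetas, rss_at, numeric(1))
  best <- thetas[which.min(rss)]
  opt <- stats::optimize(rss_at, c(best - step_deg, best + step_deg))
  theta <- opt$minimum %% 180
  th <- theta * pi / 180
  proj <- sin(th) * x - cos(th) * y
  s <- stats::.lm.fit(cbind(t, 1), proj)$coefficients[1]  # deg per ms
  list(orientation_deg = theta, speed_deg_s = abs(s) * 1000,
       rss = opt$objective)
}

# Brute-force occlusion interval of one element under a moving bar strip,
# by dense time sampling of the covered predicate.
oracle_occlusion_interval <- function(p, bar, c0, t_max, dt = 0.01) {
  o <- bar$orientation_deg * pi / 180
  n <- c(sin(o), -cos(o))
  if (n[1] * bar$dir_x + n[2] * bar$dir_y < 0) n <- -n
  sn <- bar$speed_deg_s * (n[1] * bar$dir_x + n[2] * bar$dir_y) / 1000
  ts <- seq(0, t_max, by = dt)
  lead <- c0 + sn * ts
  covered <- (lead >= sum(n * p)) & (lead - bar$width_deg <= sum(n * p))
  if (!any(covered)) return(NULL)
  c(t_off = ts[which(covered)[1]], t_on = ts[max(which(covered))] + dt)
}

# Random non-collinear event triple with known generating edge.
random_triple <- function() {
  repeat {
    theta <- stats::runif(1, 0, 180)
    speed <- stats::runif(1, 1, 20)            # deg/s
    th <- theta * pi / 180
    n <- c(sin(th), -cos(th))
    p <- matrix(stats::runif(6, -2, 2), ncol = 2)
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    scale <- max(dist(p))
    if (area / scale^2 < 0.05) next             # keep clearly non-collinear
    t0 <- stats::runif(1, 0, 50)
    t <- t0 + 1000 * (p %*% n) / speed
    return(list(events = tibble::tibble(x_deg = p[, 1], y_deg = p[, 2],
                                        time_ms = as.vector(t)),
                orientation_deg = theta, speed_deg_s = speed))
  }
}

# Random valid display condition inside the temporal gate.
random_gated_condition <- function(gate_ms = 80) {
  repeat {
    h <- stats::runif(1, 0.2, 1.0)
    v <- stats::runif(1, 3, 14)
    w <- stats::runif(1, 0.1, 0.6)
    if (1000 * h / v <= gate_ms) return(list(h = h, v = v, w = w))
  }
}
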