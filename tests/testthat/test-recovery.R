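test_that("triple solver recovers a vertical edge across the sawtooth fold", {
  # vertical bar at 10 deg/s crossing sawtooth points; triple spans the fold
  pts <- tibble::tibble(x_deg = c(0, 0.4, 1.2), y_deg = c(0, 0.4, 0.4),
                        time_ms = c(0, 40, 120))
  est <- recover_edge_triple(pts)
  expect_equal(est$status, "unique")
  expect_equal(est$orientation_deg, 90, tolerance = 1e-9)
  expect_equal(est$normal_speed_deg_s, 10, tolerance = 1e-9)
  expect_equal(est$normal, c(1, 0), tolerance = 1e-9)
  expect_lt(est$residual_rms, 1e-9)
})

test_that("collinear positions are always ambiguous, never numeric", {
  withr::with_seed(7, {
    for (i in 1:25) {
      p0 <- runif(2, -1, 1)
      dirv <- runif(2, -1, 1)
      u <- sort(runif(3, 0, 2))
      ev <- tibble::tibble(x_deg = p0[1] + u * dirv[1],
                           y_deg = p0[2] + u * dirv[2],
                           time_ms = runif(3, 0, 100))
      est <- recover_edge_triple(ev)
      expect_equal(est$status, "ambiguous_collinear")
      expect_true(is.na(est$orientation_deg))
    }
  })
})

test_that("degenerate triples are classified, not solved", {
  # simultaneous crossings of non-collinear points: no finite-speed edge
  sim <- tibble::tibble(x_deg = c(0, 1, 0), y_deg = c(0, 0, 1),
                        time_ms = c(5, 5, 5))
  expect_equal(recover_edge_triple(sim)$status, "inconsistent")

  dup <- tibble::tibble(x_deg = c(0, 0, 1), y_deg = c(0, 0, 1),
                        time_ms = c(0, 10, 20))
  expect_equal(recover_edge_triple(dup)$status, "insufficient")

  bad <- tibble::tibble(x_deg = c(0, NA, 1), y_deg = c(0, 0, 1),
                        time_ms = c(0, 10, 20))
  expect_error(recover_edge_triple(bad), "finite")
  expect_error(recover_edge_triple(sim[1:2, ]), "three")
  expect_error(recover_edge_triple(
    dplyr::mutate(sim, kind = c("offset", "onset", "offset"))), "same kind")
})

test_that("triple solver matches the brute-force grid-search oracle", {
  withr::with_seed(11, {
    for (i in 1:60) {
      tr <- random_triple()
      est <- recover_edge_triple(tr$events)
      orc <- oracle_grid_edge(tr$events)
      expect_equal(est$status, "unique")
      dtheta <- min(abs(est$orientation_deg - orc$orientation_deg),
                    180 - abs(est$orientation_deg - orc$orientation_deg))
      expect_lt(dtheta, 0.5)
      expect_lt(abs(est$normal_speed_deg_s - orc$speed_deg_s) /
                  orc$speed_deg_s, 0.01)
      # and both match the generating edge
      dgen <- min(abs(est$orientation_deg - tr$orientation_deg),
                  180 - abs(est$orientation_deg - tr$orientation_deg))
      expect_lt(dgen, 1e-6)
    }
  })
})

test_that("least-squares fit is exact on noiseless schedules and agrees with the triple solver", {
  geom <- build_sawtooth(0.3, n_dots = 12)
  bar <- virtual_bar(width_deg = 0.2, speed_deg_s = 7.3,
                     orientation_deg = 72)
  sched <- schedule_bar_events(geom, bar)
  offs <- sched[sched$kind == "offset", ]
  est <- recover_edge(offs)
  expect_equal(est$status, "unique")
  expect_equal(est$orientation_deg, 72, tolerance = 1e-9)
  # recovered speed is the bar's normal speed
  o <- 72 * pi / 180
  vn <- 7.3 * abs(sin(o))
  expect_equal(est$normal_speed_deg_s, vn, tolerance = 1e-9)
  expect_lt(est$residual_rms, 1e-9)

  est3 <- recover_edge(offs[c(1, 3, 6), ])
  tri <- recover_edge_triple(offs[c(1, 3, 6), ])
  expect_equal(est3$orientation_deg, tri$orientation_deg, tolerance = 1e-9)
  expect_equal(est3$normal_speed_deg_s, tri$normal_speed_deg_s,
               tolerance = 1e-9)

  expect_equal(recover_edge(offs[1:2, ])$status, "insufficient")
})

test_that("residual RMS reflects additive time noise", {
  geom <- build_sawtooth(0.4, n_dots = 33)
  sched <- schedule_bar_events(geom, virtual_bar(0.3, 12))
  offs <- sched[sched$kind == "offset", ]
  withr::with_seed(3, {
    rms <- replicate(20, {
      ev <- offs
      ev$time_ms <- ev$time_ms + rnorm(nrow(ev), sd = 2)
      recover_edge(ev)$residual_rms
    })
  })
  # residual RMS ~ noise sd (slightly below: 3 fitted parameters)
  expect_equal(mean(rms), 2 * sqrt((33 - 3) / 33), tolerance = 0.15)
})

test_that("recovered edges are rotation-equivariant and time-shift invariant", {
  withr::with_seed(5, {
    tr <- random_triple()
    base <- recover_edge_triple(tr$events)
    for (phi in c(17, 65, 120)) {
      th <- phi * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      rot <- as.matrix(tr$events[, c("x_deg", "y_deg")]) %*% t(R)
      ev <- tibble::tibble(x_deg = rot[, 1], y_deg = rot[, 2],
                           time_ms = tr$events$time_ms)
      est <- recover_edge_triple(ev)
      expect_equal(est$orientation_deg, (base$orientation_deg + phi) %% 180,
                   tolerance = 1e-6)
      expect_equal(est$normal_speed_deg_s, base$normal_speed_deg_s,
                   tolerance = 1e-9)
    }
    shifted <- dplyr::mutate(tr$events, time_ms = time_ms + 123.4)
    est <- recover_edge_triple(shifted)
    expect_equal(est$orientation_deg, base$orientation_deg,
                 tolerance = 1e-9)
    expect_equal(est$normal_speed_deg_s, base$normal_speed_deg_s,
                 tolerance = 1e-9)
  })
})

test_that("temporal gating groups events as the integration window allows", {
  mk <- function(times) {
    n <- length(times)
    validate_schedule(tibble::tibble(
      element_id = seq_len(n),
      x_deg = seq_len(n) * 0.4,
      y_deg = rep(c(0, 0.4), length.out = n),
      time_ms = times, kind = "offset"))
  }
  # constant 30 ms SOA: one group containing all offsets
  g <- gate_events(mk(seq(0, by = 30, length.out = 10)))
  expect_equal(nrow(g), 10)
  expect_equal(length(unique(g$group)), 1)

  # constant 150 ms SOA: gated out entirely
  expect_equal(nrow(gate_events(mk(seq(0, by = 150, length.out = 10)))), 0)

  # three events at 0, 80, 160: one group of three spanning 160 ms
  g3 <- gate_events(mk(c(0, 80, 160)))
  expect_equal(nrow(g3), 3)
  expect_equal(max(g3$time_ms) - min(g3$time_ms), 160)

  # pairs are never integrable
  expect_equal(nrow(gate_events(mk(c(0, 30)))), 0)
})

test_that("estimate_bar round-trips generating bar parameters within the gate", {
  withr::with_seed(21, {
    for (i in 1:30) {
      cond <- random_gated_condition()
      geom <- build_sawtooth(cond$h, n_dots = 9)
      bar <- virtual_bar(width_deg = cond$w, speed_deg_s = cond$v)
      est <- estimate_bar(schedule_bar_events(geom, bar))
      expect_equal(est$percept, "sbf")
      expect_equal(est$orientation_deg, 90, tolerance = 1e-6 * 90)
      expect_equal(est$speed_deg_s, cond$v, tolerance = 1e-6)
      expect_equal(est$width_deg, cond$w, tolerance = 1e-6)
    }
  })
  # the overlap (EOD > SOA) regime obeys the identical recovery contract
  geom <- build_sawtooth(0.2, n_dots = 9)
  est <- estimate_bar(schedule_bar_events(geom, virtual_bar(0.53, 10)))
  expect_equal(est$width_deg, 0.53, tolerance = 1e-9)
})

test_that("schedules beyond the gate yield no estimate", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  est <- estimate_bar(schedule_bar_events(geom, virtual_bar(0.26, 2.6)))
  expect_equal(est$percept, "apparent_motion")
  expect_true(is.na(est$width_deg))
})

test_that("percept prediction follows the SOA-only rule", {
  expect_equal(predict_percept(0.4, 13.2), "sbf")
  expect_equal(predict_percept(0.4, 2.6), "apparent_motion")
  expect_equal(predict_percept(0.2, 2.6), "sbf")
  # beyond 1 deg spacing no tested velocity reaches the gate
  grid <- tidyr::expand_grid(h = seq(1.2, 2, by = 0.2),
                             v = c(2.6, 5.3, 7.9, 10.5, 13.2))
  expect_true(all(predict_percept(grid$h, grid$v) == "apparent_motion"))
})

test_that("tidiers expose edge and bar fits as tibbles", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  sched <- schedule_bar_events(geom, virtual_bar(0.26, 13.2))
  est <- estimate_bar(sched)
  td <- tidy(est)
  expect_equal(td$edge, c("leading", "trailing"))
  expect_equal(td$status, rep("unique", 2))
  gl <- glance(est)
  expect_equal(gl$width_deg, 0.26, tolerance = 1e-9)
  e <- recover_edge(sched[sched$kind == "offset", ])
  expect_equal(nrow(tidy(e)), 1)
  expect_equal(glance(e)$status, "unique")
})
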