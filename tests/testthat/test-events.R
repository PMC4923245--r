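test_that("vertical-bar schedules realize the timing identities exactly", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  bar <- virtual_bar(width_deg = 0.53, speed_deg_s = 13.2)
  sched <- schedule_bar_events(geom, bar)

  offs <- sched[sched$kind == "offset", ]
  offs <- offs[order(offs$element_id), ]
  ons <- sched[sched$kind == "onset", ]
  ons <- ons[order(ons$element_id), ]

  soa <- 1000 * 0.4 / 13.2
  eod <- 1000 * 0.53 / 13.2
  expect_equal(diff(offs$time_ms), rep(soa, 8), tolerance = 1e-9)
  expect_equal(ons$time_ms - offs$time_ms, rep(eod, 9), tolerance = 1e-9)
  # overlap regime: w > h means several elements hidden at once
  expect_gt(eod, soa)
})

test_that("narrow bars hide exactly one element at any instant", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  bar <- virtual_bar(width_deg = 0.13, speed_deg_s = 10)
  sched <- schedule_bar_events(geom, bar)
  offs <- sched[sched$kind == "offset", ]
  ons <- sched[sched$kind == "onset", ]
  iv <- merge(offs[, c("element_id", "time_ms")],
              ons[, c("element_id", "time_ms")], by = "element_id")
  iv <- iv[order(iv$time_ms.x), ]
  # consecutive hide intervals must not overlap
  expect_true(all(iv$time_ms.y[-nrow(iv)] <= iv$time_ms.x[-1] + 1e-9))
})

test_that("oblique bars produce element-dependent offset intervals", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  bar <- virtual_bar(width_deg = 0.3, speed_deg_s = 10,
                     orientation_deg = 60)
  sched <- schedule_bar_events(geom, bar)
  offs <- sched[sched$kind == "offset", ]
  offs <- offs[order(offs$element_id), ]
  gaps <- diff(offs$time_ms)
  # unequal across the sawtooth fold
  expect_gt(diff(range(gaps)), 1)

  # cross-check a few occlusion intervals against dense time sampling
  o <- 60 * pi / 180
  n <- c(sin(o), -cos(o))
  proj <- n[1] * geom$x_deg + n[2] * geom$y_deg
  c0 <- min(proj)
  for (id in c(1, 4, 7)) {
    p <- c(geom$x_deg[id], geom$y_deg[id])
    iv <- oracle_occlusion_interval(p, bar, c0, t_max = 300)
    expect_equal(offs$time_ms[offs$element_id == id], iv[["t_off"]],
                 tolerance = 0.05)
  }
})

test_that("schedules are invariant to rigid translation", {
  geom <- build_sawtooth(0.4, n_dots = 9)
  bar <- virtual_bar(width_deg = 0.3, speed_deg_s = 8, orientation_deg = 75)
  s1 <- schedule_bar_events(geom, bar)
  geom2 <- geom
  geom2$x_deg <- geom2$x_deg + 3.7
  geom2$y_deg <- geom2$y_deg - 1.2
  s2 <- schedule_bar_events(geom2, bar)
  expect_equal(s2$time_ms, s1$time_ms, tolerance = 1e-9)
  expect_equal(s2$kind, s1$kind)
})

test_that("edge reversal concatenates a mirrored sweep", {
  geom <- build_sawtooth(0.4, n_dots = 5)
  bar <- virtual_bar(width_deg = 0.2, speed_deg_s = 10)
  s <- schedule_bar_events(geom, bar, reverse_at_edges = TRUE)
  expect_equal(nrow(s), 2 * 2 * 5)
  expect_silent(validate_schedule(s))
  # the reverse sweep hits the rightmost element first
  t_end <- max(schedule_bar_events(geom, bar)$time_ms)
  rev_offs <- s[s$time_ms >= t_end - 1e-9 & s$kind == "offset", ]
  expect_equal(rev_offs$element_id[which.min(rev_offs$time_ms)], 5L)
})

test_that("polygon schedules compute exact boundary-crossing times", {
  field <- tibble::tibble(element_id = 1:3,
                          x_deg = c(5, 5, 100), y_deg = c(0, 10, 0))
  square <- cbind(c(0, 1, 1, 0), c(-1, -1, 1, 1))  # side 2 in y, 1 in x
  s <- schedule_shape_events(field, square, velocity_deg_s = c(2, 0))
  ev1 <- s[s$element_id == 1, ]
  # entry when the leading (right) edge reaches x = 5: (5 - 1) / 2 s
  expect_equal(ev1$time_ms[ev1$kind == "flip_in"], 2000, tolerance = 1e-6)
  expect_equal(diff(ev1$time_ms), 1 / 2 * 1000, tolerance = 1e-6)
  # element above the square's path: no events
  expect_equal(sum(s$element_id == 2), 0)

  # stationary polygon -> empty schedule
  s0 <- schedule_shape_events(field, square, velocity_deg_s = c(0, 0))
  expect_equal(nrow(s0), 0)

  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(schedule_shape_events(field, bowtie, c(1, 0)), "simple")
})

test_that("event CSV round-trips losslessly and validates invariants", {
  geom <- build_sawtooth(0.4, n_dots = 7)
  sched <- schedule_bar_events(geom, virtual_bar(0.26, 13.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(sched, path)
  back <- read_events(path)
  expect_equal(tibble::as_tibble(back)[c("element_id", "time_ms", "kind")],
               tibble::as_tibble(sched)[c("element_id", "time_ms", "kind")],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$x_deg, sched$x_deg, tolerance = 1e-12)

  # onset before offset is rejected
  bad <- tibble::tibble(element_id = 1L, x_deg = 0, y_deg = 0,
                        time_ms = 5, kind = "onset")
  readr::write_csv(bad, path)
  expect_error(read_events(path), "alternate")

  # header-only file reads as an empty schedule
  readr::write_csv(bad[0, ], path)
  expect_equal(nrow(read_events(path)), 0)
})

test_that("rasterization floor-quantizes hide intervals to frames", {
  geom <- build_sawtooth(0.4, n_dots = 5)
  sched <- validate_schedule(tibble::tibble(
    element_id = 3L, x_deg = geom$x_deg[3], y_deg = geom$y_deg[3],
    time_ms = c(10, 50), kind = c("offset", "onset")))
  movie <- rasterize_schedule(sched, geometry = geom, refresh_hz = 100,
                              px_per_deg = 30, duration_ms = 100)
  # count frames where dot 3's pixels are at background
  n_hidden <- sum(vapply(seq_len(dim(movie$frames)[3]), function(f) {
    fr <- movie$frames[, , f]
    !any(fr == 0 & row(fr) > 0 &
           abs((movie$x0_deg + (col(fr) - 1) / 30) - geom$x_deg[3]) < 0.07 &
           abs((movie$y0_deg + (row(fr) - 1) / 30) - geom$y_deg[3]) < 0.07)
  }, logical(1)))
  expect_equal(n_hidden, 4)  # 40 ms at 100 Hz

  # hide-interval frame counts scale linearly with refresh rate
  movie2 <- rasterize_schedule(sched, geometry = geom, refresh_hz = 200,
                               px_per_deg = 30, duration_ms = 100)
  n_hidden2 <- sum(vapply(seq_len(dim(movie2$frames)[3]), function(f) {
    fr <- movie2$frames[, , f]
    !any(fr == 0 &
           abs((movie2$x0_deg + (col(fr) - 1) / 30) - geom$x_deg[3]) < 0.07 &
           abs((movie2$y0_deg + (row(fr) - 1) / 30) - geom$y_deg[3]) < 0.07)
  }, logical(1)))
  expect_equal(n_hidden2, 8)

  # empty schedule: every frame identical
  empty <- validate_schedule(sched[0, ])
  m0 <- rasterize_schedule(empty, geometry = geom, refresh_hz = 100,
                           px_per_deg = 30, duration_ms = 50)
  for (f in seq_len(dim(m0$frames)[3]))
    expect_identical(m0$frames[, , f], m0$frames[, , 1])
})

test_that("at most one dot is hidden per frame in the SOA = EOD display", {
  # 40 ms EOD, 0 ms ISI: each frame has exactly one dot hidden once the
  # sweep is underway, and no all-visible frame between hides
  geom <- build_sawtooth(0.4, n_dots = 9)
  bar <- virtual_bar(width_deg = 0.4, speed_deg_s = 10)  # SOA = EOD = 40 ms
  sched <- schedule_bar_events(geom, bar)
  frame_ms <- 10
  # sample mid-frame so floating-point event times never sit on a sample
  sweep <- seq(frame_ms / 2, max(sched$time_ms) - frame_ms, by = frame_ms)
  offs <- sched[sched$kind == "offset", ]
  ons <- sched[sched$kind == "onset", ]
  hidden <- vapply(sweep, function(t0) {
    sum(offs$time_ms <= t0 &
          ons$time_ms[match(offs$element_id, ons$element_id)] > t0)
  }, numeric(1))
  expect_true(all(hidden <= 1))
  expect_true(all(hidden[-c(1, length(hidden))] == 1))
})
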