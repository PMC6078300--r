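# Gait events, percent-cycle normalization, summary statistics.

make_series <- function(values, rate = 100, joint = "hip", side = "right") {
  m <- cbind(values, values * 0, values * 0)
  joint_angle_series(joint, side, m, rate)
}

test_that("gait_events enforces alternation and trims stray liftoffs", {
  ev <- gait_events(contacts = c(10, 50, 90), liftoffs = c(2, 35, 75, 95),
                    side = "right")
  expect_identical(ev$liftoffs, c(35L, 75L))
  expect_identical(hindkin::n_cycles(ev), 2L)
  expect_error(gait_events(c(10, 50), integer(), "right"), "liftoffs")
  expect_error(gait_events(c(10), c(5), "right"), "two contacts")
  expect_error(gait_events(c(10, 50), c(20, 30), "right"), "expected 1")
})

test_that("detected events land within 2 frames of generator ground truth", {
  fk <- synth_trial("stance_flat", n_cycles = 4, rate = 100)
  for (side in c("right", "left")) {
    ev <- detect_events(fk$traj, side)
    truth <- fk$truth$sides[[side]]
    expect_gte(hindkin::n_cycles(ev), 2L)
    for (ct in ev$contacts) {
      expect_lte(min(abs(truth$contacts - ct)), 2)
    }
    for (lo in ev$liftoffs) {
      expect_lte(min(abs(truth$liftoffs - lo)), 2)
    }
  }
})

test_that("stationary marker yields an empty-events error", {
  xyz <- matrix(5, 50, 3)
  traj <- trajectory_set(list(R5MT = xyz), rate = 100, up_axis = "y")
  expect_error(detect_events(traj, "right"), "no complete gait cycle")
})

test_that("events from file bypass detection and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev0 <- gait_events(c(1, 71, 141), c(43, 113), "left")
  write_events_csv(ev0, path)
  ev <- read_events_csv(path, "left")
  expect_identical(ev$contacts, ev0$contacts)
  expect_identical(ev$liftoffs, ev0$liftoffs)

  writeLines(c("side,event_type,frame", "left,contact,10", "left,contact,50",
               "left,liftoff,20", "left,liftoff,30"), path)
  expect_error(read_events_csv(path, "left"), "expected 1")
})

test_that("constant and linear series resample exactly; endpoints preserved", {
  ev <- gait_events(c(1, 51, 101), c(31, 81), "right")
  cw <- normalize_cycles(make_series(rep(100, 120)), ev)
  expect_true(all(cw$cycles[, 1, ] == 100))
  expect_true(all(cw$sd == 0))
  expect_equal(cw$stance_fraction, c(0.6, 0.6))

  ramp <- make_series(seq(0, 119))
  cw2 <- normalize_cycles(ramp, gait_events(c(1, 101), 61, "right"))
  # linear interpolation reproduces lines on the percent grid
  expect_lt(max(abs(cw2$cycles[, 1, 1] - seq(0, 100, length.out = 101))),
            1e-9)
  expect_identical(cw2$cycles[1, 1, 1], ramp$angles[1, 1])
  expect_identical(cw2$cycles[101, 1, 1], ramp$angles[101, 1])
})

test_that("mean waveform equals the oracle average of independently resampled cycles", {
  set.seed(55)
  n <- 300
  sig <- 30 + 20 * sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, sd = 1)
  contacts <- c(1, 98, 205, 300)  # deliberate phase jitter
  ser <- make_series(sig)
  ev <- gait_events(contacts, c(60, 160, 260), "right")
  cw <- normalize_cycles(ser, ev)

  grid <- seq(0, 100, length.out = 101)
  oracle <- sapply(seq_len(3), function(i) {
    idx <- contacts[i]:contacts[i + 1]
    approx((idx - idx[1]) / (idx[length(idx)] - idx[1]) * 100,
           sig[idx], xout = grid)$y
  })
  expect_lt(max(abs(cw$mean[, 1] - rowMeans(oracle))), 1e-9)
  expect_lt(max(abs(cw$sd[, 1] - apply(oracle, 1, sd))), 1e-9)
})

test_that("cycles containing invalid frames are dropped with a record", {
  sig <- make_series(sin(seq_len(200) / 10))
  sig$valid[150] <- FALSE
  ev <- gait_events(c(1, 101, 200), c(61, 161), "right")
  cw <- normalize_cycles(sig, ev)
  expect_identical(cw$dropped, 2L)
  expect_identical(dim(cw$cycles)[3], 1L)
})

test_that("summary statistics: identities and shift/offset behavior", {
  ev <- gait_events(c(1, 101, 201), c(61, 161), "right")
  base <- 90 + 25 * sin(seq(0, 4 * pi, length.out = 220))
  cw <- summarize_cycles(normalize_cycles(make_series(base), ev))
  expect_identical(cw$rom, cw$max - cw$min)
  expect_true(cw$min <= cw$mean && cw$mean <= cw$max)

  # constant offset shifts location stats, leaves sd and rom unchanged
  cw2 <- summarize_cycles(normalize_cycles(make_series(base + 13.5), ev))
  expect_equal(cw2$mean, cw$mean + 13.5, tolerance = 1e-9)
  expect_equal(cw2$max, cw$max + 13.5, tolerance = 1e-9)
  expect_equal(cw2$min, cw$min + 13.5, tolerance = 1e-9)
  expect_equal(cw2$sd, cw$sd, tolerance = 1e-12)
  expect_equal(cw2$rom, cw$rom, tolerance = 1e-12)

  # constant waveform: mean = max = min, rom = 0, sd = 0
  cwc <- summarize_cycles(normalize_cycles(make_series(rep(77, 220)), ev))
  expect_equal(cwc$mean, 77)
  expect_identical(cwc$rom, 0)
  expect_identical(cwc$sd, 0)

  # invariance to replicating identical cycles (w is 101-periodic)
  w <- 90 + 25 * sin(seq(0, 2 * pi, length.out = 101))
  one <- summarize_cycles(normalize_cycles(make_series(w),
                                           gait_events(c(1, 101), 61, "right")))
  per <- c(w[1:100], w[1:100], w)
  three <- summarize_cycles(normalize_cycles(
    make_series(per), gait_events(c(1, 101, 201, 301), c(61, 161, 261), "right")))
  expect_equal(three$mean, one$mean, tolerance = 1e-9)
  expect_equal(three$rom, one$rom, tolerance = 1e-9)
})

test_that("gait_summary produces the joint-by-plane table with rom = max - min", {
  fk <- synth_trial("stance_flat", sides = "right", n_cycles = 3, rate = 100)
  ser <- limb_angle_series(fk$traj, default_limb("right"), 1)
  tr <- fk$truth$sides$right
  ev <- gait_events(tr$contacts, tr$liftoffs, "right")
  tab <- gait_summary(ser, ev)
  expect_identical(nrow(tab), 9L)
  expect_identical(tab$rom, tab$max - tab$min)
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
})
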