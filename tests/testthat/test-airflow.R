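# Resistance network, partitioning and waveforms.

test_that("Reynolds number definition and linearity", {
  seg <- data.frame(perimeter_m = 0.06)
  expect_identical(reynolds_number(0, seg, 1.81e-5), 0)
  expect_equal(reynolds_number(1e-4, seg, 1.81e-5), 368.3, tolerance = 1e-3)
  expect_equal(reynolds_number(2e-4, seg, 1.81e-5),
               2 * reynolds_number(1e-4, seg, 1.81e-5))
  # sign-insensitive (exhalation uses the magnitude)
  expect_equal(reynolds_number(-1e-4, seg, 1.81e-5),
               reynolds_number(1e-4, seg, 1.81e-5))
})

test_that("parallel-plate friction factor f = 24/Re with laminar guard", {
  expect_identical(friction_factor(24), 1)
  expect_identical(friction_factor(12), 2)
  expect_warning(f <- friction_factor(2400), "laminar")
  expect_equal(f, 0.01)
  expect_silent(friction_factor(2400, warn = FALSE))
  expect_error(friction_factor(0), "positive")
  expect_error(friction_factor(-5), "positive")
})

test_that("Darcy-Weisbach head loss and its laminar composition", {
  expect_equal(head_loss(1, 1, 1, 1), 1 / (2 * 9.81))
  expect_equal(head_loss(0.5, 1, 2, 1), 4 * head_loss(0.5, 1, 1, 1))
  # composed with f = 24/Re: h_f = 12 mu l V / (g rho Dh^2) (algebraic oracle)
  set.seed(7)
  for (i in 1:10) {
    mu <- runif(1, 1.6e-5, 2e-5); rho <- runif(1, 1.1, 1.3)
    dh <- runif(1, 1e-3, 6e-3); l <- runif(1, 5e-4, 5e-3)
    v <- runif(1, 0.1, 6)
    re <- rho * v * dh / mu
    expect_equal(head_loss(friction_factor(re, warn = FALSE), l, v, dh),
                 12 * mu * l * v / (9.81 * rho * dh^2), tolerance = 1e-12)
  }
  expect_error(head_loss(1, -1, 1, 1), "positive")
})

test_that("specific resistance equals composed Eq(1)+(2)/mdot and scales as stated", {
  set.seed(11)
  for (i in 1:25) {
    seg <- random_segment()
    mu <- runif(1, 1.6e-5, 2e-5)
    rho <- runif(1, 1.0, 1.3)
    mdot <- runif(1, 1e-6, 5e-4)
    dh <- hydraulic_diameter(seg$area_m2, seg$perimeter_m)
    v <- mdot / (rho * seg$area_m2)
    re <- reynolds_number(mdot, seg, mu)
    hf <- head_loss(friction_factor(re, warn = FALSE), seg$length_m, v, dh)
    expect_equal(specific_resistance(seg, mu, rho), hf / mdot,
                 tolerance = 1e-12)
  }
  seg <- random_segment()
  r0 <- specific_resistance(seg, 1.8e-5, 1.2)
  seg2 <- seg; seg2$area_m2 <- 2 * seg$area_m2
  expect_equal(specific_resistance(seg2, 1.8e-5, 1.2), r0 / 8)
  seg3 <- seg; seg3$perimeter_m <- 2 * seg$perimeter_m
  expect_equal(specific_resistance(seg3, 1.8e-5, 1.2), 4 * r0)
})

test_that("series/parallel combination behaves like a resistance network", {
  eq <- total_resistance(c(1, 2), c(2, 1))
  expect_equal(eq$r_total, 3 / 2)             # equal sides -> R/2
  two_four <- total_resistance(2, 4)
  expect_equal(two_four$r_total, 4 / 3)
  expect_lt(two_four$r_total, min(two_four$sum_left, two_four$sum_right))
  # fully blocked side: total tends to the open side's sum
  expect_equal(total_resistance(2, 1e12)$r_total, 2, tolerance = 1e-6)
  expect_error(total_resistance(numeric(0), 1), "at least one")
})

test_that("partitioning ratios sum to one and favour the patent side", {
  pr <- partition_ratios(2, 4)
  expect_equal(pr$pr_left, 2 / 3)
  expect_equal(pr$pr_right, 1 / 3)
  # 2:1 resistance asymmetry -> patent side carries ~67% of the flow
  expect_equal(100 * partition_ratios(1, 2)$pr_left, 67, tolerance = 0.01)
  set.seed(3)
  for (i in 1:50) {
    s <- runif(2, 1e-3, 1e3)
    pr <- partition_ratios(s[1], s[2])
    expect_lt(abs(pr$pr_left + pr$pr_right - 1), 1e-12)
    expect_true(pr$pr_left > 0 && pr$pr_left < 1)
    if (s[1] < s[2]) expect_gt(pr$pr_left, pr$pr_right)
  }
})

test_that("congestion raises a side's resistance and lowers its share monotonically", {
  prs <- vapply(c(0, 0.15, 0.3, 0.45), function(cc) {
    geometry_partition(scaled_geometry(16, congestion_right = cc))$ratios$pr_right
  }, 0)
  expect_true(all(diff(prs) < 0))
  expect_equal(prs[1], 0.5)
})

test_that("sinusoid waveform volumes, zeros and peak", {
  rho <- 1.19
  wf <- tidal_waveform(500e-6, 5, air_density = rho)
  tt <- seq(0, 2.5, by = 1e-4)
  inhaled <- sum(diff(tt) * (wf$fn(tt)[-1] + wf$fn(tt)[-length(tt)]) / 2) / rho
  expect_equal(inhaled, 500e-6, tolerance = 1e-3)
  expect_equal(wf$fn(0), 0, tolerance = 1e-15)
  expect_equal(wf$fn(2.5), 0, tolerance = 1e-12)
  expect_equal(max(wf$mass_flow), pi * 500e-6 * rho / 5)
  # periodic continuation
  expect_equal(wf$fn(7.3), wf$fn(2.3))
})

test_that("table waveform round-trips and rejects imbalanced traces", {
  rho <- 1.19
  wf <- tidal_waveform(500e-6, 5, air_density = rho)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(time_s = wf$times, mass_flow_kg_s = wf$mass_flow),
    path, row.names = FALSE
  )
  wt <- tidal_waveform(shape = "table", table_path = path, air_density = rho)
  expect_equal(wt$period, 5)
  expect_equal(wt$tidal_volume, 500e-6, tolerance = 1e-3)
  expect_equal(wt$fn(1.23), wf$fn(1.23), tolerance = 1e-3)

  bad <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 5, length.out = 200)
  utils::write.csv(
    data.frame(time_s = tt,
               mass_flow_kg_s = sin(2 * pi * tt / 5) + 0.2),  # net inhale bias
    bad, row.names = FALSE
  )
  expect_error(tidal_waveform(shape = "table", table_path = bad), "imbalance")
})

test_that("flow apportionment conserves the total trace", {
  wf <- tidal_waveform(air_density = 1.19)
  pr <- partition_ratios(2, 4)
  ap <- apportion_flow(wf, pr)
  expect_equal(ap$left + ap$right, ap$total, tolerance = 1e-15)
  expect_equal(max(ap$left), 2 * max(ap$right), tolerance = 1e-12)
  half <- apportion_flow(wf, partition_ratios(1, 1))
  expect_identical(half$left, half$right)
})
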