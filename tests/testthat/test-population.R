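test_that("dose sampling is reproducible and matches its distribution", {
  d <- dose_distribution("fixed", location = 0)
  expect_equal(sample_doses(d, 5), rep(0, 5))
  ln <- dose_distribution("lognormal", location = -1, scale = 0.5)
  x <- sample_doses(ln, 1e5, seed = 11)
  mu <- exp(-1 + 0.5^2 / 2)
  sdev <- sqrt((exp(0.5^2) - 1) * exp(-2 + 0.5^2))
  expect_lt(abs(mean(x) - mu), 3 * sdev / sqrt(1e5))
  expect_identical(sample_doses(ln, 100, seed = 3),
                   sample_doses(ln, 100, seed = 3))
  expect_error(dose_distribution("gamma"), "family")
})

test_that("undriven populations stay NANOG-high; strong drive flips every cell", {
  m <- fate_model(); pr <- pulse_protocol()
  p0 <- simulate_population(m, pr, dose_distribution("fixed", 0), n = 4,
                            times = c(0, 6, 30))
  expect_true(all(p0$fates == "NANOG_high"))
  expect_equal(fraction_differentiated(p0), 0)
  dstar <- critical_dose(m, pr, c(0.01, 2))
  ph <- simulate_population(m, pr,
                            dose_distribution("fixed", 100 * dstar),
                            n = 4, times = c(0, 6, 30))
  expect_true(all(ph$fates == "GATA_high"))
  expect_equal(fraction_differentiated(ph), 1)
})

test_that("differentiated fraction is a simple count over resolved cells", {
  m <- fate_model(); pr <- pulse_protocol()
  dstar <- critical_dose(m, pr, c(0.01, 2))
  doses <- c(rep(0.5 * dstar, 5), rep(2 * dstar, 3))
  pop <- simulate_population(m, pr, doses = doses, times = c(0, 6, 30))
  expect_equal(fraction_differentiated(pop), 3 / 8)
})

test_that("critical dose separates the two fates and rises as signaling falls", {
  m <- fate_model(); pr <- pulse_protocol()
  dstar <- critical_dose(m, pr, c(0.01, 2))
  att <- fateswitch:::stable_attractors(find_equilibria(m))
  init <- fateswitch:::preculture_state(m)
  expect_equal(fateswitch:::fate_of_dose(1.01 * dstar, m, pr, att, init),
               "GATA_high")
  expect_equal(fateswitch:::fate_of_dose(0.99 * dstar, m, pr, att, init),
               "NANOG_high")
  d_low_s <- critical_dose(fate_model(s = 0.25), pr, c(0.01, 2))
  d_mid_s <- critical_dose(fate_model(s = 0.5), pr, c(0.01, 2))
  expect_gt(d_low_s, d_mid_s)
  expect_gt(d_mid_s, dstar)
  expect_error(critical_dose(m, pr, c(2 * dstar, 4 * dstar)), "same fate")
  expect_error(critical_dose(fate_model(alpha_G = 1e-8), pr, c(0.01, 5)),
               "same fate")
})

test_that("fate is a single-flip step function of dose", {
  m <- fate_model(); pr <- pulse_protocol()
  doses <- seq(0.02, 1, length.out = 50)
  pop <- simulate_population(m, pr, doses = doses, times = c(0, 6, 30))
  g <- pop$fates == "GATA_high"
  expect_false(any(is.na(g)))
  expect_equal(sum(diff(g) != 0), 1L)   # exactly one flip
  expect_true(g[length(g)] && !g[1L])
})

test_that("longer pulses differentiate weakly-non-decreasing fractions of cells", {
  m <- fate_model()
  doses <- sample_doses(dose_distribution(), 40, seed = 5)
  fr <- vapply(c(2, 4, 6, 10), function(dur) {
    pr <- pulse_protocol(t_start = 0, t_end = dur, t_final = 30)
    fraction_differentiated(
      simulate_population(m, pr, doses = doses, times = c(0, dur, 30)))
  }, numeric(1L))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[4L], fr[1L])
})

test_that("with paired doses, cells differentiating at low signaling also do at high", {
  m <- fate_model()
  pr <- pulse_protocol()
  doses <- sample_doses(dose_distribution(), 60, seed = 9)
  hi <- simulate_population(fate_model(s = 1), pr, doses = doses,
                            times = c(0, 6, 30))
  lo <- simulate_population(fate_model(s = 0.25), pr, doses = doses,
                            times = c(0, 6, 30))
  set_hi <- which(hi$fates == "GATA_high")
  set_lo <- which(lo$fates == "GATA_high")
  expect_true(all(set_lo %in% set_hi))
})

test_that("identical seeds reproduce fates bitwise", {
  m <- fate_model(); pr <- pulse_protocol()
  a <- simulate_population(m, pr, dose_distribution(), n = 10, seed = 21,
                           times = c(0, 6, 30))
  b <- simulate_population(m, pr, dose_distribution(), n = 10, seed = 21,
                           times = c(0, 6, 30))
  expect_identical(a$fates, b$fates)
  expect_identical(a$doses, b$doses)
  expect_identical(a$traces, b$traces)
})

test_that("NANOG-inhibition sweep: NANOG-positive peak shifts up, GATA peak holds", {
  sw <- signaling_sweep(fate_model(mode = "inhibits_nanog"),
                        pulse_protocol(), n = 200,
                        s_levels = c(1, 0.5, 0.25), seed = 2)
  sm <- sw$summary   # rows ordered s = 1, 0.5, 0.25
  expect_true(all(diff(sm$nanog_high_peak) > 0))
  expect_lt(max(sm$gata_high_peak) / min(sm$gata_high_peak) - 1, 0.10)
  expect_true(all(diff(sm$fraction) <= 0))
  expect_gt(sm$fraction[1L], sm$fraction[3L])
})

test_that("GATA-promotion sweep: GATA-positive peak moves down with signaling", {
  sw <- signaling_sweep(fate_model(mode = "promotes_gata"),
                        pulse_protocol(), n = 200,
                        s_levels = c(1, 0.85, 0.7), seed = 2)
  sm <- sw$summary
  expect_true(all(diff(sm$gata_high_peak) < 0))
  expect_true(all(diff(sm$fraction) <= 0))
  expect_gt(sm$fraction[1L], sm$fraction[3L])
})
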