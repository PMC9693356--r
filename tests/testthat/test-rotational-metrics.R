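test_that("std strength matches closed forms and the brute-force oracle", {
  # constant track: zero spread
  cst <- rotational_strength_std(make_energy_track(rep(2.5, 300)), 147)
  expect_true(all(cst$values == 0))
  # pure cosine over an integer number of periods: RMS = A / sqrt(2)
  A <- 1.7
  tone <- make_energy_track(A * cos(2 * pi * (0:399) / 10))
  s50 <- rotational_strength_std(tone, 50)
  expect_equal(s50$values, rep(A / sqrt(2), length(s50$values)),
               tolerance = 1e-12)
  # brute-force per-window recomputation
  set.seed(41)
  v <- rnorm(120)
  st <- rotational_strength_std(make_energy_track(v), 51)
  for (i in c(1, 30, 70)) {
    w <- v[i:(i + 50)]
    expect_equal(st$values[i], sqrt(mean((w - mean(w))^2)), tolerance = 1e-9)
  }
  # sample flavor
  sts <- rotational_strength_std(make_energy_track(v), 51, population = FALSE)
  expect_equal(sts$values[30], stats::sd(v[30:80]), tolerance = 1e-9)
  expect_error(rotational_strength_std(make_energy_track(rnorm(20)), 51),
               "shorter")
  expect_error(rotational_strength_std(make_energy_track(v), 9), ">= 11")
})

test_that("FFT strength matches the pure-tone closed form", {
  cst <- periodic_power_fft(make_energy_track(rep(3, 200)), 50, 10)
  expect_equal(cst$values, rep(0, length(cst$values)), tolerance = 1e-9)
  A <- 2.2
  for (phase in c(0, 1.1)) {
    tone <- make_energy_track(A * cos(2 * pi * (0:299) / 10 + phase))
    f <- periodic_power_fft(tone, 50, 10)
    expect_equal(f$values, rep(A * 25, length(f$values)), tolerance = 1e-9)
  }
  expect_error(periodic_power_fft(make_energy_track(rnorm(100)), 50, 60),
               "period")
  expect_error(periodic_power_fft(make_energy_track(rnorm(100)), 15, 10),
               "2 \\* period")
})

test_that("planted periodicity outscores white noise of equal variance", {
  set.seed(42)
  periodic <- sqrt(2) * cos(2 * pi * (0:499) / 10)   # variance 1
  noise <- rnorm(500)                                 # variance 1
  fp <- periodic_power_fft(make_energy_track(periodic), 50, 10)
  fn <- periodic_power_fft(make_energy_track(noise), 50, 10)
  expect_gt(mean(fp$values), mean(fn$values))
})

test_that("strength statistics share invariances and rank order", {
  set.seed(43)
  v <- rnorm(400) + 0.6 * cos(2 * pi * (0:399) / 10) * rep(c(1, 0),
                                                           each = 200)
  tr <- make_energy_track(v)
  shifted <- make_energy_track(v + 5)
  scaled <- make_energy_track(3 * v)
  s0 <- rotational_strength_std(tr, 51)
  expect_equal(rotational_strength_std(shifted, 51)$values, s0$values,
               tolerance = 1e-9)
  expect_equal(rotational_strength_std(scaled, 51)$values, 3 * s0$values,
               tolerance = 1e-9)
  f0 <- periodic_power_fft(tr, 50)
  expect_equal(periodic_power_fft(shifted, 50)$values, f0$values,
               tolerance = 1e-8)
  # the two views of rotational strength agree in rank on real-ish signal
  g <- generate_periodic_sequence(synthetic_spec(n_nucleosomes = 15,
                                                 signal = 0.8, seed = 44))
  bend <- energy_track(g$sequence, fixture_template, fixture_params,
                       "bending")
  s <- rotational_strength_std(bend, 51)
  f <- periodic_power_fft(bend, 50, 10)
  common <- intersect(track_positions(s), track_positions(f))
  rho <- stats::cor(track_value_at(s, common), track_value_at(f, common),
                    method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("predict_dyad picks the leftmost argmax in the search interval", {
  # self-match at an exact peak
  v <- -(0:100 - 50)^2
  tr <- new_track("s", 0, v, class_ = "rpi_track")
  expect_identical(predict_dyad(tr, 50), 50L)
  # unique quadratic peak at center + 3
  v2 <- -((0:100) - 53)^2
  expect_identical(predict_dyad(new_track("s", 0, v2, class_ = "rpi_track"),
                                50), 53L)
  # flat track: leftmost tie
  flat <- new_track("s", 0, rep(1, 101), class_ = "rpi_track")
  expect_identical(predict_dyad(flat, 50), 45L)
  expect_identical(predict_dyad(flat, 50, half_width = 3), 47L)
  # undefined anywhere in the interval: NA
  v3 <- rep(1, 101); v3[48] <- NA
  expect_true(is.na(predict_dyad(new_track("s", 0, v3, class_ = "rpi_track"),
                                 50)))
})

test_that("evaluate_dyads summarizes offsets and skips unevaluable dyads", {
  v <- rep(0, 500)
  peaks <- c(100, 200, 300)
  v[peaks + 1] <- 5
  tr <- new_track("s", 0, v, class_ = "rpi_track")
  ev <- evaluate_dyads(tr, peaks)
  expect_equal(ev$fraction, 1)
  expect_equal(ev$offsets, c(0, 0, 0))
  # a dyad beyond the track is skipped, not fatal
  ev2 <- evaluate_dyads(tr, c(peaks, 600))
  expect_equal(ev2$n_skipped, 1L)
  expect_equal(ev2$n_evaluated, 3L)
  expect_error(evaluate_dyads(tr, c(600, 700)), "zero evaluable")
})

test_that("dyad recovery works on planted fixtures and beats off-phase", {
  g <- generate_periodic_sequence(synthetic_spec(n_nucleosomes = 20,
                                                 seed = 45))
  rpi <- rpi_from_sequence(g$sequence)
  ev <- evaluate_dyads(rpi, g$truth$dyads, half_width = 5, tol = 2)
  expect_gte(ev$fraction, 0.9)
  # anti-phase references (half period off) must do worse
  ev_anti <- evaluate_dyads(rpi, g$truth$dyads + 5, half_width = 5, tol = 2)
  expect_lt(ev_anti$fraction, ev$fraction)
  # invariance under strictly monotone transforms of the score
  mono <- new_track(rpi$seqname, rpi$start, exp(rpi$values),
                    class_ = "rpi_track")
  expect_equal(evaluate_dyads(mono, g$truth$dyads)$fraction, ev$fraction)
  cub <- new_track(rpi$seqname, rpi$start, rpi$values^3,
                   class_ = "rpi_track")
  expect_equal(evaluate_dyads(cub, g$truth$dyads)$fraction, ev$fraction)
})

test_that("raw-bending-minimum baseline plugs into the same evaluator", {
  g <- generate_periodic_sequence(synthetic_spec(n_nucleosomes = 20,
                                                 seed = 46))
  bend <- energy_track(g$sequence, fixture_template, fixture_params,
                       "bending")
  neg <- new_track(bend$seqname, bend$start, -bend$values)
  ev <- evaluate_dyads(neg, g$truth$dyads)
  expect_gte(ev$fraction, 0.8)   # energy minima mark the planted dyads
})

test_that("dyad evaluation TSV export round-trips", {
  v <- rep(0, 300); v[c(101, 201)] <- 1
  tr <- new_track("s", 0, v, class_ = "rpi_track")
  ev <- evaluate_dyads(tr, c(100, 200))
  path <- tempfile(fileext = ".tsv")
  write_dyad_evaluation(ev, path)
  df <- read.delim(path, comment.char = "#")
  expect_equal(df$dyad, c(100, 200))
  expect_equal(df$offset, ev$offsets)
})
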