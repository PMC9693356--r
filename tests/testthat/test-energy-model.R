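test_that("nucleosome template geometry matches its closed forms", {
  tpl <- build_nucleosome_template(101, 10.0, 4.5)
  ctr <- (101 - 1) / 2
  expect_equal(tpl$roll_t[ctr], 4.5)
  expect_equal(tpl$tilt_t[ctr], 0)
  expect_equal(tpl$roll_t[ctr + 5], -4.5)
  expect_equal(unique(tpl$twist_t), 36)
  # total imposed bend: |(roll, tilt)| is constant rho at every step
  tpl129 <- build_nucleosome_template(129, 10.0, 4.5)
  expect_equal(sum(sqrt(tpl129$roll_t^2 + tpl129$tilt_t^2)), 128 * 4.5)
  # roll/tilt in quadrature: constant bend magnitude rho at every step
  expect_equal(sqrt(tpl$roll_t^2 + tpl$tilt_t^2), rep(4.5, 100))
})

test_that("template construction rejects invalid windows", {
  expect_error(build_nucleosome_template(100), "odd")
  expect_error(build_nucleosome_template(73), "\\[75, 147\\]")
  expect_error(build_nucleosome_template(149), "\\[75, 147\\]")
  expect_error(build_nucleosome_template(101, helical_period = 0), "period")
  expect_error(build_nucleosome_template(101, curvature_amplitude = -1))
})

test_that("packaged parameter table satisfies its structural invariants", {
  p <- default_step_params()
  expect_identical(dim(p$theta0), c(6L, 16L))
  expect_length(p$stiffness, 16L)
  for (M in p$stiffness) {
    expect_true(all(abs(M - t(M)) < 1e-12))
    expect_true(all(diag(M) > 0))
    expect_gte(min(eigen(M, symmetric = TRUE)$values), -1e-12)
  }
  # reverse-complement symmetry spot checks
  expect_equal(p$theta0["roll", "AG"], p$theta0["roll", "CT"])
  expect_equal(p$theta0["tilt", "AA"], -p$theta0["tilt", "TT"])
  expect_equal(p$stiffness[["CA"]], p$stiffness[["TG"]] *
                 outer(c(1, 1, -1, -1, 1, 1), c(1, 1, -1, -1, 1, 1)),
               ignore_attr = TRUE)
})

test_that("window_energy agrees with the brute-force quadratic-form oracle", {
  set.seed(11)
  for (kind in c("bending", "shearing")) {
    for (r in 1:5) {
      s <- rand_seq(101)
      expect_equal(window_energy(s, fixture_template, fixture_params, kind),
                   oracle_window_energy(s, fixture_template, fixture_params,
                                        kind),
                   tolerance = 1e-9)
    }
  }
  # flat template (rho = 0): pure straightening cost, still oracle-equal
  flat <- build_nucleosome_template(101, 10.0, 0, slide_amplitude = 0)
  s <- rand_seq(101)
  expect_equal(window_energy(s, flat, fixture_params, "bending"),
               oracle_window_energy(s, flat, fixture_params, "bending"),
               tolerance = 1e-9)
})

test_that("window_energy is translation invariant on a homogeneous sequence", {
  polyA <- strrep("A", 300)
  tr <- energy_track(polyA, fixture_template, fixture_params, "bending")
  expect_equal(length(unique(tr$values)), 1L)
  expect_equal(tr$values[1],
               window_energy(strrep("A", 101), fixture_template,
                             fixture_params, "bending"))
})

test_that("A/T steps planted at the favored template phase lower the energy", {
  set.seed(12)
  inphase <- outphase <- numeric(30)
  for (r in 1:30) {
    s <- rand_seq(101)
    inphase[r] <- window_energy(plant_window(s, fixture_template, 0),
                                fixture_template, fixture_params, "bending")
    outphase[r] <- window_energy(plant_window(s, fixture_template, 5),
                                 fixture_template, fixture_params, "bending")
  }
  expect_true(all(inphase < outphase))
})

test_that("ambiguous-base policy: reject by default, averaging optional", {
  s <- paste0(strrep("A", 50), "N", strrep("A", 50))
  expect_error(window_energy(s, fixture_template, fixture_params, "bending"),
               "non-ACGT")
  e <- window_energy(s, fixture_template, fixture_params, "bending",
                     n_policy = "average")
  expect_true(is.finite(e))
  expect_error(window_energy(strrep("A", 99), fixture_template,
                             fixture_params), "length")
})

test_that("energy_track equals per-window recomputation and honors edges", {
  set.seed(13)
  s <- rand_seq(260)
  tr <- energy_track(s, fixture_template, fixture_params, "bending")
  expect_equal(length(tr$values), nchar(s) - 101 + 1)       # edge contract
  expect_identical(tr$start, 50L)
  for (i in c(1, 2, 57, 100, 160)) {
    sub <- substr(s, i, i + 100)
    expect_equal(tr$values[i],
                 window_energy(sub, fixture_template, fixture_params,
                               "bending"),
                 tolerance = 1e-9)
  }
  # single-window sequence
  one <- energy_track(substr(s, 1, 101), fixture_template, fixture_params,
                      "bending")
  expect_length(one$values, 1L)
  expect_error(energy_track(substr(s, 1, 100), fixture_template,
                            fixture_params), "shorter")
})

test_that("energy values are local: flanking sequence does not change them", {
  set.seed(14)
  s <- rand_seq(200)
  flank <- rand_seq(50)
  tr1 <- energy_track(s, fixture_template, fixture_params, "bending")
  tr2 <- energy_track(paste0(flank, s, flank), fixture_template,
                      fixture_params, "bending")
  expect_identical(track_value_at(tr2, track_positions(tr1) + 50),
                   tr1$values)
})

test_that("windows containing N are undefined under the default policy", {
  set.seed(15)
  s <- rand_seq(300)
  substr(s, 150, 150) <- "N"
  tr <- energy_track(s, fixture_template, fixture_params, "bending")
  pos <- track_positions(tr)
  touched <- pos >= (149 - 50) & pos <= (149 + 50)  # windows covering the N
  expect_true(all(is.na(tr$values[touched])))
  expect_true(all(!is.na(tr$values[!touched])))
  tra <- energy_track(s, fixture_template, fixture_params, "bending",
                      n_policy = "average")
  expect_false(anyNA(tra$values))
})

test_that("unit-range normalization is the documented affine map", {
  tr <- make_energy_track(c(2, 3, 4, 5, 6))
  nz <- normalize_unit_range(tr, 2, 6)
  expect_equal(nz$values, c(-1, -0.5, 0, 0.5, 1))
  expect_true(attr(nz, "normalized"))
  # defaults use the track extrema; ordering is preserved
  nz2 <- normalize_unit_range(make_energy_track(c(5, 1, 3)))
  expect_equal(nz2$values, c(1, -1, 0))
  expect_identical(order(nz2$values), order(c(5, 1, 3)))
  # foreign constants clip
  nz3 <- normalize_unit_range(make_energy_track(c(0, 10)), 2, 6)
  expect_equal(nz3$values, c(-1, 1))
  expect_error(normalize_unit_range(tr, 3, 3), "emin")
})

test_that("planted periodic signal gives a dominant DFT period near 10 bp", {
  g <- generate_periodic_sequence(synthetic_spec(n_nucleosomes = 5,
                                                 seed = 21))
  tr <- energy_track(g$sequence, fixture_template, fixture_params, "bending")
  # 150-bp stretch centered on the middle dyad
  v <- track_value_at(tr, g$truth$dyads[3] + (-74:75))
  sp <- Mod(stats::fft(v - mean(v)))[2:75]
  dom <- which.max(sp)                    # frequency index (cycles / 150 bp)
  expect_gte(150 / dom, 9)
  expect_lte(150 / dom, 11)
})

test_that("energy computation is bit-deterministic", {
  set.seed(16)
  s <- rand_seq(300)
  a <- energy_track(s, fixture_template, fixture_params, "bending")
  b <- energy_track(s, fixture_template, fixture_params, "bending")
  expect_identical(a, b)
})
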