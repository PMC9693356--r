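# Independent brute-force oracles and fixture builders.  These deliberately
# re-derive quantities with the dumbest possible code (explicit loops, full
# 6x6 quadratic forms, direct summation) and share no kernels or cost tables
# with the package internals they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# deformation energy of one window by explicit per-step summation over the
# full 6-vector with a mask selecting the parameter group
oracle_window_energy <- function(seq, template, params, kind) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- template$L
  stopifnot(length(bases) == L)
  mask <- if (kind == "bending") c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
          else c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  total <- 0
  for (j in 1:(L - 1)) {
    d <- paste0(bases[j], bases[j + 1])
    target <- c(template$twist_t[j], template$roll_t[j], template$tilt_t[j],
                template$shift_t[j], template$slide_t[j], 0)
    delta <- target - params$theta0[, d]
    FM <- params$stiffness[[d]]
    acc <- 0
    for (a in 1:6) for (b in 1:6)
      if (mask[a] && mask[b]) acc <- acc + FM[a, b] * delta[a] * delta[b]
    total <- total + 0.5 * acc
  }
  unname(total / (L - 1))
}

# direct summation of the 147-tap Gaussian kernel constant
oracle_kernel_W <- function() {
  s <- 0
  for (k in -73:73) s <- s + exp(-0.5 * (k / 20)^2)
  s
}

# RPI at index i (1-based into p) by direct complex summation
oracle_rpi <- function(p, i, sigma2 = 400, period = 9.906) {
  acc <- 0 + 0i
  for (k in -73:73)
    acc <- acc + p[i + k] * exp(-k^2 / (2 * sigma2)) *
      exp(1i * 2 * pi * k / period)
  Re(acc)
}

# maximum total score over all spacing-feasible subsets (exhaustive; use only
# for <= ~15 positions)
oracle_best_dyad_score <- function(pos, score, min_dist) {
  n <- length(pos)
  best <- 0
  for (m in 0:(2^n - 1)) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0)
    if (length(sel) > 1) {
      d <- diff(sort(pos[sel]))
      if (any(d < min_dist)) next
    }
    best <- max(best, sum(score[sel]))
  }
  best
}

# plant the favored dinucleotide class every `period` bp into a window, at
# template-phase `phase0` relative to the central step (phase 0 = template
# roll maxima under the packaged convention)
plant_window <- function(seq, template, phase0 = 0) {
  bases <- strsplit(seq, "")[[1]]
  L <- template$L
  ctr <- (L - 1) / 2                      # central step index (1-based steps)
  j <- ctr + phase0
  while (j >= 1) {
    bases[j] <- "A"; bases[j + 1] <- "A"   # step j = bases (j, j+1)
    j <- j - 10
  }
  j <- ctr + phase0 + 10
  while (j + 1 <= L) {
    bases[j] <- "A"; bases[j + 1] <- "A"
    j <- j + 10
  }
  paste(bases, collapse = "")
}

make_score_track <- function(values, start = 0, beta = 1,
                             energy_kind = "bending", seqname = "s")
  new_track(seqname, start, values, class_ = "score_track", beta = beta,
            energy_kind = energy_kind)

make_energy_track <- function(values, start = 0, normalized = FALSE,
                              seqname = "s", kind = "bending")
  new_track(seqname, start, values, class_ = "energy_track", window = 101L,
            kind = kind, normalized = normalized, emin = -1, emax = 1)

# shared small fixtures (built once per test run)
fixture_params <- default_step_params()
fixture_template <- build_nucleosome_template(101)

# bending RPI for a sequence, normalizing over the track itself
rpi_from_sequence <- function(seq, template = fixture_template,
                              params = fixture_params, beta = 1,
                              period = 9.906) {
  et <- energy_track(seq, template, params, "bending")
  p <- positioning_scores(normalize_unit_range(et), beta)
  rotational_positioning_index(p, period = period)
}
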