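#' Boltzmann nucleosome-positioning scores
#'
#' `p_i = exp(-beta * E_i)` on a unit-range normalized energy track: low
#' deformation energy means a high positioning score.  With `E_i` in
#' `[-1, 1]`, `p_i` lies in `[exp(-beta), exp(beta)]`.
#'
#' @param track a unit-range normalized `energy_track` (see
#'   [normalize_unit_range()]); passing a raw track is an error.
#' @param beta inverse-temperature factor (default 1).
#' @return a `score_track`.
#' @export
positioning_scores <- function(track, beta = 1) {
  stopifnot(inherits(track, "energy_track"))
  if (!isTRUE(attr(track, "normalized")))
    stop("positioning_scores requires a unit-range normalized energy track; ",
         "call normalize_unit_range() first")
  new_track(track$seqname, track$start, exp(-beta * track$values),
            class_ = "score_track", beta = beta,
            energy_kind = attr(track, "kind"), window = attr(track, "window"))
}

gaussian_weights <- function(half = 73L, sd = 20) {
  k <- -half:half
  exp(-0.5 * (k / sd)^2)
}

#' Nucleosome occupancy, model 1 (Gaussian center-weighted Boltzmann scores)
#'
#' `occ_i = sum_{k=-73}^{73} w_k p_{i+k}` with Gaussian weights
#' `w_k = exp(-(1/2) (k/20)^2)`.  Defined where all 147 neighbouring scores
#' are defined; the track shrinks by 73 bp on each side.  Model 1 is
#' conventionally computed from shearing-energy scores (the shearing channel
#' is the stronger occupancy predictor; the bending channel feeds the
#' rotational positioning index and model 2).
#'
#' @param p a `score_track` from [positioning_scores()].
#' @return an `occupancy_track` (model tag `"model1"`).
#' @export
occupancy_model1 <- function(p) {
  stopifnot(inherits(p, "score_track"))
  w <- gaussian_weights()
  if (length(p$values) < length(w))
    stop("score track shorter than the 147-bp kernel: empty occupancy track")
  occ <- kernel_sum(p$values, w)
  shrink_track(p, 73L, occ, class_ = "occupancy_track", model = "model1",
               beta = attr(p, "beta"), energy_kind = attr(p, "energy_kind"))
}

#' Rotational positioning index (nucleosome center score)
#'
#' Correlates the positioning-score profile with a Gabor-like wave packet:
#' `RPI_i = Re[ sum_{k=-73}^{73} p_{i+k} exp(-k^2/(2 sigma2))
#' exp(2 pi i k / period) ]`.
#' The packet has ~10-bp periodicity with its peak at the packet center, so
#' the index is large where the score profile oscillates with nucleosomal
#' periodicity *in phase* with a dyad at `i` — it indicates the rotational
#' setting, and its value is also read as a nucleosome center score.
#'
#' Since the imaginary part of the kernel is odd in `k`, the real part of the
#' inner product equals a correlation with the even cosine packet; the result
#' does not depend on the sign convention of the complex frequency.
#'
#' @param p a `score_track`; bending-derived scores are the intended input
#'   (a warning is raised otherwise).
#' @param sigma2 Gaussian envelope variance in bp^2 (default 400, i.e.
#'   `exp(-k^2/800)`).
#' @param period wave-packet period in bp (default 9.906).
#' @return an `rpi_track` (defined region shrinks by 73 bp on each side).
#' @export
rotational_positioning_index <- function(p, sigma2 = 400, period = 9.906) {
  stopifnot(inherits(p, "score_track"))
  if (period <= 0) stop("period must be positive")
  ek <- attr(p, "energy_kind")
  if (!is.null(ek) && !identical(ek, "bending"))
    warning("rotational_positioning_index is intended for bending-energy ",
            "scores; got ", ek)
  k <- -73:73
  kern <- exp(-k^2 / (2 * sigma2)) * cos(2 * pi * k / period)
  if (length(p$values) < length(kern))
    stop("score track shorter than the 147-bp wave packet")
  rpi <- kernel_sum(p$values, kern)
  shrink_track(p, 73L, rpi, class_ = "rpi_track",
               sigma2 = sigma2, period = period)
}

# strict 3-point local maxima with plateau handling: a plateau flanked by
# lower values counts once, at its midpoint (left-of-middle for even runs).
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_along(r$values)) {
    if (is.na(r$values[i])) next
    lo <- if (i == 1L) -Inf else r$values[i - 1L]
    hi <- if (i == length(r$values)) -Inf else r$values[i + 1L]
    if (is.na(lo) || is.na(hi)) next
    if (i > 1L && i < length(r$values) && r$values[i] > lo && r$values[i] > hi)
      out <- c(out, starts[i] + (r$lengths[i] - 1L) %/% 2L)
  }
  out
}

#' Nucleosome occupancy, model 2 (envelope of the rotational positioning index)
#'
#' Fits the upper contour of the oscillating RPI landscape: the strict local
#' maxima of the index are taken as knots, joined by monotone-preserving
#' piecewise-cubic interpolation (no overshoot below the knots), held
#' constant beyond the outermost knots, and floored at 0.  The fitted value
#' at each site is the model-2 occupancy estimate, defined solely on bending
#' energy.
#'
#' @param rpi an `rpi_track`.
#' @return an `occupancy_track` (model tag `"model2"`).  If fewer than 2
#'   local maxima exist the constant `max(RPI, 0)` is returned with a
#'   warning (attribute `degenerate = TRUE`).
#' @export
envelope_occupancy <- function(rpi) {
  stopifnot(inherits(rpi, "rpi_track"))
  v <- rpi$values
  pk <- local_maxima_idx(v)
  if (length(pk) < 2L) {
    warning("fewer than 2 RPI local maxima; returning constant envelope")
    env <- rep(max(c(v, 0), na.rm = TRUE), length(v))
    env[is.na(v)] <- NA_real_
    return(new_track(rpi$seqname, rpi$start, pmax(env, 0),
                     class_ = "occupancy_track", model = "model2",
                     degenerate = TRUE))
  }
  f <- stats::splinefun(pk, v[pk], method = "monoH.FC")
  idx <- seq_along(v)
  env <- numeric(length(v))
  env[idx < pk[1]] <- v[pk[1]]
  env[idx > pk[length(pk)]] <- v[pk[length(pk)]]
  mid <- idx >= pk[1] & idx <= pk[length(pk)]
  env[mid] <- f(idx[mid])
  env <- pmax(env, 0)
  env[is.na(v)] <- NA_real_
  new_track(rpi$seqname, rpi$start, env, class_ = "occupancy_track",
            model = "model2", degenerate = FALSE,
            period = attr(rpi, "period"), sigma2 = attr(rpi, "sigma2"))
}
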