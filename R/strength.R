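#' Rotational positioning strength: sliding-window standard deviation
#'
#' The bending-energy profile of a rotationally positioned nucleosome
#' oscillates with ~10-bp period, so the spread of bending energies inside a
#' nucleosome-sized window is a direct readout of rotational-positioning
#' strength.  Computed as the *population* standard deviation (divide by
#' `n`, not `n - 1`; configurable) of the energies in a centered sliding
#' window.
#'
#' For even windows the value at position `i` covers
#' `[i - window/2, i + window/2 - 1]` (same convention as
#' [periodic_power_fft()]).
#'
#' @param bend an `energy_track` (bending), raw or normalized.
#' @param window window length in bp, >= 11.  Default 147 (nucleosome
#'   footprint); gene-profile figures conventionally use 50.
#' @param population logical; `FALSE` gives the sample (n-1) flavor.
#' @return a `strength_track` (stat `"std"`).
#' @export
rotational_strength_std <- function(bend, window = 147L, population = TRUE) {
  stopifnot(inherits(bend, "rotpos_track"))
  window <- as.integer(window)
  if (window < 11L)
    stop("window must be >= 11")
  v <- bend$values
  if (length(v) < window)
    stop("track (", length(v), ") shorter than window (", window,
         "): empty strength track")
  s1 <- roll_sum(v, window)
  s2 <- roll_sum(v^2, window)
  m <- s1 / window
  var <- pmax(0, s2 / window - m^2)
  # guard against catastrophic cancellation: relative variance below machine
  # precision (e.g. a constant window) is exactly zero
  var[var < 1e-12 * pmax(1, abs(s2) / window)] <- 0
  if (!population) var <- var * window / (window - 1)
  shrink_track(bend, window %/% 2L, sqrt(var), class_ = "strength_track",
               stat = "std", window = window)
}

#' Rotational positioning strength: Fourier amplitude at a target period
#'
#' Magnitude of the discrete-Fourier component of the mean-subtracted
#' windowed energies at the frequency bin nearest `1/period` cycles/bp
#' (`m = round(window / period)`).  For a pure tone `A cos(2 pi i / 10)` and
#' `window = 50` this is exactly `A * window / 2` (integer periods per
#' window).  Mean subtraction is a no-op at nonzero integer bins but is kept
#' explicit in the definition.
#'
#' For even windows the value at position `i` covers
#' `[i - window/2, i + window/2 - 1]`.
#'
#' @param bend an `energy_track` (bending).
#' @param window window length in bp (>= 2 * period).  Default 50.
#' @param period target period in bp.  Default 10.
#' @return a `strength_track` (stat `"fft_power"`).
#' @export
periodic_power_fft <- function(bend, window = 50L, period = 10) {
  stopifnot(inherits(bend, "rotpos_track"))
  window <- as.integer(window)
  if (period >= window) stop("period must be smaller than window")
  if (window < 2 * period) stop("window must be >= 2 * period")
  v <- bend$values
  if (length(v) < window)
    stop("track shorter than window: empty strength track")
  m <- round(window / period)
  phi <- 2 * pi * m / window
  t0 <- seq_along(v) - 1
  # windowed sum of v * exp(-i phi j) has the same magnitude as the rolling
  # sum of v * exp(-i phi t) (global phase drops out); mean subtraction
  # contributes nothing at a nonzero integer bin.
  re <- roll_sum(v * cos(phi * t0), window)
  im <- roll_sum(v * sin(phi * t0), window)
  shrink_track(bend, window %/% 2L, sqrt(re^2 + im^2),
               class_ = "strength_track", stat = "fft_power",
               window = window, period = period)
}

#' Predict a nucleosome dyad near a reference center
#'
#' The predicted dyad is the position with the highest nucleosome center
#' score (rotational positioning index) in the interval
#' `[center - half_width, center + half_width]`; ties go to the leftmost
#' position.  To use raw bending energy as the predictor (its minima mark
#' preferred dyads) pass the negated energy track.
#'
#' @param rpi any per-base track of center scores (typically an
#'   `rpi_track`).
#' @param center 0-based reference position.
#' @param half_width search half-width in bp (default 5).
#' @return the predicted 0-based position, or `NA` if the track is undefined
#'   anywhere in the interval.
#' @export
predict_dyad <- function(rpi, center, half_width = 5L) {
  pos <- (center - half_width):(center + half_width)
  val <- track_value_at(rpi, pos)
  if (anyNA(val)) return(NA_integer_)
  pos[which.max(val)]   # which.max is leftmost on ties
}

#' Evaluate dyad predictions against reference centers
#'
#' Applies [predict_dyad()] at each reference dyad and reports the signed
#' offsets and the fraction predicted within `tol` bp.  Dyads whose search
#' interval is not fully covered by the track are skipped and counted as
#' unevaluable.
#'
#' @param rpi center-score track.
#' @param dyads integer vector of 0-based reference dyad positions.
#' @param half_width search half-width (default 5).
#' @param tol tolerance in bp for a correct prediction (default 2).
#' @return a `dyad_evaluation`: list with `offsets` (signed, per evaluable
#'   dyad), `predicted`, `dyads`, `fraction`, `n_evaluated`, `n_skipped`,
#'   `tol`, `half_width`.
#' @export
evaluate_dyads <- function(rpi, dyads, half_width = 5L, tol = 2L) {
  stopifnot(length(dyads) >= 1L)
  pred <- vapply(dyads, function(d) {
    p <- predict_dyad(rpi, d, half_width)
    if (is.na(p)) NA_integer_ else as.integer(p)
  }, integer(1))
  ok <- !is.na(pred)
  if (!any(ok))
    stop("zero evaluable dyads (", length(dyads), " supplied, all skipped)")
  off <- pred[ok] - dyads[ok]
  structure(list(dyads = dyads[ok], predicted = pred[ok], offsets = off,
                 fraction = mean(abs(off) <= tol),
                 n_evaluated = sum(ok), n_skipped = sum(!ok),
                 tol = tol, half_width = half_width),
            class = "dyad_evaluation")
}

#' @export
print.dyad_evaluation <- function(x, ...) {
  cat(sprintf("<dyad_evaluation> %d evaluated (%d skipped): %.1f%% within %d bp (half-width %d)\n",
              x$n_evaluated, x$n_skipped, 100 * x$fraction, x$tol,
              x$half_width))
  invisible(x)
}

#' Write a dyad evaluation as TSV
#'
#' Columns `dyad`, `predicted`, `offset`, preceded by a one-line `#` summary.
#' @param x a `dyad_evaluation`.
#' @param path output path.
#' @export
write_dyad_evaluation <- function(x, path) {
  stopifnot(inherits(x, "dyad_evaluation"))
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sprintf("# %d/%d within %d bp (fraction %.4f); %d skipped",
                     sum(abs(x$offsets) <= x$tol), x$n_evaluated, x$tol,
                     x$fraction, x$n_skipped), tmp)
  suppressWarnings(utils::write.table(
    data.frame(dyad = x$dyads, predicted = x$predicted, offset = x$offsets),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  file.rename(tmp, path)
  invisible(path)
}
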