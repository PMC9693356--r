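#' Build the superhelical nucleosome template
#'
#' The deformation-energy model measures how much a window of DNA must be bent
#' and sheared to follow the path of nucleosomal DNA.  That path is encoded as
#' per-step target deformations over the `L - 1` base-pair steps of an
#' `L`-bp window: roll and tilt follow sinusoids in quadrature at the helical
#' frequency (their vector sum is a constant bend of `curvature_amplitude`
#' degrees per step, i.e. a uniformly curved superhelix), twist is the
#' constant `360 / helical_period`, and the shearing targets are a small
#' slide sinusoid in phase with roll plus zero shift.
#'
#' The central step index is `c = (L - 1) / 2` (the step ending at the
#' window's central base), so `roll_t(c) = curvature_amplitude` and
#' `tilt_t(c) = 0`.  Templates for windows other than the canonical length
#' are rebuilt at the requested length with unchanged curvature and period.
#'
#' @param window_len odd window length in bp, between 75 and 147 (default
#'   101, the length used throughout the analyses; 75 and 129 are the other
#'   supported choices).
#' @param helical_period helical repeat in bp/turn (default 10.0).
#' @param curvature_amplitude superhelix curvature in degrees/step (default
#'   4.5, approximating the 1.65-turn 147-bp crystallographic superhelix).
#' @param slide_amplitude amplitude of the slide target sinusoid in Angstrom
#'   (default 0.3); shift target is identically zero.
#' @return a `nucleosome_template`: list with `L`, `omega` (radians/step),
#'   `rho`, and per-step target vectors `roll_t`, `tilt_t`, `twist_t`,
#'   `shift_t`, `slide_t` (length `L - 1`).
#' @export
build_nucleosome_template <- function(window_len = 101L,
                                      helical_period = 10.0,
                                      curvature_amplitude = 4.5,
                                      slide_amplitude = 0.3) {
  if (window_len %% 2L == 0L)
    stop("window_len must be odd, got ", window_len)
  if (window_len < 75L || window_len > 147L)
    stop("window_len must be in [75, 147], got ", window_len)
  if (helical_period <= 0) stop("helical_period must be > 0")
  if (curvature_amplitude < 0) stop("curvature_amplitude must be >= 0")
  L <- as.integer(window_len)
  omega <- 2 * pi / helical_period
  j <- seq_len(L - 1L)
  ctr <- (L - 1L) / 2
  phase <- omega * (j - ctr)
  structure(list(
    L = L,
    omega = omega,
    rho = curvature_amplitude,
    center_step = ctr,
    roll_t  = curvature_amplitude * cos(phase),
    tilt_t  = curvature_amplitude * sin(phase),
    twist_t = rep(360 / helical_period, L - 1L),
    shift_t = rep(0, L - 1L),
    slide_t = slide_amplitude * cos(phase)
  ), class = "nucleosome_template")
}

#' @export
print.nucleosome_template <- function(x, ...) {
  cat(sprintf(paste0("<nucleosome_template> L=%d bp, period=%.3f bp/turn, ",
                     "curvature=%.2f deg/step\n"),
              x$L, 2 * pi / x$omega, x$rho))
  invisible(x)
}
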