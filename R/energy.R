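ENERGY_KINDS <- c(bending = "bending", shearing = "shearing")

# parameter indices entering each energy kind; cross-terms between the
# bending group {roll, tilt} and the shearing group {shift, slide} (and all
# twist/rise terms) are excluded by construction.
energy_param_idx <- function(kind) {
  switch(match.arg(kind, ENERGY_KINDS),
         bending  = c(2L, 3L),   # roll, tilt
         shearing = c(4L, 5L))   # shift, slide
}

# dinucleotide step codes 1..16 (A=1..T=4, code = 4*(b1-1)+b2); NA for steps
# touching a non-ACGT base.  Input: uppercase sequence string.
dinuc_codes <- function(seq) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n <- length(b)
  if (n < 2L) return(integer(0))
  4L * (b[-n] - 1L) + b[-1L]
}

template_targets <- function(template, idx) {
  rbind(roll = template$roll_t, tilt = template$tilt_t,
        twist = template$twist_t, shift = template$shift_t,
        slide = template$slide_t,
        rise = rep(0, length(template$roll_t)))[PARAM_NAMES[idx], ,
                                                drop = FALSE]
}

#' Deformation energy of a single window
#'
#' Harmonic cost, in kT per base-pair step, of deforming `seq` from its
#' sequence-dependent equilibrium step geometry onto the nucleosome
#' template:
#' `E = (1/(L-1)) * sum_j 1/2 * (theta_t(j) - theta_0(d_j))' F(d_j)
#' (theta_t(j) - theta_0(d_j))`,
#' restricted to the roll/tilt block (`kind = "bending"`) or the shift/slide
#' block (`kind = "shearing"`).
#'
#' This is the reference implementation (explicit per-step quadratic forms);
#' [energy_track()] computes the same quantity for all windows of a long
#' sequence via a precomputed per-step cost table and is tested against this
#' function.
#'
#' @param seq DNA string of length `template$L` (A/C/G/T; see `n_policy`).
#' @param template a [build_nucleosome_template()] object.
#' @param params a [read_step_params()] table.
#' @param kind `"bending"` or `"shearing"`.
#' @param n_policy what to do with windows containing non-ACGT bases:
#'   `"reject"` (default, error) or `"average"` (substitute the mean step
#'   cost over the 16 dinucleotides at that step).
#' @return energy in kT/bps (a single number).
#' @export
window_energy <- function(seq, template, params = default_step_params(),
                          kind = c("bending", "shearing"),
                          n_policy = c("reject", "average")) {
  kind <- match.arg(kind)
  n_policy <- match.arg(n_policy)
  seq <- toupper(seq)
  L <- template$L
  if (nchar(seq) != L)
    stop("sequence length ", nchar(seq), " != template window ", L)
  d <- dinuc_codes(seq)
  if (anyNA(d) && n_policy == "reject")
    stop("window contains non-ACGT bases (n_policy = \"reject\")")
  idx <- energy_param_idx(kind)
  tt <- template_targets(template, idx)
  e <- 0
  for (j in seq_len(L - 1L)) {
    if (is.na(d[j])) {
      # average cost over all steps at this template position
      cj <- vapply(seq_len(16L), function(k)
        step_cost(k, tt[, j], params, idx), numeric(1))
      e <- e + mean(cj)
    } else {
      e <- e + step_cost(d[j], tt[, j], params, idx)
    }
  }
  e / (L - 1L)
}

step_cost <- function(code, target, params, idx) {
  delta <- target - params$theta0[idx, code]
  0.5 * drop(delta %*% params$stiffness[[code]][idx, idx] %*% delta)
}

# 16 x (L-1) matrix of per-step costs: cost of placing dinucleotide d at
# template step j.  Shared by energy_track for all windows.
step_cost_matrix <- function(template, params, kind) {
  idx <- energy_param_idx(kind)
  tt <- template_targets(template, idx)
  nstep <- ncol(tt)
  C <- matrix(0, 16L, nstep)
  for (code in seq_len(16L)) {
    M <- params$stiffness[[code]][idx, idx]
    d1 <- tt[1, ] - params$theta0[idx[1], code]
    d2 <- tt[2, ] - params$theta0[idx[2], code]
    C[code, ] <- 0.5 * (M[1, 1] * d1^2 + 2 * M[1, 2] * d1 * d2 +
                          M[2, 2] * d2^2)
  }
  C
}

#' Sliding-window deformation-energy track
#'
#' Computes [window_energy()] for every `L`-bp window of a sequence; the
#' value is assigned to the window's central base.  Positions whose window
#' contains a non-ACGT base are `NA` under the default policy.
#'
#' @param seq DNA string (length >= `template$L`).
#' @param template,params,kind,n_policy as in [window_energy()].
#' @param seqname name recorded on the track.
#' @return an `energy_track` (raw, i.e. not yet unit-range normalized) with
#'   one value per position `i` in `[(L-1)/2, nchar(seq)-1-(L-1)/2]`
#'   (0-based).
#' @export
energy_track <- function(seq, template, params = default_step_params(),
                         kind = c("bending", "shearing"),
                         n_policy = c("reject", "average"),
                         seqname = "seq") {
  kind <- match.arg(kind)
  n_policy <- match.arg(n_policy)
  seq <- toupper(seq)
  L <- template$L
  N <- nchar(seq)
  if (N < L)
    stop("sequence (", N, " bp) shorter than window (", L, " bp): empty track")
  C <- step_cost_matrix(template, params, kind)
  if (n_policy == "average") C <- rbind(C, colMeans(C))
  d <- dinuc_codes(seq)
  if (n_policy == "average") d[is.na(d)] <- 17L
  nwin <- N - L + 1L
  E <- numeric(nwin)
  for (j in seq_len(L - 1L)) E <- E + C[d[j:(j + nwin - 1L)], j]
  new_track(seqname, (L - 1L) %/% 2L, E / (L - 1L), class_ = "energy_track",
            window = L, kind = kind, normalized = FALSE)
}

#' Normalize an energy track to the unit range [-1, 1]
#'
#' Affine map `E' = 2 (E - emin) / (emax - emin) - 1`.  By default `emin` and
#' `emax` are the extrema of the supplied track(s); for genome-scale work
#' pass the extrema computed over the whole track set so all sequences share
#' one normalization.  Values from a foreign normalization are clipped to
#' `[-1, 1]`.
#'
#' @param track an `energy_track` (raw).
#' @param emin,emax normalization constants; default: extrema of `track`.
#' @return a unit-range `energy_track` (attributes `normalized`, `emin`,
#'   `emax` set).
#' @export
normalize_unit_range <- function(track, emin = NULL, emax = NULL) {
  stopifnot(inherits(track, "energy_track"))
  v <- track$values
  if (is.null(emin)) emin <- min(v, na.rm = TRUE)
  if (is.null(emax)) emax <- max(v, na.rm = TRUE)
  if (emin >= emax) stop("invalid normalization: emin >= emax")
  z <- 2 * (v - emin) / (emax - emin) - 1
  z <- pmin(1, pmax(-1, z))
  new_track(track$seqname, track$start, z, class_ = "energy_track",
            window = attr(track, "window"), kind = attr(track, "kind"),
            normalized = TRUE, emin = emin, emax = emax)
}

#' Extrema of a set of raw energy tracks
#'
#' Convenience for genome-scale normalization: the min and max over the
#' defined values of all supplied tracks.
#' @param tracks list of raw `energy_track`s.
#' @return named numeric vector `c(emin=, emax=)`.
#' @export
energy_range <- function(tracks) {
  v <- unlist(lapply(tracks, function(t) t$values), use.names = FALSE)
  c(emin = min(v, na.rm = TRUE), emax = max(v, na.rm = TRUE))
}
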