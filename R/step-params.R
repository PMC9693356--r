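PARAM_NAMES <- c("twist", "roll", "tilt", "shift", "slide", "rise")
DINUCS <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))

#' Read a base-pair-step elastic parameter table
#'
#' The table drives the deformation-energy model: for each of the 16
#' dinucleotide steps it supplies the equilibrium values of the six base-pair
#' step parameters (twist, roll, tilt in degrees; shift, slide, rise in
#' Angstrom) and a symmetric positive-semidefinite 6x6 stiffness matrix in kT
#' per squared unit.
#'
#' File format: plain text, `#` comments, a header row, then one row per
#' dinucleotide: `step`, the 6 equilibrium values, and the 21 unique entries
#' of the stiffness matrix (upper triangle, column-major:
#' (1,1),(1,2),(2,2),(1,3),(2,3),(3,3),...).
#'
#' @param path path to the table; the default is the parameter set packaged
#'   with rotpos (a constructed, reverse-complement-symmetric stand-in with
#'   crystallography-scale magnitudes — see `?default_step_params`).
#' @return a `step_param_table`: list with `theta0` (6 x 16 matrix of
#'   equilibrium values) and `stiffness` (list of 16 named 6x6 matrices).
#' @export
read_step_params <- function(path = system.file("extdata",
                                                "bpstep_params_synthetic.tsv",
                                                package = "rotpos")) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) != 16L || !setequal(df$step, DINUCS))
    stop("parameter table must have exactly one row per dinucleotide step")
  df <- df[match(DINUCS, df$step), ]
  theta0 <- t(as.matrix(df[, paste0("t0_", PARAM_NAMES)]))
  dimnames(theta0) <- list(PARAM_NAMES, DINUCS)
  ut <- upper.tri(matrix(0, 6, 6), diag = TRUE)
  kcols <- as.matrix(df[, 8:28])
  stiffness <- lapply(seq_len(16L), function(i) {
    M <- matrix(0, 6, 6, dimnames = list(PARAM_NAMES, PARAM_NAMES))
    M[ut] <- kcols[i, ]
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  })
  names(stiffness) <- DINUCS
  out <- structure(list(theta0 = theta0, stiffness = stiffness),
                   class = "step_param_table")
  validate_step_params(out)
  out
}

#' @rdname read_step_params
#' @export
default_step_params <- function() read_step_params()

validate_step_params <- function(p) {
  for (d in DINUCS) {
    M <- p$stiffness[[d]]
    if (any(abs(M - t(M)) > 1e-9)) stop("stiffness matrix not symmetric: ", d)
    if (any(diag(M) <= 0)) stop("non-positive diagonal stiffness: ", d)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9) stop("stiffness matrix not PSD: ", d)
  }
  # reverse-complement symmetry: twist/roll/slide/rise invariant, tilt/shift
  # flip sign; stiffness couplings involving exactly one of {tilt, shift}
  # flip sign.
  sgn <- c(1, 1, -1, -1, 1, 1)
  for (d in DINUCS) {
    r <- rc_step(d)
    if (any(abs(p$theta0[, d] * sgn - p$theta0[, r]) > 1e-6))
      warning("equilibrium values violate reverse-complement symmetry: ",
              d, "/", r)
    S <- outer(sgn, sgn)
    if (any(abs(p$stiffness[[d]] * S - p$stiffness[[r]]) > 1e-6))
      warning("stiffness violates reverse-complement symmetry: ", d, "/", r)
  }
  invisible(p)
}

rc_step <- function(d) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
}

#' @export
print.step_param_table <- function(x, ...) {
  cat("<step_param_table> 16 dinucleotide steps\n")
  cat("equilibrium values (theta0):\n")
  print(round(x$theta0, 3))
  invisible(x)
}
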