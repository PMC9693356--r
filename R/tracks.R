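#' Per-base genomic tracks
#'
#' All quantitative results in rotpos (deformation energies, positioning
#' scores, occupancies, rotational indices, strength statistics, NCP scores)
#' are represented as dense per-base tracks: a contiguous run of values on one
#' sequence, 0-based internally.  Undefined positions inside the run (for
#' example windows containing an ambiguous base) are `NA`.
#'
#' A track is a list with elements `seqname`, `start` (0-based position of the
#' first value) and `values`, carrying metadata in attributes.  Subclasses
#' (`energy_track`, `score_track`, `occupancy_track`, `rpi_track`,
#' `strength_track`, `ncp_track`) tag the quantity and its parameters.
#'
#' @param seqname sequence (chromosome) name.
#' @param start 0-based position of the first value.
#' @param values numeric vector; `NA` marks undefined positions.
#' @param class_ track subclass tag.
#' @param ... further metadata stored as attributes.
#' @return a `rotpos_track` object.
#' @export
new_track <- function(seqname, start, values, class_ = "rotpos_track", ...) {
  stopifnot(is.character(seqname), length(seqname) == 1L,
            is.numeric(start), length(start) == 1L, start >= 0)
  obj <- structure(list(seqname = seqname, start = as.integer(start),
                        values = as.numeric(values)),
                   class = unique(c(class_, "rotpos_track")))
  meta <- list(...)
  for (nm in names(meta)) attr(obj, nm) <- meta[[nm]]
  obj
}

#' @export
length.rotpos_track <- function(x) length(x$values)

#' 0-based positions covered by a track
#' @param x a track.
#' @return integer vector of positions, parallel to `track_values(x)`.
#' @export
track_positions <- function(x) x$start + seq_along(x$values) - 1L

#' Values of a track
#' @param x a track.
#' @export
track_values <- function(x) x$values

#' Look up track values at 0-based positions
#'
#' Positions outside the track's span return `NA`.
#' @param x a track.
#' @param pos integer positions (0-based).
#' @export
track_value_at <- function(x, pos) {
  idx <- pos - x$start + 1L
  idx[idx < 1L | idx > length(x$values)] <- NA_integer_
  x$values[idx]
}

#' @export
print.rotpos_track <- function(x, ...) {
  v <- x$values
  def <- sum(!is.na(v))
  cat(sprintf("<%s> %s:%d-%d  (%d positions, %d defined)\n",
              class(x)[1], x$seqname, x$start, x$start + length(v) - 1L,
              length(v), def))
  if (def > 0)
    cat(sprintf("  values: min %.4g  max %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  meta <- attributes(x)
  meta <- meta[setdiff(names(meta), c("names", "class"))]
  if (length(meta))
    cat("  meta:", paste(names(meta),
                         vapply(meta, function(m) paste(format(m), collapse = ","),
                                ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rotpos_track <- function(x, ...) {
  data.frame(seqname = x$seqname, pos = track_positions(x),
             value = x$values)
}

# rolling sum of x over windows of width w, NA whenever the window touches an
# NA.  Entry t of the result is the sum over x[t .. t+w-1]; the window "center"
# used by callers is offset floor(w/2) from the window start (for odd w the
# exact center, for even w the right-of-middle convention).
roll_sum <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  isna <- is.na(x)
  x0 <- x
  x0[isna] <- 0
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(isna))
  s <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  s[(cn[(w + 1):(n + 1)] - cn[1:(n - w + 1)]) > 0] <- NA_real_
  s
}

# centered weighted kernel sum: y_i = sum_k kernel[k] * x[i + k - half - 1],
# kernel of odd length 2*half+1.  Returns a vector shorter by 2*half with the
# implied new start offset handled by the caller.  NA propagates.
kernel_sum <- function(x, kernel) {
  w <- length(kernel)
  stopifnot(w %% 2L == 1L)
  n <- length(x)
  if (n < w) return(numeric(0))
  out <- numeric(n - w + 1L)
  for (j in seq_len(w)) out <- out + kernel[j] * x[j:(j + n - w)]
  out
}

# shrink a track by `half` positions on each side, replacing values
shrink_track <- function(x, half, values, class_, ...) {
  new_track(x$seqname, x$start + half, values, class_ = class_, ...)
}
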