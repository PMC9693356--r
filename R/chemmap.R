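#' Read an experimental nucleosome-center-positioning (NCP) score track
#'
#' Chemical nucleosome mapping yields a per-base score for how often a
#' nucleosome center (dyad) falls at each position.  Input is bedGraph
#' (0-based half-open, expanded to per-base values) or wig (1-based).
#' Negative scores are an error; positions with no datum are treated as
#' score 0; unsorted input is sorted with a warning; overlapping bedGraph
#' intervals are an error.
#'
#' @param path track file.
#' @param dialect `"auto"`, `"bedGraph"` or `"wig"`.
#' @return an `ncp_track` (dense, zero-filled over its span).
#' @export
read_ncp <- function(path, dialect = c("auto", "bedGraph", "wig")) {
  tr <- read_track(path, match.arg(dialect))
  v <- tr$values
  if (any(v < 0, na.rm = TRUE)) stop("negative NCP scores in ", path)
  v[is.na(v)] <- 0
  new_track(tr$seqname, tr$start, v, class_ = "ncp_track")
}

#' Center-weighted nucleosome occupancy from dyads or NCP scores
#'
#' Each dyad (or each scored NCP position) spreads its score over the
#' nucleosome footprint with the Gaussian center weight
#' `w_k = exp(-(1/2) (k/20)^2)` truncated at `|k| <= 73`:
#' `occ_i = sum_dyads score * w_{i - dyad}`.  Unscored dyad lists count 1
#' per dyad.  The operation is linear in the scores and
#' translation-equivariant.
#'
#' @param x a dyad data.frame (columns `chrom`, `pos`, optional `score`) as
#'   returned by [call_dyads()], or an `ncp_track` (every position with a
#'   positive score acts as a scored dyad).
#' @return an `occupancy_track` (model tag `"experimental"`) spanning
#'   `[min(dyad) - 73, max(dyad) + 73]`.
#' @export
center_weighted_occupancy <- function(x) {
  if (inherits(x, "ncp_track")) {
    keep <- which(x$values > 0)
    if (!length(keep)) stop("NCP track has no positive scores")
    pos <- track_positions(x)[keep]
    score <- x$values[keep]
    chrom <- x$seqname
  } else {
    stopifnot(is.data.frame(x), nrow(x) >= 1L)
    pos <- as.integer(x$pos)
    score <- if (is.null(x$score)) rep(1, nrow(x)) else as.numeric(x$score)
    chrom <- as.character(x$chrom[1])
    if (!all(x$chrom == chrom)) stop("dyads span multiple chromosomes")
  }
  half <- 73L
  w <- gaussian_weights(half)
  start <- min(pos) - half
  occ <- numeric(max(pos) + half - start + 1L)
  for (i in seq_along(pos)) {
    at <- (pos[i] - half - start):(pos[i] + half - start) + 1L
    occ[at] <- occ[at] + score[i] * w
  }
  new_track(chrom, start, occ, class_ = "occupancy_track",
            model = "experimental")
}

#' Call nucleosome dyads from an NCP track (greedy, minimum spacing)
#'
#' Repeatedly accepts the highest-scoring remaining position and discards
#' every position strictly within `min_dist` of it; ties are broken by score
#' (descending) then position (ascending), so the call set is deterministic.
#' Two accepted dyads may be exactly `min_dist` apart ("at least `min_dist`
#' bp").  Positions with score 0 are never called.
#'
#' The redundant-map convention is `min_dist = 10`; a unique
#' (non-overlapping nucleosome) map conventionally uses `min_dist = 107`
#' (a field convention, not tied to any particular dataset).
#'
#' @param ncp an `ncp_track`.
#' @param min_dist minimum center-to-center spacing in bp (>= 1).
#' @param map_type label recorded on the result (`"redundant"` or
#'   `"unique"`; informational).
#' @return data.frame (`chrom`, `pos`, `score`) sorted by position, with
#'   attribute `map_type`; zero rows if the track is all zero.
#' @export
call_dyads <- function(ncp, min_dist = 10L,
                       map_type = c("redundant", "unique")) {
  stopifnot(inherits(ncp, "ncp_track"))
  map_type <- match.arg(map_type)
  if (min_dist < 1L) stop("min_dist must be >= 1")
  keep <- which(ncp$values > 0)
  pos <- track_positions(ncp)[keep]
  score <- ncp$values[keep]
  ord <- order(-score, pos)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - pos[i]) >= min_dist))
      accepted <- c(accepted, pos[i])
  }
  accepted <- sort(accepted)
  out <- data.frame(chrom = rep(ncp$seqname, length(accepted)),
                    pos = accepted,
                    score = ncp$values[accepted - ncp$start + 1L])
  attr(out, "map_type") <- map_type
  attr(out, "min_dist") <- as.integer(min_dist)
  out
}
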