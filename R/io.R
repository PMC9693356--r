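#' Read a multi-record FASTA file
#'
#' Sequences are uppercased; `N` and other IUPAC ambiguity codes are
#' preserved (downstream policies decide how to treat them).  Duplicate
#' record names are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a per-base track as bedGraph or fixed-step wig
#'
#' bedGraph is 0-based half-open (adjacent equal values are merged into one
#' interval); wig `fixedStep` is 1-based with `step=1 span=1` (a new block is
#' opened after each undefined stretch).  Undefined (`NA`) positions are
#' omitted in both dialects.  Output is written to a temporary file and
#' renamed, so a failed write leaves nothing partial.
#'
#' @param track a `rotpos_track`.
#' @param path output path.
#' @param dialect `"bedGraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, dialect = c("bedGraph", "wig")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "rotpos_track"))
  pos <- track_positions(track)
  val <- track$values
  keep <- !is.na(val)
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  if (!any(keep)) {
    warning("track has no defined values; writing empty file")
    file.create(tmp)
    file.rename(tmp, path)
    return(invisible(path))
  }
  pos <- pos[keep]; val <- val[keep]
  if (dialect == "bedGraph") {
    # merge runs of adjacent positions with identical values
    brk <- c(TRUE, diff(pos) != 1L | val[-1] != val[-length(val)])
    s <- pos[brk]
    e <- pos[c(which(brk)[-1] - 1L, length(pos))] + 1L
    con <- file(tmp, "w")
    writeLines(sprintf("%s\t%d\t%d\t%s", track$seqname, s, as.integer(e),
                       format(val[brk], digits = 15, trim = TRUE,
                              scientific = FALSE)), con)
    close(con)
  } else {
    brk <- c(TRUE, diff(pos) != 1L)
    grp <- cumsum(brk)
    con <- file(tmp, "w")
    for (g in unique(grp)) {
      i <- grp == g
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                         track$seqname, pos[i][1] + 1L), con)
      writeLines(format(val[i], digits = 15, trim = TRUE,
                        scientific = FALSE), con)
    }
    close(con)
  }
  file.rename(tmp, path)
  invisible(path)
}

#' Read a bedGraph or wig file into a per-base track
#'
#' bedGraph: 4 columns (chrom, start, end, value), 0-based half-open;
#' overlapping intervals are an error, unsorted input is sorted with a
#' warning.  wig: `fixedStep` and `variableStep` blocks (1-based).  Gaps
#' within the track span become `NA`.
#'
#' @param path input file.
#' @param dialect `"bedGraph"` or `"wig"` (default: guessed from content).
#' @return a `rotpos_track` (empty file gives a zero-length track with a
#'   warning).
#' @export
read_track <- function(path, dialect = c("auto", "bedGraph", "wig")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track\\b|browser\\b)", lines) &
                   nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty track file: ", path)
    return(new_track("NA", 0L, numeric(0)))
  }
  if (dialect == "auto")
    dialect <- if (any(grepl("^(fixed|variable)Step", lines))) "wig"
               else "bedGraph"
  if (dialect == "bedGraph") parse_bedgraph(lines) else parse_wig(lines)
}

parse_bedgraph <- function(lines) {
  f <- strsplit(lines, "\t| +")
  if (any(lengths(f) < 4L)) stop("malformed bedGraph line(s)")
  chrom <- vapply(f, `[[`, "", 1L)
  if (length(unique(chrom)) > 1L)
    stop("multi-chromosome tracks are not supported in one object; split by ",
         "chromosome first")
  s <- as.integer(vapply(f, `[[`, "", 2L))
  e <- as.integer(vapply(f, `[[`, "", 3L))
  v <- as.numeric(vapply(f, `[[`, "", 4L))
  if (anyNA(s) || anyNA(e) || anyNA(v) || any(e <= s))
    stop("malformed bedGraph intervals")
  o <- order(s)
  if (is.unsorted(s)) {
    warning("unsorted bedGraph input; sorting")
    s <- s[o]; e <- e[o]; v <- v[o]
  }
  if (any(s[-1] < e[-length(e)])) stop("overlapping bedGraph intervals")
  start <- s[1]
  vals <- rep(NA_real_, e[length(e)] - start)
  for (i in seq_along(s))
    vals[(s[i] - start + 1L):(e[i] - start)] <- v[i]
  new_track(chrom[1], start, vals)
}

parse_wig <- function(lines) {
  hdr_idx <- grep("^(fixed|variable)Step", lines)
  if (!length(hdr_idx)) stop("no wig block headers found")
  pos <- integer(0); val <- numeric(0); chrom <- NULL
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (b in seq_along(hdr_idx)) {
    h <- lines[hdr_idx[b]]
    body <- lines[(hdr_idx[b] + 1L):(bounds[b + 1L] - 1L)]
    if (hdr_idx[b] + 1L > bounds[b + 1L] - 1L) body <- character(0)
    get <- function(key, default = NA) {
      m <- regmatches(h, regexec(paste0(key, "=([^ ]+)"), h))[[1]]
      if (length(m) == 2L) m[2] else default
    }
    ch <- get("chrom")
    if (is.null(chrom)) chrom <- ch
    if (!identical(ch, chrom)) stop("multi-chromosome wig not supported")
    if (grepl("^fixedStep", h)) {
      start1 <- as.integer(get("start"))
      step <- as.integer(get("step", "1"))
      v <- as.numeric(body)
      p <- start1 - 1L + step * (seq_along(v) - 1L)
    } else {
      f <- strsplit(body, "\t| +")
      p <- as.integer(vapply(f, `[[`, "", 1L)) - 1L
      v <- as.numeric(vapply(f, `[[`, "", 2L))
    }
    pos <- c(pos, p); val <- c(val, v)
  }
  if (anyNA(pos) || anyNA(val)) stop("malformed wig body")
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  if (anyDuplicated(pos)) stop("duplicate wig positions")
  start <- pos[1]
  vals <- rep(NA_real_, pos[length(pos)] - start + 1L)
  vals[pos - start + 1L] <- val
  new_track(chrom, start, vals)
}

#' Write dyad calls as BED
#'
#' 0-based half-open; each dyad is a 1-bp interval, score in column 5.
#' @param dyads a data.frame from [call_dyads()] (columns `chrom`, `pos`,
#'   `score`).
#' @param path output path.
#' @export
write_dyads_bed <- function(dyads, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "w")
  writeLines(sprintf("%s\t%d\t%d\tdyad\t%s\t.", dyads$chrom, dyads$pos,
                     dyads$pos + 1L,
                     format(dyads$score, digits = 15, trim = TRUE)), con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
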