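#' Read genomic anchors (TSS, TTS, interval midpoints) with class labels
#'
#' Two input formats:
#' \describe{
#'   \item{BED}{BED3/BED6; the name field (column 4) supplies the class
#'     label (`"all"` if absent), column 6 the strand.  `anchor = "tss"`
#'     gives the strand-aware 5' end (start for `+`, `end - 1` for `-`),
#'     `"tts"` the 3' end, `"midpoint"` the interval midpoint rounded down
#'     (used for TF-binding-site intervals; strand is forced to `+`).}
#'   \item{refgene}{tab-separated table with a header naming at least
#'     `chrom`, `strand`, `txStart`, `txEnd` (0-based half-open, UCSC
#'     refGene convention) and optionally `name`/`name2`.  TSS = `txStart`
#'     for `+` genes, `txEnd - 1` for `-`; TTS mirrored.}
#' }
#' Strand `.` is treated as `+`; any other character is an error reporting
#' the offending lines.  Duplicate (chrom, position, strand) anchors are
#' collapsed to one record.  Class labels can also be supplied (or
#' overridden) via `classes`, a two-column (id, class) file or data.frame
#' matched against the name field.
#'
#' @param path anchor file.
#' @param format `"bed"` or `"refgene"`.
#' @param anchor `"tss"`, `"tts"` or `"midpoint"`.
#' @param classes optional two-column (id, class) file or data.frame.
#' @return an `anchor_set`: data.frame with `chrom`, `pos` (0-based),
#'   `strand`, `class`.
#' @export
read_anchors <- function(path, format = c("bed", "refgene"),
                         anchor = c("tss", "tts", "midpoint"),
                         classes = NULL) {
  format <- match.arg(format)
  anchor <- match.arg(anchor)
  if (!file.exists(path)) stop("anchor file not found: ", path)
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    chrom <- df[[1]]; s <- as.integer(df[[2]]); e <- as.integer(df[[3]])
    name <- if (ncol(df) >= 4) as.character(df[[4]]) else rep("all", nrow(df))
    strand <- if (ncol(df) >= 6) as.character(df[[6]]) else rep("+", nrow(df))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "strand", "txStart", "txEnd")
    if (!all(need %in% names(df)))
      stop("refgene table must name columns: ", paste(need, collapse = ", "))
    chrom <- df$chrom; s <- as.integer(df$txStart); e <- as.integer(df$txEnd)
    strand <- as.character(df$strand)
    name <- if (!is.null(df$name2)) as.character(df$name2)
            else if (!is.null(df$name)) as.character(df$name)
            else rep("all", nrow(df))
  }
  strand[strand == "."] <- "+"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand character on line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  pos <- switch(anchor,
                tss = ifelse(strand == "+", s, e - 1L),
                tts = ifelse(strand == "+", e - 1L, s),
                midpoint = (s + e - 1L) %/% 2L)
  if (anchor == "midpoint") strand <- rep("+", length(pos))
  cls <- name
  if (!is.null(classes)) {
    cm <- if (is.character(classes))
      utils::read.table(classes, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)
    else classes
    cls <- cm[[2]][match(name, cm[[1]])]
    cls[is.na(cls)] <- "unclassified"
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                    class = cls, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("chrom", "pos", "strand")]), , drop = FALSE]
  if (any(out$pos < 0)) stop("negative anchor positions")
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Strand-aware metagene profile of a track around anchors
#'
#' For each anchor the track values at signed offsets `-flank .. +flank` are
#' extracted (in gene direction: the window is reversed for `-` strand
#' anchors) and averaged per offset within each class, ignoring undefined
#' positions; per-offset contributing-anchor counts are reported.  Anchors
#' near a sequence edge contribute only their defined offsets.
#'
#' @param track a `rotpos_track`, or a named list of tracks keyed by
#'   sequence name for multi-chromosome anchor sets.
#' @param anchors an [read_anchors()] `anchor_set` (or any data.frame with
#'   `chrom`, `pos`, `strand`, `class`).
#' @param flank half-width of the profile in bp (default 1000).
#' @param stat `"mean"` (plain average, the convention for occupancy
#'   profiles) or `"median"`.
#' @return named list (one element per class) of `metagene_profile`
#'   data.frames with columns `offset`, `mean` (or `median`), `count`.
#'   Classes with zero usable anchors are skipped with a warning.
#' @export
metagene_profile <- function(track, anchors, flank = 1000L,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (inherits(track, "rotpos_track")) {
    tracks <- list(track)
    names(tracks) <- track$seqname
  } else tracks <- track
  flank <- as.integer(flank)
  offs <- -flank:flank
  out <- list()
  for (cl in unique(anchors$class)) {
    a <- anchors[anchors$class == cl, , drop = FALSE]
    rows <- matrix(NA_real_, nrow(a), length(offs))
    for (i in seq_len(nrow(a))) {
      tr <- tracks[[a$chrom[i]]]
      if (is.null(tr)) next
      v <- track_value_at(tr, a$pos[i] + offs)
      if (a$strand[i] == "-") v <- rev(v)
      rows[i, ] <- v
    }
    cnt <- colSums(!is.na(rows))
    if (all(cnt == 0)) {
      warning("class '", cl, "' has no usable anchors; skipped")
      next
    }
    m <- if (stat == "mean") colMeans(rows, na.rm = TRUE)
         else apply(rows, 2, stats::median, na.rm = TRUE)
    m[cnt == 0] <- NA_real_
    prof <- data.frame(offset = offs, value = m, count = cnt)
    names(prof)[2] <- stat
    class(prof) <- c("metagene_profile", "data.frame")
    attr(prof, "class_label") <- cl
    attr(prof, "flank") <- flank
    attr(prof, "n_anchors") <- nrow(a)
    out[[cl]] <- prof
  }
  if (!length(out)) stop("no class produced a profile")
  out
}

#' Write metagene profiles as TSV (one file per class)
#'
#' @param profiles result of [metagene_profile()].
#' @param prefix output path prefix; files are named
#'   `<prefix>.<class>.tsv`.
#' @return the written paths, invisibly.
#' @export
write_profiles <- function(profiles, prefix) {
  paths <- character(0)
  for (cl in names(profiles)) {
    path <- paste0(prefix, ".", gsub("[^A-Za-z0-9_.-]", "_", cl), ".tsv")
    tmp <- paste0(path, ".tmp")
    suppressWarnings(utils::write.table(profiles[[cl]], tmp, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    file.rename(tmp, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
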