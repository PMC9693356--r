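# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# .Random.seed afterwards (generators are pure functions of their arguments).
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

revcomp <- function(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")

#' Specification for a synthetic periodic-nucleosome genome
#'
#' Describes the stated world the generator emulates: `n_nucleosomes` dyads
#' `spacing` bp apart, each with a planted rotational signal — within +/-73
#' bp of a dyad, positions at phase 0 (mod `period`, relative to the dyad)
#' receive an A/T-class dinucleotide (AA/TT/TA) with probability `signal`,
#' and positions at half phase receive a G/C-class dinucleotide (GC/CG/GG)
#' with probability `signal`; everything else is drawn from `background`.
#' Linkers are random background (`linker = "random"`) or poly-A
#' (`"a-tract"`).
#'
#' The default signal period is 10.0 bp, deliberately distinct from the
#' analysis wave-packet default of 9.906 bp so the test surface also probes
#' small period mismatches.
#'
#' @param n_nucleosomes number of planted nucleosomes (default 50).
#' @param spacing dyad-to-dyad distance in bp, >= 147 (default 200).
#' @param period planted signal period in bp (default 10).
#' @param signal planting probability `s` in [0, 1] (default 1).
#' @param linker `"random"` or `"a-tract"`.
#' @param seed RNG seed (default 1).
#' @param background ACGT probabilities (default uniform).
#' @param margin background padding on each side of the array (default 150).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nucleosomes = 50L, spacing = 200L, period = 10,
                           signal = 1, linker = c("random", "a-tract"),
                           seed = 1L,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           margin = 150L) {
  linker <- match.arg(linker)
  if (spacing < 147L) stop("spacing must be >= 147 bp")
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]")
  stopifnot(n_nucleosomes >= 1L, period > 0, margin >= 80L)
  structure(list(n_nucleosomes = as.integer(n_nucleosomes),
                 spacing = as.integer(spacing), period = period,
                 signal = signal, linker = linker, seed = seed,
                 background = background / sum(background),
                 margin = as.integer(margin)),
            class = "synthetic_spec")
}

# plant the periodic dinucleotide signal of one nucleosome footprint into a
# character vector (modified in place and returned).  0-based dyad.
plant_footprint <- function(chars, dyad, period, s) {
  half <- 73L
  favored <- c("AA", "TT", "TA")
  disfavored <- c("GC", "CG", "GG")
  jr <- ceiling(-half / period):floor((half - 1) / period)
  for (j in jr) {
    g <- dyad + round(j * period)             # phase 0
    if (g >= 0 && g + 1 < length(chars) && stats::runif(1) <= s && s > 0) {
      din <- sample(favored, 1L)
      chars[g + 1L] <- substr(din, 1, 1)
      chars[g + 2L] <- substr(din, 2, 2)
    }
    g2 <- dyad + round(j * period + period / 2)  # half phase
    if (g2 >= dyad - half && g2 + 1 <= dyad + half &&
        g2 >= 0 && g2 + 1 < length(chars) && stats::runif(1) <= s && s > 0) {
      din <- sample(disfavored, 1L)
      chars[g2 + 1L] <- substr(din, 1, 1)
      chars[g2 + 2L] <- substr(din, 2, 2)
    }
  }
  chars
}

#' Generate a sequence with planted rotationally positioned nucleosomes
#'
#' @param spec a [synthetic_spec()].
#' @return list with `sequence` (character string), `truth` (list:
#'   `dyads` — 0-based planted dyad positions, `phase` — planted phase per
#'   dyad (all 0), `spec`).
#' @export
generate_periodic_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_nucleosomes
    dyads <- spec$margin + (seq_len(n) - 1L) * spec$spacing
    len <- 2L * spec$margin + (n - 1L) * spec$spacing + 1L
    chars <- sample(names(spec$background), len, replace = TRUE,
                    prob = spec$background)
    if (spec$linker == "a-tract") {
      foot <- rep(FALSE, len)
      for (d in dyads) {
        lo <- max(0L, d - 73L); hi <- min(len - 1L, d + 73L)
        foot[(lo + 1L):(hi + 1L)] <- TRUE
      }
      chars[!foot] <- "A"
    }
    for (d in dyads)
      chars <- plant_footprint(chars, d, spec$period, spec$signal)
    list(sequence = paste(chars, collapse = ""),
         truth = list(dyads = dyads, phase = rep(0, n), spec = spec))
  })
}

#' Generate a synthetic NCP score track from planted dyads
#'
#' Each planted dyad emits a score peak at `dyad + round(N(0, jitter_sd))`;
#' uniform background noise positions appear at `noise_rate` per bp with
#' scores in `(0, noise_score]`, small relative to `peak_score`.
#'
#' @param truth ground truth from [generate_periodic_sequence()] (or any
#'   list with a `dyads` element).
#' @param peak_score score emitted at each dyad (default 20).
#' @param jitter_sd Gaussian positional jitter of the peaks in bp
#'   (default 0).
#' @param noise_rate per-bp probability of a background noise position
#'   (default 0.01).
#' @param noise_score maximal noise score (default 1).
#' @param seed RNG seed (default 1).
#' @param seqname sequence name on the track.
#' @return an `ncp_track` spanning the dyad range + 150 bp margins.
#' @export
generate_ncp_track <- function(truth, peak_score = 20, jitter_sd = 0,
                               noise_rate = 0.01, noise_score = 1,
                               seed = 1L, seqname = "synth") {
  stopifnot(peak_score > 0, jitter_sd >= 0, noise_rate >= 0)
  dyads <- truth$dyads
  with_seed(seed, {
    start <- max(0L, min(dyads) - 150L)
    end <- max(dyads) + 150L
    v <- numeric(end - start + 1L)
    at <- dyads + as.integer(round(stats::rnorm(length(dyads), 0, jitter_sd)))
    at <- pmin(pmax(at, start), end)
    for (p in at) v[p - start + 1L] <- v[p - start + 1L] + peak_score
    noise <- which(stats::runif(length(v)) < noise_rate & v == 0)
    v[noise] <- stats::runif(length(noise), 0, noise_score)
    new_track(seqname, start, v, class_ = "ncp_track")
  })
}

#' Generate a gene fixture: planted nucleosome arrays downstream of TSSs
#'
#' Builds one synthetic chromosome carrying `n_plus + n_minus` genes.  Each
#' gene has, in gene-local coordinates, an A-tract nucleosome-depleted
#' region immediately upstream of the TSS and an array of `n_nucs` planted
#' periodic nucleosomes starting at `+1` dyad position TSS + 100 (spacing
#' 200 bp), built identically for every gene; minus-strand genes insert the
#' reverse complement, so all genes share the same structure in gene
#' direction.
#'
#' @param n_plus,n_minus number of `+` / `-` strand genes.
#' @param flank background flank retained around each gene (default 1000).
#' @param seed RNG seed.
#' @param n_nucs nucleosomes per gene array (default 4).
#' @param gene_gap spacing between consecutive gene blocks (default 500).
#' @return list with `sequence` (named character vector of length 1),
#'   `anchors` (an `anchor_set` of TSSs, class = `"plus"`/`"minus"`),
#'   `truth` (genomic dyad positions per gene, gene strands, NDR intervals).
#' @export
generate_gene_fixture <- function(n_plus = 5L, n_minus = 5L, flank = 1000L,
                                  seed = 1L, n_nucs = 4L, gene_gap = 500L) {
  stopifnot(n_plus + n_minus >= 1L)
  with_seed(seed, {
    ndr_len <- 120L
    arr_span <- (n_nucs - 1L) * 200L
    tss_local <- flank + ndr_len          # 0-based within the gene block
    block_len <- tss_local + 100L + arr_span + 73L + flank
    strands <- c(rep("+", n_plus), rep("-", n_minus))
    blocks <- character(length(strands))
    tss_g <- integer(length(strands))
    dyads_g <- vector("list", length(strands))
    ndr_g <- vector("list", length(strands))
    offset <- 0L
    for (i in seq_along(strands)) {
      chars <- sample(c("A", "C", "G", "T"), block_len, replace = TRUE)
      chars[(tss_local - ndr_len + 1L):tss_local] <- "A"   # NDR upstream
      dy_local <- tss_local + 100L + (seq_len(n_nucs) - 1L) * 200L
      for (d in dy_local) chars <- plant_footprint(chars, d, 10, 1)
      blk <- paste(chars, collapse = "")
      if (strands[i] == "+") {
        tss_g[i] <- offset + tss_local
        dyads_g[[i]] <- offset + dy_local
        ndr_g[[i]] <- offset + c(tss_local - ndr_len, tss_local - 1L)
      } else {
        blk <- revcomp(blk)
        tss_g[i] <- offset + (block_len - 1L) - tss_local
        dyads_g[[i]] <- offset + (block_len - 1L) - dy_local
        ndr_g[[i]] <- offset + (block_len - 1L) -
          c(tss_local - 1L, tss_local - ndr_len)
      }
      blocks[i] <- blk
      offset <- offset + block_len + gene_gap
    }
    gaps <- vapply(seq_along(strands), function(i)
      paste(sample(c("A", "C", "G", "T"), gene_gap, replace = TRUE),
            collapse = ""), "")
    seqstr <- paste(paste0(blocks, gaps), collapse = "")
    anchors <- data.frame(chrom = "synth", pos = tss_g, strand = strands,
                          class = ifelse(strands == "+", "plus", "minus"),
                          stringsAsFactors = FALSE)
    class(anchors) <- c("anchor_set", "data.frame")
    list(sequence = c(synth = seqstr), anchors = anchors,
         truth = list(dyads = dyads_g, strand = strands, tss = tss_g,
                      ndr = ndr_g))
  })
}
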