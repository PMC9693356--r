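#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the sequence-to-occupancy pipeline, validates
#' all of them against the module preconditions up front (before any
#' computation starts), and returns a `run_config`.
#'
#' @param fasta input FASTA path.
#' @param out_dir output directory (created if missing).
#' @param window energy window length in bp (odd; 75/101/129 supported;
#'   default 101).
#' @param beta Boltzmann factor for positioning scores (default 1).
#' @param period wave-packet period in bp (default 9.906).
#' @param sigma2 wave-packet envelope variance (default 400).
#' @param helical_period,curvature_amplitude template geometry (defaults
#'   10.0 bp/turn, 4.5 deg/step).
#' @param strength_window window for the std strength statistic (default
#'   147).
#' @param fft_window,fft_period window/period for the Fourier strength
#'   statistic (defaults 50, 10).
#' @param min_dist_redundant,min_dist_unique dyad-calling spacings
#'   (defaults 10, 107).
#' @param flank metagene flank (default 1000).
#' @param anchors optional anchor file (BED) for metagene output.
#' @param anchor_type anchor type for `anchors` (default `"tss"`).
#' @param params_file optional step-parameter table path (default:
#'   packaged table).
#' @param n_policy ambiguous-base policy (default `"reject"`, i.e. NA
#'   windows).
#' @param seed seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed matters only for synthetic inputs).
#' @return a validated `run_config` list.
#' @export
run_config <- function(fasta, out_dir, window = 101L, beta = 1,
                       period = 9.906, sigma2 = 400, helical_period = 10.0,
                       curvature_amplitude = 4.5, strength_window = 147L,
                       fft_window = 50L, fft_period = 10,
                       min_dist_redundant = 10L, min_dist_unique = 107L,
                       flank = 1000L, anchors = NULL, anchor_type = "tss",
                       params_file = NULL, n_policy = "reject", seed = 1L) {
  if (!file.exists(fasta)) stop("config: FASTA not found: ", fasta)
  if (window %% 2L == 0L || window < 75L || window > 147L)
    stop("config: window must be odd and in [75, 147]")
  if (period <= 0) stop("config: period must be > 0")
  if (sigma2 <= 0) stop("config: sigma2 must be > 0")
  if (strength_window %% 2L == 0L || strength_window < 11L)
    stop("config: strength_window must be odd and >= 11")
  if (fft_period >= fft_window) stop("config: fft_period must be < fft_window")
  if (min_dist_redundant < 1L || min_dist_unique < 1L)
    stop("config: min_dist values must be >= 1")
  if (!is.null(anchors) && !file.exists(anchors))
    stop("config: anchor file not found: ", anchors)
  structure(list(fasta = fasta, out_dir = out_dir, window = as.integer(window),
                 beta = beta, period = period, sigma2 = sigma2,
                 helical_period = helical_period,
                 curvature_amplitude = curvature_amplitude,
                 strength_window = as.integer(strength_window),
                 fft_window = as.integer(fft_window), fft_period = fft_period,
                 min_dist_redundant = as.integer(min_dist_redundant),
                 min_dist_unique = as.integer(min_dist_unique),
                 flank = as.integer(flank), anchors = anchors,
                 anchor_type = anchor_type, params_file = params_file,
                 n_policy = n_policy, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full sequence-to-occupancy pipeline
#'
#' FASTA -> bending and shearing energy tracks (unit-range normalized with
#' extrema shared across all records) -> Boltzmann positioning scores ->
#' model-1 occupancy (shearing channel) and rotational positioning index +
#' model-2 envelope occupancy (bending channel) -> optional metagene
#' profiles, plus a machine-readable JSON manifest of all parameters.  Any
#' stage failure aborts with the stage name; outputs are written atomically.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return named character vector of written artifact paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- stage("params", {
    if (is.null(config$params_file)) default_step_params()
    else read_step_params(config$params_file)
  })
  template <- stage("template", build_nucleosome_template(
    config$window, config$helical_period, config$curvature_amplitude))
  seqs <- stage("fasta", read_fasta(config$fasta))
  say("pipeline: ", length(seqs), " sequence(s)")
  artifacts <- character(0)
  outp <- function(nm) file.path(config$out_dir, nm)
  raw_bend <- stage("energy", lapply(names(seqs), function(nm)
    energy_track(seqs[[nm]], template, params, "bending",
                 n_policy = config$n_policy, seqname = nm)))
  raw_shear <- stage("energy", lapply(names(seqs), function(nm)
    energy_track(seqs[[nm]], template, params, "shearing",
                 n_policy = config$n_policy, seqname = nm)))
  rb <- energy_range(raw_bend)
  rs <- energy_range(raw_shear)
  model2_tracks <- list()
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    bend <- normalize_unit_range(raw_bend[[i]], rb["emin"], rb["emax"])
    shear <- normalize_unit_range(raw_shear[[i]], rs["emin"], rs["emax"])
    stage("write-energy", {
      write_track(raw_bend[[i]], outp(paste0(nm, ".bending.bedGraph")))
      write_track(raw_shear[[i]], outp(paste0(nm, ".shearing.bedGraph")))
    })
    pb <- positioning_scores(bend, config$beta)
    ps <- positioning_scores(shear, config$beta)
    occ1 <- stage("model1", occupancy_model1(ps))
    rpi <- stage("rpi", rotational_positioning_index(pb, config$sigma2,
                                                    config$period))
    occ2 <- stage("model2", envelope_occupancy(rpi))
    std <- stage("strength", rotational_strength_std(bend,
                                                     config$strength_window))
    stage("write-tracks", {
      write_track(occ1, outp(paste0(nm, ".occ_model1.bedGraph")))
      write_track(rpi, outp(paste0(nm, ".rpi.bedGraph")))
      write_track(occ2, outp(paste0(nm, ".occ_model2.bedGraph")))
      write_track(std, outp(paste0(nm, ".strength_std.bedGraph")))
    })
    model2_tracks[[nm]] <- occ2
    artifacts <- c(artifacts,
                   outp(paste0(nm, c(".bending.bedGraph",
                                     ".shearing.bedGraph",
                                     ".occ_model1.bedGraph", ".rpi.bedGraph",
                                     ".occ_model2.bedGraph",
                                     ".strength_std.bedGraph"))))
  }
  if (!is.null(config$anchors)) {
    anch <- stage("anchors", read_anchors(config$anchors, "bed",
                                          config$anchor_type))
    prof <- stage("metagene", metagene_profile(model2_tracks, anch,
                                               config$flank))
    artifacts <- c(artifacts,
                   stage("write-metagene",
                         write_profiles(prof, outp("metagene_model2"))))
  }
  manifest <- outp("manifest.json")
  stage("manifest", {
    cfg <- unclass(config)
    cfg$rotpos_version <- as.character(utils::packageVersion("rotpos"))
    cfg$energy_norm <- list(bending = as.list(rb), shearing = as.list(rs))
    tmp <- paste0(manifest, ".tmp")
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    file.rename(tmp, manifest)
  })
  artifacts <- c(artifacts, manifest)
  say("pipeline: wrote ", length(artifacts), " artifact(s) to ",
      config$out_dir)
  invisible(artifacts)
}
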