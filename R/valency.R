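## Frame-by-frame valency classification and ensemble aggregation:
## dock -> buried surface between docked ligands -> zero-tolerance rule ->
## per-trajectory bivalent-competent fractions and the cross-trajectory
## unweighted mean.

## positions of the scoring atoms within the ligand atom block
.scoringPositions <- function(template, scoringMode) {
  iLig <- resolveSelection(template@complex, template@ligandSel)
  if (scoringMode == "whole_ligand") return(seq_along(iLig))
  iCt <- resolveSelection(template@complex, template@ligandCterm)
  match(iCt, iLig)
}

#' Classify one dimer conformer as monovalent or bivalent-competent
#'
#' Docks the template ligand onto both monomers, measures the surface
#' area buried between the two docked ligands' scoring selections
#' (their carboxy-terminal domains by default), and applies the
#' zero-buried-surface rule: a frame whose buried area is at or below
#' `zeroTolerance` has no ligand-ligand contact and is bivalent-competent.
#' The tolerance (default 1 Angstrom^2) absorbs test-point discretisation
#' noise; the boundary is inclusive.
#'
#' @param frame dimer conformer [Structure].
#' @param monomer1,monomer2 [AtomSelection]s of the two monomers.
#' @param template a [BindingTemplate].
#' @param scoringMode `"cterm_domain"` (default) scores only the ligand
#'   carboxy-terminal domains; `"whole_ligand"` scores entire ligands.
#' @param probeRadius,nSpherePoints SASA parameters.
#' @param zeroTolerance buried area at or below this counts as zero,
#'   Angstrom^2.
#' @param rmsdCeiling dock-quality fit-RMSD threshold, Angstrom.
#' @param radiusTable element radius table for the ligand atoms.
#' @param trajectoryId,frameIndex,frameTime bookkeeping fields copied into
#'   the record.
#' @return one-row data.frame: `trajectory_id`, `frame_index`,
#'   `frame_time_ns`, `buried_area_A2`, `bivalent_competent`,
#'   `fit_rmsd_1_A`, `fit_rmsd_2_A`, `dock_quality_flag`.
#' @export
classifyFrame <- function(frame, monomer1, monomer2, template,
                          scoringMode = c("cterm_domain", "whole_ligand"),
                          probeRadius = 1.4, nSpherePoints = 960L,
                          zeroTolerance = 1.0, rmsdCeiling = 3.0,
                          radiusTable = defaultVdwRadii(),
                          trajectoryId = "traj", frameIndex = 0L,
                          frameTime = NA_real_) {
  scoringMode <- match.arg(scoringMode)
  docked <- withCallingHandlers(
    dockDimer(frame, monomer1, monomer2, template, rmsdCeiling),
    warning = function(w) {
      if (grepl("dock-quality", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pos <- .scoringPositions(template, scoringMode)
  g1 <- assignRadii(subsetStructure(docked@ligand1, pos), radiusTable)
  g2 <- assignRadii(subsetStructure(docked@ligand2, pos), radiusTable)
  bs <- buriedSurface(g1, g2, probeRadius = probeRadius,
                      nSpherePoints = nSpherePoints)
  data.frame(
    trajectory_id = trajectoryId,
    frame_index = as.integer(frameIndex),
    frame_time_ns = frameTime,
    buried_area_A2 = bs@value,
    bivalent_competent = bs@value <= zeroTolerance,
    fit_rmsd_1_A = docked@fitRmsd1,
    fit_rmsd_2_A = docked@fitRmsd2,
    dock_quality_flag = docked@qualityFlag1 || docked@qualityFlag2,
    stringsAsFactors = FALSE)
}

#' Classify every sampled frame of an ensemble
#'
#' Applies [classifyFrame()] to frames `1, 1+stride, 1+2*stride, ...`
#' (reported with 0-based `frame_index`), preserving order.  Deterministic:
#' identical inputs and parameters give identical records.
#'
#' @param ensemble an [Ensemble].
#' @param monomer1,monomer2,template,scoringMode,probeRadius,nSpherePoints
#'   passed to [classifyFrame()].
#' @param zeroTolerance,rmsdCeiling,radiusTable passed to [classifyFrame()].
#' @param frameStride sample every `frameStride`-th frame (default 1).
#' @return data.frame of per-frame records, one row per sampled frame.
#' @export
analyzeEnsemble <- function(ensemble, monomer1, monomer2, template,
                            scoringMode = c("cterm_domain", "whole_ligand"),
                            probeRadius = 1.4, nSpherePoints = 960L,
                            zeroTolerance = 1.0, rmsdCeiling = 3.0,
                            radiusTable = defaultVdwRadii(),
                            frameStride = 1L) {
  scoringMode <- match.arg(scoringMode)
  frameStride <- as.integer(frameStride)
  if (frameStride < 1L) stop("frameStride must be >= 1")
  sampled <- seq.int(1L, nFrames(ensemble), by = frameStride)
  recs <- lapply(sampled, function(i) {
    classifyFrame(ensemble@frames[[i]], monomer1, monomer2, template,
                  scoringMode = scoringMode, probeRadius = probeRadius,
                  nSpherePoints = nSpherePoints,
                  zeroTolerance = zeroTolerance, rmsdCeiling = rmsdCeiling,
                  radiusTable = radiusTable,
                  trajectoryId = ensemble@trajectoryId,
                  frameIndex = i - 1L,
                  frameTime = ensemble@frameTimes[i])
  })
  do.call(rbind, recs)
}

#' Summarise valency records across trajectories
#'
#' Per-trajectory bivalent-competent fraction (# bivalent frames / # frames)
#' and the unweighted arithmetic mean of those fractions across
#' trajectories — the headline statistic.  A frame-weighted pooled fraction
#' is reported alongside, and frames whose docking fit exceeded the RMSD
#' ceiling are counted per trajectory (their records are kept).
#'
#' @param records a data.frame of per-frame records (from
#'   [analyzeEnsemble()]), possibly spanning several `trajectory_id`s, or a
#'   list of such data.frames.
#' @param zeroTolerance the tolerance used when the records were produced
#'   (echoed in the summary).
#' @return an [EnsembleSummary].
#' @examples
#' recs <- data.frame(trajectory_id = rep(c("t1", "t2", "t3"), each = 10),
#'                    frame_index = rep(0:9, 3), frame_time_ns = NA_real_,
#'                    buried_area_A2 = 0,
#'                    bivalent_competent = rep(c(TRUE, FALSE), c(15, 15)),
#'                    fit_rmsd_1_A = 0, fit_rmsd_2_A = 0,
#'                    dock_quality_flag = FALSE)
#' summarizeValency(recs)
#' @export
summarizeValency <- function(records, zeroTolerance = 1.0) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (nrow(records) == 0L) stop("no records to summarise")
  ids <- unique(records$trajectory_id)
  byId <- split(records, factor(records$trajectory_id, levels = ids))
  if (any(vapply(byId, nrow, integer(1)) == 0L))
    stop("empty trajectory in records")
  frac <- vapply(byId, function(d) mean(d$bivalent_competent), numeric(1))
  nfr <- vapply(byId, nrow, integer(1))
  nflag <- vapply(byId, function(d) sum(d$dock_quality_flag), integer(1))
  new("EnsembleSummary",
      perTrajectoryFraction = frac,
      meanFraction = mean(frac),
      weightedMeanFraction = mean(records$bivalent_competent),
      nFramesPerTrajectory = nfr,
      nQualityFlagged = nflag,
      zeroTolerance = zeroTolerance,
      records = records)
}

#' Run the full valency pipeline on files
#'
#' Reads a multi-model ensemble PDB and a template bundle, classifies every
#' sampled frame, and writes `records.csv` (one row per frame) and
#' `summary.json` (fractions, mean, tolerance, config echo) into `outDir`.
#' Output is deterministic: two runs on identical inputs produce
#' byte-identical files.  Per-stage timings go to stderr.
#'
#' @param ensemblePath multi-model PDB file (one MODEL per frame).
#' @param templatePdbPath,templateConfigPath template bundle (see
#'   [readTemplateBundle()]).
#' @param outDir output directory (created if needed).
#' @param config named list overriding defaults: `monomer1_chains`,
#'   `monomer2_chains`, `probe_radius`, `n_sphere_points`, `zero_tolerance`,
#'   `stride`, `scoring_mode`, `rmsd_ceiling`.
#' @param writeComplexes also write each docked complex as
#'   `complex_<frame>.pdb`.
#' @return the [EnsembleSummary], invisibly.
#' @export
runValencyPipeline <- function(ensemblePath, templatePdbPath,
                               templateConfigPath, outDir,
                               config = list(), writeComplexes = FALSE) {
  defaults <- list(monomer1_chains = "A", monomer2_chains = "B",
                   probe_radius = "1.4", n_sphere_points = "960",
                   zero_tolerance = "1.0", stride = "1",
                   scoring_mode = "cterm_domain", rmsd_ceiling = "3.0")
  cfg <- utils::modifyList(defaults, lapply(config, as.character))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg, tPrev) {
    tNow <- proc.time()[["elapsed"]]
    message(sprintf("[bivalens] %s (%.2f s)", msg, tNow - tPrev))
    tNow
  }
  ens <- readPdb(ensemblePath, modelPolicy = "all",
                 trajectoryId = tools::file_path_sans_ext(basename(ensemblePath)))
  t1 <- stage(sprintf("read ensemble: %d frames x %d atoms",
                      nFrames(ens), nAtoms(ens)), t0)
  template <- readTemplateBundle(templatePdbPath, templateConfigPath)
  t2 <- stage("read template bundle", t1)
  m1 <- atomSelection(chains = strsplit(cfg$monomer1_chains, ",")[[1L]])
  m2 <- atomSelection(chains = strsplit(cfg$monomer2_chains, ",")[[1L]])
  records <- analyzeEnsemble(ens, m1, m2, template,
                             scoringMode = cfg$scoring_mode,
                             probeRadius = as.numeric(cfg$probe_radius),
                             nSpherePoints = as.integer(cfg$n_sphere_points),
                             zeroTolerance = as.numeric(cfg$zero_tolerance),
                             rmsdCeiling = as.numeric(cfg$rmsd_ceiling),
                             frameStride = as.integer(cfg$stride))
  t3 <- stage(sprintf("classified %d frames", nrow(records)), t2)
  summary <- summarizeValency(records,
                              zeroTolerance = as.numeric(cfg$zero_tolerance))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeValencyRecords(records, file.path(outDir, "records.csv"))
  writeValencySummary(summary, cfg, file.path(outDir, "summary.json"))
  if (writeComplexes) {
    for (i in seq_len(nFrames(ens))) {
      docked <- suppressWarnings(
        dockDimer(ens@frames[[i]], m1, m2, template,
                  rmsdCeiling = as.numeric(cfg$rmsd_ceiling)))
      writePdb(asStructure(docked),
               file.path(outDir, sprintf("complex_%04d.pdb", i - 1L)))
    }
  }
  stage("wrote outputs", t3)
  invisible(summary)
}

#' Write per-frame valency records as CSV
#'
#' Buried areas are serialised with full precision via [format()] on 15
#' significant digits so the file is byte-stable across runs.
#'
#' @param records data.frame of per-frame records.
#' @param path output path.
#' @return invisibly, `records`.
#' @export
writeValencyRecords <- function(records, path) {
  out <- records
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' Write an ensemble summary as JSON
#'
#' @param summary an [EnsembleSummary].
#' @param config named list echoed under `"config"`.
#' @param path output path.
#' @return invisibly, the list serialised.
#' @export
writeValencySummary <- function(summary, config, path) {
  x <- list(
    per_trajectory_fraction = as.list(summary@perTrajectoryFraction),
    mean_fraction = summary@meanFraction,
    weighted_mean_fraction = summary@weightedMeanFraction,
    n_frames_per_trajectory = as.list(summary@nFramesPerTrajectory),
    n_dock_quality_flagged = as.list(summary@nQualityFlagged),
    zero_tolerance_A2 = summary@zeroTolerance,
    config = config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}
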