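## End-to-end orchestration with reproducible configuration: simulate a
## dataset, profile replicates, compare conditions. Every run writes its
## resolved configuration alongside the outputs.

#' Default pipeline parameters
#'
#' One flat list of every stage parameter and its default: window alignable
#' content 1000 bp; read length 100; eUR segmentation r2 0.04, SD threshold
#' 1, minimum length 50 kb, gap tolerance 10 kb; outlier filtering r2 0.06
#' with SD threshold 2 (arm) / 3 (eUR); spline parameter 1e-15; zones of
#' more than 20 windows; smoothing gap limit 5 kb; variant window 50 kb,
#' alpha 0.01, region length > 200 kb; autocorrelation lags 1000; overlap
#' fraction 0.5; region merge distance 11 bp.
#'
#' @param ... overrides by name
#' @return named list of parameters
#' @export
defaultParams <- function(...) {
  p <- list(
    targetAlignable = 1000L, readLength = 100L,
    eurR2 = 0.04, eurSD = 1, eurMinLen = 50e3, eurMaxGap = 10e3,
    outlierR2 = 0.06, outlierSDArm = 2, outlierSDEUR = 3, minSeg = 5L,
    gcSpan = 0.4, splineP = 1e-15, minZone = 21L, smoothMaxGap = 5e3,
    variantWindow = 50e3, alpha = 0.01, minRegion = 200e3,
    acfLags = 1000L, overlapFraction = 0.5, mergeDistance = 11,
    perChromosomeAnchor = FALSE)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

writeRunConfig <- function(config, outdir) {
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

writeManifest <- function(outdir) {
  files <- setdiff(list.files(outdir), "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- data.frame(file = files, md5 = unname(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic dataset to disk
#'
#' Builds a [SyntheticTruth-class] (see [simulateTruth()]), simulates
#' `replicates` count tracks per condition and writes: one count table per
#' replicate, the truth eUR/PH BED files, the true-RT bedGraph, the resolved
#' configuration and a checksum manifest. `config$seed` is mandatory —
#' every file is reproducible bit for bit from the configuration.
#'
#' Conditions beyond the baseline are given as
#' `config$conditions$<name> = list(urRemoved =, rtShifts = list(chrom,
#' start, end, delta))` and are simulated from the perturbed truth
#' ([perturbCondition()]).
#'
#' @param config list (or YAML/JSON path) mirroring [simulateTruth()]
#'   arguments, plus `seed` (mandatory), `replicates` (default 2) and
#'   optional `conditions`
#' @param outdir output directory (created)
#' @return (invisibly) list with the truth objects and written file paths
#' @export
simulateDataset <- function(config = list(), outdir) {
  config <- resolveConfig(config)
  if (is.null(config$seed))
    stop("config must carry an explicit 'seed' for a reproducible run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  reps <- config$replicates %||% 2L
  truthArgs <- config[intersect(names(config), names(formals(simulateTruth)))]
  truth <- do.call(simulateTruth, truthArgs)

  conds <- list(baseline = truth)
  for (nm in names(config$conditions)) {
    cnd <- config$conditions[[nm]]
    shifts <- NULL
    if (!is.null(cnd$rtShifts)) {
      sh <- as.data.frame(cnd$rtShifts)
      shifts <- GRanges(sh$chrom, IRanges(start = sh$start + 1L, end = sh$end))
      shifts$delta <- sh$delta
    }
    conds[[nm]] <- perturbCondition(truth, rtShifts = shifts,
                                    urRemoved = isTRUE(cnd$urRemoved))
  }

  grid <- computeGC(truth@genome,
                    makeWindows(truth@genome,
                                config$targetAlignable %||% 1000L))
  files <- character(0)
  k <- 0L
  for (nm in names(conds)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      sim <- simulateDepth(conds[[nm]], grid = grid,
                           seed = config$seed + 1000L * k)
      f <- file.path(outdir, sprintf("counts_%s_rep%d.tsv", nm, r))
      writeCountTable(sim$track, f)
      files <- c(files, f)
    }
  }
  writeRegionsBed(truth@urRegions, file.path(outdir, "truth_eur.bed"))
  writeRegionsBed(truth@phRegions, file.path(outdir, "truth_ph.bed"))
  rtgr <- GRanges()
  g <- truth@genome
  for (i in seq_along(g@chromNames)) {
    n <- length(truth@rt@rt[[i]])
    rtgr <- suppressWarnings(c(rtgr, GRanges(g@chromNames[i],
                            IRanges(start = (seq_len(n) - 1) * g@grid + 1,
                                    width = g@grid),
                            score = truth@rt@rt[[i]])))
  }
  rtracklayer::export(rtgr, file.path(outdir, "true_rt.bedgraph"),
                      format = "bedGraph")
  writeRunConfig(config, outdir)
  writeManifest(outdir)
  invisible(list(truths = conds, grid = grid, countFiles = files,
                 outdir = outdir))
}

#' Profile replication timing from count tables
#'
#' Runs the full RT pipeline ([buildRTProfile()]) on each replicate count
#' table and writes, per replicate, the rawRT and smoothed bedGraphs and
#' the quartile BED, plus quartile cutoffs, a QC JSON (pairwise replicate
#' correlations and an autocorrelation summary) and the resolved parameters.
#'
#' @param countFiles character vector of count-table paths (or a list of raw
#'   [DepthTrack-class] objects), one per replicate
#' @param ph `GRanges` of PH regions, or a BED path, or `NULL`
#' @param publishedUR optional prior UR regions (`GRanges` or BED path)
#' @param params see [defaultParams()]
#' @param outdir output directory, or `NULL` to skip writing
#' @param quartileOn `smoothed` (default) or `rawRT`
#' @return (invisibly) list with `profiles` (one [RTProfile-class] per
#'   replicate) and `qc`
#' @export
profileRT <- function(countFiles, ph = NULL, publishedUR = NULL,
                      params = defaultParams(), outdir = NULL,
                      quartileOn = "smoothed") {
  if (length(countFiles) == 0L) stop("no input count tables")
  tracks <- lapply(countFiles, function(f)
    if (is(f, "DepthTrack")) f else readCountTable(f))
  if (is.character(ph)) ph <- readRegionsBed(ph, label = "PH")
  if (is.null(ph)) ph <- GRanges()
  if (is.character(publishedUR))
    publishedUR <- readRegionsBed(publishedUR, label = "published_UR")
  profiles <- lapply(tracks, buildRTProfile, ph = ph,
                     publishedUR = publishedUR, params = params,
                     quartileOn = quartileOn)
  qc <- list()
  if (length(profiles) > 1L) {
    prs <- list()
    for (i in seq_along(profiles)) for (j in seq_len(i - 1L)) {
      r <- rtCorrelation(profiles[[j]], profiles[[i]], on = "smoothed")
      prs[[sprintf("rep%d_vs_rep%d", j, i)]] <- r$r
    }
    qc$replicate_r <- prs
  }
  ac <- rtAutocorrelation(rawRT(profiles[[1L]]),
                          nLags = min(params$acfLags,
                                      length(profiles[[1L]]@rawRT) - 1L))
  qc$acf <- list(lag1 = ac[1L], lag10 = ac[min(10L, length(ac))],
                 lag50 = ac[min(50L, length(ac))])
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(profiles)) {
      pr <- profiles[[i]]
      writeBedGraph(rawRT(pr), file.path(outdir, sprintf("rawRT_rep%d.bedgraph", i)))
      writeBedGraph(smoothedRT(pr),
                    file.path(outdir, sprintf("smoothedRT_rep%d.bedgraph", i)))
      grid <- windowGrid(pr)
      q <- quartiles(pr)
      ok <- !is.na(q)
      qb <- granges(grid)[ok]; qb$label <- as.character(q[ok])
      writeRegionsBed(qb, file.path(outdir, sprintf("quartiles_rep%d.bed", i)))
      jsonlite::write_json(as.list(quartileCutoffs(pr)),
                           file.path(outdir, sprintf("cutoffs_rep%d.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(qc, file.path(outdir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeRunConfig(params, outdir)
    writeManifest(outdir)
  }
  invisible(list(profiles = profiles, qc = qc))
}

#' Compare two conditions and call RT-variant regions
#'
#' @param groupA,groupB lists of [RTProfile-class]s (e.g. from
#'   [profileRT()]) or rawRT tracks
#' @param params see [defaultParams()]
#' @param outdir output directory, or `NULL` to skip writing
#' @return (invisibly) the [VariantTable-class]
#' @export
compareRT <- function(groupA, groupB, params = defaultParams(),
                      outdir = NULL) {
  vt <- callVariants(groupA, groupB, window = params$variantWindow,
                     alpha = params$alpha, minRegion = params$minRegion)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(variantStats(vt), file.path(outdir, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(variantRegions(vt)))
      writeRegionsBed(variantRegions(vt), file.path(outdir, "variants.bed"))
    else file.create(file.path(outdir, "variants.bed"))
    writeRunConfig(params, outdir)
    writeManifest(outdir)
  }
  invisible(vt)
}
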