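## End-to-end pipeline: generate -> write imzML -> extract -> normalize ->
## threshold -> spatial stats -> group stats, with a reproducible manifest.

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the analysis in one object and validates it up
#' front (in particular, the ion-target registry must contain the
#' budesonide, internal-standard and heme targets) so that configuration
#' errors surface before any computation.
#'
#' @param outputDir directory for all pipeline outputs.
#' @param seed master seed; recorded in the manifest and used for every
#'   source of randomness.
#' @param nPerGroup sections per treated group (default 5, the study size).
#' @param registry named list of \linkS4class{IonTarget}s.
#' @param thresholdQuantile quantile of pooled control intensities used as
#'   the detection threshold.
#' @param connectivity clump adjacency rule.
#' @param alphaMm alpha-hull length parameter (mm).
#' @param binEdgesMm distance-profile bin edges (mm).
#' @param maskMinFraction tissue-mask threshold as a fraction of the median
#'   positive heme intensity.
#' @param generatorParams template \linkS4class{GeneratorParams} for the
#'   synthetic cohort.
#' @param writeImzml write each section as an imzML pair under
#'   \code{outputDir/imzml} (default TRUE).
#' @return A list of class \code{"msiPipelineConfig"}.
#' @export
pipelineConfig <- function(outputDir = tempfile("msi_run_"), seed = 1L,
                           nPerGroup = 5L, registry = ionTargetRegistry(),
                           thresholdQuantile = 0.99,
                           connectivity = c("8-neighbor", "4-neighbor"),
                           alphaMm = 1.2, binEdgesMm = c(0, 3, 6, 9, 12),
                           maskMinFraction = 0.05,
                           generatorParams = GeneratorParams("dispersed"),
                           writeImzml = TRUE) {
  connectivity <- match.arg(connectivity)
  need <- c("budesonide", "internal_standard", "heme")
  missing <- setdiff(need, names(registry))
  if (length(missing))
    stop("configuration error: registry is missing target(s): ",
         paste(missing, collapse = ", "))
  for (t in registry) validObject(t)
  if (thresholdQuantile <= 0 || thresholdQuantile > 1)
    stop("configuration error: thresholdQuantile must be in (0, 1]")
  validObject(generatorParams)
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              nPerGroup = as.integer(nPerGroup), registry = registry,
              thresholdQuantile = thresholdQuantile,
              connectivity = connectivity, alphaMm = alphaMm,
              binEdgesMm = binEdgesMm, maskMinFraction = maskMinFraction,
              generatorParams = generatorParams, writeImzml = writeImzml)
  class(cfg) <- "msiPipelineConfig"
  cfg
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outputDir")]), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(stage, sectionId, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed for section '%s': %s",
                 stage, sectionId, conditionMessage(e)), call. = FALSE))
}

#' Analyze one section against a fixed detection threshold
#'
#' The per-section arm of the pipeline: extract the heme, internal-standard
#' and budesonide images, build the tissue mask, normalize, threshold,
#' z-score, bin in quartiles, detect clumps, estimate the alpha-hull border
#' and the distance-to-border profile of the 4th-quartile pixels, and (when
#' a companion SP-C dataset is given) score budesonide/SP-C colocalization.
#'
#' @param budDataset budesonide-acquisition \linkS4class{MSIDataset}.
#' @param spcDataset optional companion SP-C \linkS4class{MSIDataset}.
#' @param threshold control-derived detection threshold (normalized
#'   intensity); use \code{\link{controlThreshold}}.
#' @param registry ion-target registry.
#' @param connectivity,alphaMm,binEdgesMm,maskMinFraction tunables as in
#'   \code{\link{pipelineConfig}}.
#' @return A list with the section's images, mask, quartile map, clumps,
#'   border, distance profile, clump summary and colocalization score.
#' @export
analyzeSection <- function(budDataset, spcDataset = NULL, threshold,
                           registry = ionTargetRegistry(),
                           connectivity = "8-neighbor", alphaMm = 1.2,
                           binEdgesMm = c(0, 3, 6, 9, 12),
                           maskMinFraction = 0.05) {
  id <- sectionId(budDataset)
  heme <- .stage("extract", id,
                 extractIonImage(budDataset, registry$heme))
  isImg <- .stage("extract", id,
                  extractIonImage(budDataset, registry$internal_standard))
  bud <- .stage("extract", id,
                extractIonImage(budDataset, registry$budesonide))
  mask <- .stage("tissue-mask", id,
                 tissueMaskFromHeme(heme, minFraction = maskMinFraction))
  budNorm <- .stage("normalize", id, normalizeImage(bud, isImg))
  above <- .stage("threshold", id,
                  aboveThresholdMap(budNorm, mask, threshold))
  z <- .stage("zscore", id, zscoreSection(budNorm, mask))
  qmap <- .stage("quartiles", id, quartileBin(z, mask))
  clumps <- .stage("clumps", id, findClumps(qmap, connectivity))
  border <- .stage("border", id, alphaHullBorder(mask, alphaMm))
  profile <- .stage("distance-profile", id,
                    distanceProfile(qmap, border, pixelPitch(budDataset),
                                    binEdgesMm))
  coloc <- NA_real_
  if (!is.null(spcDataset)) {
    spcImg <- .stage("extract-spc", id,
                     extractIonImage(spcDataset, registry$spc))
    coloc <- tryCatch(colocalizationScore(budNorm, spcImg, mask),
                      error = function(e) NA_real_)
  }
  list(sectionId = id, group = groupLabel(budDataset), mask = mask,
       budNormalized = budNorm, aboveThreshold = above, zscored = z,
       quartileMap = qmap, clumps = clumps, border = border,
       distanceProfile = profile, clumpSummary = clumpSummary(clumps),
       nAboveThreshold = sum(!is.na(above@values)),
       normalizationDropped = budNorm@dropTally,
       logIntensity = logIntensityValues(budNorm, mask),
       colocalization = coloc)
}

## Threshold from the control sections of a cohort.
.cohortThreshold <- function(sections, registry, quantile, maskMinFraction) {
  ctrl <- Filter(function(s) groupLabel(s$budesonide) == "control", sections)
  if (!length(ctrl)) stop("cohort has no control sections")
  imgs <- list(); msks <- list()
  for (s in ctrl) {
    heme <- extractIonImage(s$budesonide, registry$heme)
    isImg <- extractIonImage(s$budesonide, registry$internal_standard)
    bud <- extractIonImage(s$budesonide, registry$budesonide)
    msk <- tissueMaskFromHeme(heme, minFraction = maskMinFraction)
    imgs <- c(imgs, list(normalizeImage(bud, isImg)))
    msks <- c(msks, list(msk))
  }
  controlThreshold(imgs, msks, quantile)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, optionally writes each section as an imzML pair,
#' derives the control-based detection threshold, analyzes every section,
#' runs the group comparisons (dispersed vs clumpy clump statistics;
#' per-bin distance-fraction tests) and writes delimited per-section tables
#' plus a JSON summary and a manifest (seed, configuration hash, package
#' version, per-file checksums). Rerunning with the same configuration
#' reproduces identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the per-section results, the group
#'   comparisons, the threshold and the manifest.
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "msiPipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outputDir, "sections"), showWarnings = FALSE)

  cohort <- generateCohort(config$nPerGroup, config$seed,
                           config$generatorParams)
  sections <- cohort$sections

  files <- character(0)
  if (config$writeImzml) {
    imzdir <- file.path(config$outputDir, "imzml")
    dir.create(imzdir, showWarnings = FALSE)
    for (nm in names(sections)) {
      p <- writeImzML(sections[[nm]]$budesonide, file.path(imzdir, nm))
      files <- c(files, p, sub("\\.imzML$", ".ibd", p))
    }
  }

  threshold <- .cohortThreshold(sections, config$registry,
                                config$thresholdQuantile,
                                config$maskMinFraction)

  results <- lapply(sections, function(s)
    analyzeSection(s$budesonide, s$spc, threshold,
                   registry = config$registry,
                   connectivity = config$connectivity,
                   alphaMm = config$alphaMm,
                   binEdgesMm = config$binEdgesMm,
                   maskMinFraction = config$maskMinFraction))

  ## per-section exports
  secdir <- file.path(config$outputDir, "sections")
  for (r in results) {
    d <- file.path(secdir, r$sectionId)
    dir.create(d, showWarnings = FALSE)
    wt <- function(x, f) {
      p <- file.path(d, f)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, p)
    }
    wt(intensityValues(r$budNormalized), "normalized_intensity.tsv")
    wt(quartileLabels(r$quartileMap), "quartile_labels.tsv")
    sz <- clumpSizes(r$clumps)
    wt(data.frame(clump = seq_along(sz), sizePx = sz), "clumps.tsv")
    rings <- borderRings(r$border)
    wt(do.call(rbind, lapply(seq_along(rings), function(k)
      data.frame(ring = k, x_mm = rings[[k]][, 1L],
                 y_mm = rings[[k]][, 2L]))), "border_rings.tsv")
    pr <- r$distanceProfile
    wt(data.frame(binStartMm = pr@binEdgesMm[-length(pr@binEdgesMm)],
                  binEndMm = pr@binEdgesMm[-1L], count = pr@binCounts,
                  fraction = pr@binFractions), "distance_profile.tsv")
  }

  groupOf <- vapply(results, `[[`, character(1), "group")
  disp <- results[groupOf == "dispersed"]
  clum <- results[groupOf == "clumpy"]
  comparisons <- list()
  if (length(disp) >= 2L && length(clum) >= 2L) {
    comparisons$clumps <- compareClumpStats(
      lapply(disp, `[[`, "clumps"), lapply(clum, `[[`, "clumps"))
    comparisons$distanceBins <- compareDistanceBins(
      lapply(disp, `[[`, "distanceProfile"),
      lapply(clum, `[[`, "distanceProfile"))
  }

  summary <- list(
    seed = config$seed, threshold = threshold,
    sections = lapply(results, function(r) list(
      sectionId = r$sectionId, group = r$group,
      tissuePixels = sum(maskMatrix(r$mask)),
      clumpCount = r$clumpSummary$count,
      clumpMedianSizePx = r$clumpSummary$medianSizePx,
      nAboveThreshold = r$nAboveThreshold,
      normalizationDropped = r$normalizationDropped,
      colocalization = r$colocalization,
      distanceBinFractions = r$distanceProfile@binFractions)),
    comparisons = if (length(comparisons)) list(
      clumpCount = list(p = pValue(comparisons$clumps$count),
                        method = comparisons$clumps$count@method),
      clumpMedianSize = list(p = pValue(comparisons$clumps$medianSize),
                             method = comparisons$clumps$medianSize@method),
      distanceBins = lapply(comparisons$distanceBins, function(g)
        list(p = pValue(g), method = g@method))) else NULL)
  sumPath <- file.path(config$outputDir, "summary.json")
  jsonlite::write_json(summary, sumPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sumPath)

  manifest <- list(
    seed = config$seed, configHash = .configHash(config),
    packageVersion = as.character(utils::packageVersion("msiSpatial")),
    threshold = threshold,
    warnings = list(
      normalizationDropped = sum(vapply(results, `[[`, numeric(1),
                                        "normalizationDropped")),
      pixelsOutsideBorder = sum(vapply(results, function(r)
        r$distanceProfile@nOutside, integer(1)))),
    cohort = cohort$manifest,
    files = data.frame(path = sub(paste0("^", config$outputDir, "/?"), "",
                                  files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  manPath <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(results = results, comparisons = comparisons,
                 threshold = threshold, manifest = manifest,
                 outputDir = config$outputDir))
}

#' Render per-section maps as PNG images
#'
#' Writes three rasters for one analyzed section: the above-threshold
#' intensity map, the 2nd/4th-quartile overlay (grey/orange on a white
#' background) and the tissue mask with the border rings drawn on top.
#'
#' @param sectionResult one element of \code{runFullPipeline()$results} (or
#'   the output of \code{\link{analyzeSection}}).
#' @param dir output directory.
#' @return Character vector of the three file paths written.
#' @export
renderMaps <- function(sectionResult, dir) {
  r <- sectionResult
  need <- c("aboveThreshold", "quartileMap", "mask", "border")
  for (nm in need)
    if (is.null(r[[nm]])) stop("missing stage output: ", nm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%s.png", r$sectionId,
                                  c("intensity", "quartiles", "border")))
  drawRaster <- function(m, col, breaks = NULL) {
    graphics::par(mar = c(0, 0, 0, 0))
    z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
    if (all(is.na(z))) {
      graphics::plot.new()  # empty map: render a blank panel
    } else if (is.null(breaks)) {
      graphics::image(z, col = col, axes = FALSE, useRaster = TRUE)
    } else {
      graphics::image(z, col = col, breaks = breaks, axes = FALSE,
                      useRaster = TRUE)
    }
  }
  grDevices::png(paths[1L], width = 500, height = 240)
  drawRaster(intensityValues(r$aboveThreshold),
             grDevices::hcl.colors(64, "viridis"))
  grDevices::dev.off()

  grDevices::png(paths[2L], width = 500, height = 240)
  lab <- quartileLabels(r$quartileMap)
  sel <- matrix(NA_real_, nrow(lab), ncol(lab))
  sel[!is.na(lab) & lab == 2L] <- 1
  sel[!is.na(lab) & lab == 4L] <- 2
  graphics::par(mar = c(0, 0, 0, 0), bg = "white")
  if (all(is.na(sel))) graphics::plot.new() else
    graphics::image(t(sel)[, rev(seq_len(nrow(sel))), drop = FALSE],
                    col = c("grey60", "orange"), breaks = c(0.5, 1.5, 2.5),
                    axes = FALSE, useRaster = TRUE)
  grDevices::dev.off()

  grDevices::png(paths[3L], width = 500, height = 240)
  m <- maskMatrix(r$mask)
  pitch <- pixelPitch(r$mask) / 1000
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(0, ncol(m) * pitch),
                 ylim = c(nrow(m) * pitch, 0), asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  pts <- .pixelCentersMm(.maskCoords(m), pixelPitch(r$mask))
  graphics::points(pts, pch = 15, cex = 0.3, col = "grey80")
  for (ring in borderRings(r$border))
    graphics::polygon(ring, border = "red3", lwd = 2)
  grDevices::dev.off()
  paths
}
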