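# End-to-end orchestration: segment -> mesh -> material map -> solve ->
# summarize, with a serializable configuration and provenance-stamped
# reports.

#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline parameter with its default:
#' calibration curve and density-modulus law constants, the segmentation
#' threshold (HU 1500) and minimum lysis size, mesh edges, load case,
#' strip width, tuning grids, and the material factors to apply
#' (`tuned = FALSE` runs the non-tuned model with both factors zero).
#'
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return Named list; serializable losslessly via
#'   [writePipelineConfig()] / [readPipelineConfig()].
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    calibration = list(slope = 1.0123, intercept = 93.0710),
    density_modulus = list(coefficient = 3378, exponent = 1.52,
                           ash_slope = 0.8772, ash_intercept = 0.07895,
                           density_floor = 0.01),
    ascl_law = list(slope = 994.23, intercept = -184.55,
                    clamp_lo = -1, clamp_hi = 0.5),
    segmentation = list(threshold_hu = 1500, min_lysis_voxels = 8,
                        distal_length_mm = 63.5),
    mesh = list(fine_edge_mm = 0.5, coarse_edge_mm = 1),
    load = list(total_force_n = 7500, angle_frontal_deg = 60,
                angle_transverse_deg = 30, distribution = "uniform-nodal"),
    strip_width_mm = 3,
    poisson_ratio = 0.3,
    tuning = list(ascl_grid = seq(-1, 0.5, by = 0.05),
                  dlys_grid = seq(0.5, 0.95, by = 0.05),
                  pooled_dlys = 0.65),
    tuned = FALSE,
    seed = seed)
}

#' @rdname defaultPipelineConfig
#' @param config A pipeline configuration list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  utils::modifyList(def, cfg)
}

.configObjects <- function(config) {
  dm <- config$density_modulus
  list(
    curve = new("CalibrationCurve", slope = config$calibration$slope,
                intercept = config$calibration$intercept,
                plugDensities = numeric(), plugHU = numeric()),
    law = new("DensityModulusLaw", coefficient = dm$coefficient,
              exponent = dm$exponent, ashSlope = dm$ash_slope,
              ashIntercept = dm$ash_intercept,
              densityFloor = dm$density_floor),
    asclLaw = new("AsclLaw", slope = config$ascl_law$slope,
                  intercept = config$ascl_law$intercept,
                  clampLo = config$ascl_law$clamp_lo,
                  clampHi = config$ascl_law$clamp_hi),
    load = loadCase(config$load$total_force_n,
                    config$load$angle_frontal_deg,
                    config$load$angle_transverse_deg,
                    config$load$distribution))
}

.configHash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

.stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for specimen '", id, "': ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full virtual mechanical testing pipeline on one specimen
#'
#' Executes segment (HU-threshold region labelling), mesh, material map,
#' linear elastic solve, and PSG strain summary, returning all
#' intermediate products plus a provenance-stamped report. Deterministic
#' for a given (specimen, config).
#'
#' @param specimen Specimen bundle: a list with `image`
#'   ([VoxelImage-class]), masks (`boneMask`, `trabecularMask`,
#'   `psgRegionMask`, optionally `condyleMask`), `frame`
#'   ([AnatomicalFrame-class]), `psgPlane`, `loadPatchSpec`, and
#'   optionally `id`. A phantom from [makeCondylePhantom()] qualifies.
#' @param config Configuration list from [defaultPipelineConfig()].
#' @param outputDir Optional directory; when given, the label volume
#'   (NIfTI), mesh + field (VTK) and the JSON report are written there.
#' @return List with `labels`, `mesh`, `factors`, `field`, `summary`,
#'   and `report` (the serializable report list).
#' @export
runPipeline <- function(specimen, config = defaultPipelineConfig(),
                        outputDir = NULL) {
  id <- if (!is.null(specimen$id)) specimen$id else "specimen"
  obj <- .configObjects(config)

  labels <- .stage("segment", id,
    labelRegions(specimen$image, specimen$boneMask, specimen$trabecularMask,
                 specimen$psgRegionMask,
                 thresholdHu = config$segmentation$threshold_hu,
                 minLysisVoxels = config$segmentation$min_lysis_voxels))
  mesh <- .stage("mesh", id, {
    m <- voxelsToTets(labels, specimen$image, obj$curve, obj$law,
                      fineEdgeMm = config$mesh$fine_edge_mm,
                      coarseEdgeMm = config$mesh$coarse_edge_mm)
    tagBoundarySets(m, specimen$frame, specimen$psgPlane,
                    config$strip_width_mm, specimen$loadPatchSpec)
  })
  factors <- .stage("material-map", id, {
    if (isTRUE(config$tuned)) {
      if (is.null(specimen$condyleMask))
        .stopInvalid("tuned model needs a condyle mask for V_SCL")
      vScl <- scleroticVolumeFraction(labels, specimen$condyleMask)
      hasLys <- any(labelArray(labels) == labelCodes()[["LYS"]])
      regionFactors(asclFromVscl(vScl, obj$asclLaw),
                    if (hasLys) config$tuning$pooled_dlys else 0)
    } else regionFactors(0, 0)
  })
  field <- .stage("solve", id,
    assembleAndSolve(mesh, law = obj$law, factors = factors,
                     nu = config$poisson_ratio, load = obj$load,
                     frame = specimen$frame))
  summ <- .stage("summarize", id, psgSummary(field, mesh))

  report <- list(
    specimen = id,
    psg_mean_max_principal_strain = psgMean(summ),
    psg_mean_percent = 100 * psgMean(summ),
    psg_strip_facets = summ@facetCount,
    psg_strip_area_mm2 = summ@areaMm2,
    n_nodes = nrow(meshNodes(mesh)),
    n_elements = nrow(meshTets(mesh)),
    factors = list(a_scl = factors@aScl, d_lys = factors@dLys),
    provenance = list(package = "condyleFE",
                      version = as.character(utils::packageVersion("condyleFE")),
                      config_hash = .configHash(config),
                      seed = config$seed))

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(labels, file.path(outputDir, paste0(id, "-labels.nii.gz")))
    writeMeshVTK(mesh, file.path(outputDir, paste0(id, "-mesh.vtk")),
                 obj$law, factors, field)
    writeReportJson(report, file.path(outputDir, paste0(id, "-report.json")))
  }
  list(labels = labels, mesh = mesh, factors = factors, field = field,
       summary = summ, report = report)
}
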