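# Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for condyleFE classes
#' @description Small accessor generics so user code never touches slots
#'   directly.
#' @param x An object.
#' @param name Set name, for `nodeSet()` / `facetSet()`.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("imageSpacing", function(x) standardGeneric("imageSpacing"))
#' @rdname accessors
#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setGeneric("meshTets", function(x) standardGeneric("meshTets"))
#' @rdname accessors
#' @export
setGeneric("meshBoundary", function(x) standardGeneric("meshBoundary"))
#' @rdname accessors
#' @export
setGeneric("elementRegion", function(x) standardGeneric("elementRegion"))
#' @rdname accessors
#' @export
setGeneric("elementRhoAsh", function(x) standardGeneric("elementRhoAsh"))
#' @rdname accessors
#' @export
setGeneric("nodeSet", function(x, name) standardGeneric("nodeSet"))
#' @rdname accessors
#' @export
setGeneric("facetSet", function(x, name) standardGeneric("facetSet"))
#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @rdname accessors
#' @export
setGeneric("principalStrains", function(x) standardGeneric("principalStrains"))
#' @rdname accessors
#' @export
setGeneric("psgMean", function(x) standardGeneric("psgMean"))
#' @rdname accessors
#' @export
setGeneric("optimum", function(x) standardGeneric("optimum"))

setMethod("imageValues", "VoxelImage", function(x) x@values)
setMethod("imageSpacing", "VoxelImage", function(x) x@spacing)
setMethod("imageOrigin", "VoxelImage", function(x) x@origin)
setMethod("imageSpacing", "LabelVolume", function(x) x@spacing)
setMethod("imageOrigin", "LabelVolume", function(x) x@origin)
setMethod("labelArray", "LabelVolume", function(x) x@labels)
setMethod("meshNodes", "TetrahedralMesh", function(x) x@nodes)
setMethod("meshTets", "TetrahedralMesh", function(x) x@tets)
setMethod("meshBoundary", "TetrahedralMesh", function(x) x@boundary)
setMethod("elementRegion", "TetrahedralMesh", function(x) x@elementRegion)
setMethod("elementRhoAsh", "TetrahedralMesh", function(x) x@elementRhoAsh)
setMethod("nodeSet", "TetrahedralMesh", function(x, name) {
  if (!name %in% names(x@nodeSets))
    .stopInvalid("unknown node set '", name, "'")
  x@nodeSets[[name]]
})
setMethod("facetSet", "TetrahedralMesh", function(x, name) {
  if (!name %in% names(x@facetSets))
    .stopInvalid("unknown facet set '", name, "'")
  x@facetSets[[name]]
})
setMethod("displacements", "StrainField", function(x) x@displacements)
setMethod("principalStrains", "StrainField", function(x) x@elementPrincipal)
setMethod("psgMean", "PSGStrainSummary", function(x) x@meanMaxPrincipal)
setMethod("optimum", "TuningGrid", function(x) x@optimum)

# ---- show methods ------------------------------------------------------------

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: HU =", format(object@slope), "* rhoCT +",
      format(object@intercept), "\n")
  if (length(object@plugDensities))
    cat("  plugs (mgHA/cm^3):", paste(object@plugDensities, collapse = ", "),
        "\n")
})

setMethod("show", "DensityModulusLaw", function(object) {
  cat("DensityModulusLaw: E =", format(object@coefficient), "* rho_ash^",
      format(object@exponent), "MPa;",
      "rho_ash =", format(object@ashSlope), "* rho_ct +",
      format(object@ashIntercept), "g/cm^3\n")
})

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@values)
  cat("VoxelImage:", paste(d, collapse = " x "), "voxels, spacing",
      paste(format(object@spacing), collapse = " x "), "mm\n")
  cat("  HU range:", paste(format(range(object@values)), collapse = " .. "),
      "\n")
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat("LabelVolume:", paste(d, collapse = " x "), "voxels\n")
  tab <- table(factor(object@labels, levels = labelCodes(),
                      labels = names(labelCodes())))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat("  ", nm, ": ", tab[[nm]], " voxels\n", sep = "")
})

setMethod("show", "TetrahedralMesh", function(object) {
  cat("TetrahedralMesh:", nrow(object@nodes), "nodes,",
      nrow(object@tets), "tets,", nrow(object@boundary$facets),
      "boundary facets\n")
  cat("  edges (fine/coarse):", object@fineEdge, "/", object@coarseEdge,
      "mm;  regions:",
      paste(names(table(object@elementRegion)), table(object@elementRegion),
            collapse = ", "), "\n")
  cat("  sets:", paste(c(names(object@nodeSets), names(object@facetSets)),
                       collapse = ", "), "\n")
})

setMethod("show", "StrainField", function(object) {
  cat("StrainField:", nrow(object@displacements), "nodes,",
      nrow(object@elementStrain), "elements\n")
  cat("  max |displacement|:",
      format(max(abs(object@displacements))), "mm\n")
  cat("  max principal strain range:",
      paste(format(range(object@elementPrincipal[, 1])), collapse = " .. "),
      "\n")
})

setMethod("show", "PSGStrainSummary", function(object) {
  cat("PSGStrainSummary: mean max principal strain =",
      format(object@meanMaxPrincipal),
      sprintf("(%.3f%%)", 100 * object@meanMaxPrincipal), "over",
      object@facetCount, "facets,", format(object@areaMm2), "mm^2\n")
})

setMethod("show", "TuningGrid", function(object) {
  cat("TuningGrid (", object@factorName, "): ", length(object@candidates),
      " candidates in [", min(object@candidates), ", ",
      max(object@candidates), "]\n", sep = "")
  cat("  optimum:", object@optimum, " objective:",
      format(min(object@objective)), "\n")
  if (length(object@tieRule) && nzchar(object@tieRule))
    cat("  tie-break:", object@tieRule, "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", nrow(object@table), "specimens\n")
  print(object@table, row.names = FALSE)
  if (is.finite(object@slope))
    cat("  slope:", format(object@slope), " intercept:",
        format(object@intercept), " R^2:", format(object@rSquared), "\n")
  cat("  mean relative error:",
      sprintf("%.2f%%", 100 * object@meanRelativeError), "\n")
})
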