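# Standard-format I/O: NIfTI volumes, VTK and Abaqus-INP mesh exports,
# JSON reports.

#' Write a volume to NIfTI
#'
#' @param x A [VoxelImage-class] or [LabelVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  vals <- if (is(x, "VoxelImage")) x@values else x@labels
  img <- RNifti::asNifti(vals,
                         reference = list(pixdim = c(1, x@spacing, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param what `"image"` for a [VoxelImage-class], `"labels"` for a
#'   [LabelVolume-class].
#' @return The requested object. The origin is taken as zero; world
#'   coordinates inside this package are voxel-grid coordinates scaled
#'   by the spacing.
#' @export
readVolume <- function(path, what = c("image", "labels")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim(img))
  if (what == "image")
    new("VoxelImage", values = vals, spacing = sp, origin = c(0, 0, 0))
  else {
    storage.mode(vals) <- "integer"
    new("LabelVolume", labels = vals, spacing = sp, origin = c(0, 0, 0))
  }
}

#' Export a mesh as a legacy-ASCII VTK unstructured grid
#'
#' Writes the tet mesh with per-element region code, ash density and
#' Young's modulus as cell data, and optionally per-element principal
#' strain and per-node displacements from a solved field.
#'
#' @param mesh A [TetrahedralMesh-class].
#' @param path Output `.vtk` path.
#' @param law [DensityModulusLaw-class] for the modulus cell data.
#' @param factors [RegionFactors-class] for the modulus cell data.
#' @param field Optional [StrainField-class].
#' @return `path`, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, law = defaultDensityModulusLaw(),
                         factors = regionFactors(), field = NULL) {
  n <- nrow(mesh@nodes); m <- nrow(mesh@tets)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("condyleFE tetrahedral mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(apply(format(mesh@nodes, trim = TRUE), 1, paste,
                   collapse = " "), con)
  wl("CELLS ", m, " ", 5 * m)
  writeLines(paste(4, mesh@tets[, 1] - 1, mesh@tets[, 2] - 1,
                   mesh@tets[, 3] - 1, mesh@tets[, 4] - 1), con)
  wl("CELL_TYPES ", m)
  writeLines(rep("10", m), con)
  wl("CELL_DATA ", m)
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  regionCode <- c(plain = 0L, sclerotic = 1L, lytic = 2L)
  writeLines(as.character(regionCode[mesh@elementRegion]), con)
  wl("SCALARS rho_ash double 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(mesh@elementRhoAsh, trim = TRUE), con)
  wl("SCALARS youngs_modulus double 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(elementModuli(mesh, law, factors), trim = TRUE), con)
  if (!is.null(field)) {
    wl("SCALARS max_principal_strain double 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(field@elementPrincipal[, 1], trim = TRUE), con)
    wl("POINT_DATA ", n)
    wl("VECTORS displacement double")
    writeLines(apply(format(field@displacements, trim = TRUE), 1, paste,
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export a mesh in a minimal Abaqus-INP dialect
#'
#' Nodes, C3D4 elements, element sets per region and the named node set
#' of the fixed proximal end, for interoperability with external FE
#' tools.
#'
#' @param mesh A [TetrahedralMesh-class].
#' @param path Output `.inp` path.
#' @return `path`, invisibly.
#' @export
writeMeshInp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("*NODE")
  writeLines(paste(seq_len(nrow(mesh@nodes)),
                   format(mesh@nodes[, 1], trim = TRUE),
                   format(mesh@nodes[, 2], trim = TRUE),
                   format(mesh@nodes[, 3], trim = TRUE), sep = ", "), con)
  wl("*ELEMENT, TYPE=C3D4")
  writeLines(paste(seq_len(nrow(mesh@tets)), mesh@tets[, 1], mesh@tets[, 2],
                   mesh@tets[, 3], mesh@tets[, 4], sep = ", "), con)
  for (rg in unique(mesh@elementRegion)) {
    wl("*ELSET, ELSET=", toupper(rg))
    idx <- which(mesh@elementRegion == rg)
    writeLines(vapply(split(idx, ceiling(seq_along(idx) / 10)),
                      paste, character(1), collapse = ", "), con)
  }
  if ("PROXIMAL_FIXED" %in% names(mesh@nodeSets)) {
    wl("*NSET, NSET=PROXIMAL_FIXED")
    idx <- mesh@nodeSets$PROXIMAL_FIXED
    writeLines(vapply(split(idx, ceiling(seq_along(idx) / 10)),
                      paste, character(1), collapse = ", "), con)
  }
  invisible(path)
}

#' Write a report object as JSON
#'
#' @param x A list (report contents).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
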