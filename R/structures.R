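# StructureSet: labelled voxel masks on a common lattice.

#' Create a structure set
#'
#' Bundles binary voxel masks for the HR-CTV and the organs at risk on a
#' single lattice with physical voxel spacing.  All masks must share one grid
#' shape; the HR-CTV mask must be non-empty and strictly disjoint from every
#' organ-at-risk mask (the ring expansion is defined outside the target, so
#' an overlap is a contouring error, not something to clip silently).
#'
#' @param masks Named list of 3-D logical arrays.  Must contain an element
#'   named `"hrctv"`; any other elements are organs at risk.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin Numeric length-3, physical coordinate (mm) of voxel
#'   `[1, 1, 1]`.  Voxel `[i, j, k]` sits at `origin + (i-1, j-1, k-1) * spacing`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0)) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("'masks' must be a named list of logical arrays")
  if (!HRCTV %in% names(masks))
    stop("structure set must contain an '", HRCTV, "' mask")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  shape <- dim(masks[[1L]])
  if (length(shape) != 3L) stop("masks must be 3-D arrays")
  masks <- lapply(masks, function(m) {
    if (!identical(dim(m), shape))
      stop("all masks must share one grid shape")
    storage.mode(m) <- "logical"
    m
  })
  if (!any(masks[[HRCTV]])) stop("empty structure: ", HRCTV)
  hr <- masks[[HRCTV]]
  for (nm in setdiff(names(masks), HRCTV)) {
    if (any(masks[[nm]] & hr))
      stop("structure '", nm, "' overlaps the HR-CTV; masks must be disjoint")
  }
  structure(
    list(masks = masks, spacing = spacing, origin = origin, shape = shape),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> grid", paste(x$shape, collapse = "x"),
      "spacing", paste(format(x$spacing), collapse = "x"), "mm\n")
  vv <- voxel_volume_cm3(x$spacing)
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %8.2f cm3\n", nm, sum(x$masks[[nm]]) * vv))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' @param spacing Voxel spacing in mm (length 3).
#' @return Volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(spacing) prod(spacing) / 1000

#' Structure volume in cubic centimetres
#'
#' @param structures A [structure_set].
#' @param name Structure name.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
structure_volume_cm3 <- function(structures, name) {
  m <- get_mask(structures, name)
  sum(m) * voxel_volume_cm3(structures$spacing)
}

get_mask <- function(structures, name) {
  stopifnot(inherits(structures, "structure_set"))
  if (!name %in% names(structures$masks))
    stop("unknown structure: '", name, "'")
  structures$masks[[name]]
}

#' Write a structure set as a NIfTI label volume
#'
#' Encodes the masks as one integer label image (labels are powers of two so
#' overlapping organs-at-risk remain representable) plus a JSON file mapping
#' structure name to label bit.
#'
#' @param structures A [structure_set].
#' @param nifti_path Output path for the `.nii`/`.nii.gz` volume.
#' @param labels_path Output path for the JSON name-to-label map; defaults to
#'   `nifti_path` with a `.labels.json` suffix.
#' @return Invisibly, the two paths written.
#' @export
write_structures <- function(structures, nifti_path,
                             labels_path = paste0(nifti_path, ".labels.json")) {
  nms <- names(structures$masks)
  bits <- stats::setNames(2L^(seq_along(nms) - 1L), nms)
  lab <- array(0L, dim = structures$shape)
  for (nm in nms) lab <- lab + bits[[nm]] * structures$masks[[nm]]
  img <- RNifti::asNifti(lab, reference = NULL)
  RNifti::pixdim(img) <- structures$spacing
  RNifti::writeNifti(img, nifti_path)
  jsonlite::write_json(
    list(labels = as.list(bits), spacing = structures$spacing,
         origin = structures$origin),
    labels_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(nifti = nifti_path, labels = labels_path))
}

#' Read a structure set written by [write_structures()]
#'
#' @param nifti_path Path to the NIfTI label volume.
#' @param labels_path Path to the JSON label map.
#' @return A [structure_set].
#' @export
read_structures <- function(nifti_path,
                            labels_path = paste0(nifti_path, ".labels.json")) {
  lab <- as.array(RNifti::readNifti(nifti_path))
  meta <- jsonlite::read_json(labels_path, simplifyVector = TRUE)
  masks <- lapply(meta$labels, function(bit) {
    array(bitwAnd(as.integer(lab), as.integer(bit)) > 0L, dim = dim(lab))
  })
  structure_set(masks, spacing = meta$spacing, origin = meta$origin)
}

#' Physical voxel-center coordinates of a lattice
#'
#' @param shape Integer length-3 grid shape.
#' @param spacing Voxel spacing (mm).
#' @param origin Physical coordinate of voxel `[1, 1, 1]` (mm).
#' @return List of three arrays (`x`, `y`, `z`), each of dimension `shape`,
#'   giving the physical coordinate of every voxel center.
#' @keywords internal
lattice_coords <- function(shape, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}
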