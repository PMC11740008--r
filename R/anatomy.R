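#' Define a regular voxel grid
#'
#' The grid carries the image geometry shared by every mask of a structure
#' set: array shape, physical spacing and the mm coordinate of the first voxel
#' center. The patient frame is fixed: +x patient-left, +y posterior,
#' +z superior.
#'
#' @param shape integer triple, voxels per axis (each >= 1).
#' @param spacing mm triple, voxel spacing per axis (each > 0).
#' @param origin mm triple, coordinate of voxel (1,1,1)'s center. Defaults to
#'   centering the grid on (0,0,0).
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(shape, spacing, origin = -(shape - 1) * spacing / 2) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("grid shape must be an integer triple with components >= 1")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be a positive mm triple")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("grid origin must be a finite mm triple")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grid_axis <- function(grid, k) {
  grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k]
}

#' Voxel volume of a grid in cc
#' @param grid a [voxel_grid()].
#' @return voxel volume in cm^3.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

#' A named binary structure on a voxel grid
#'
#' @param name structure label, e.g. `"CTV"`.
#' @param mask logical 3D array conforming to `grid$shape`.
#' @param grid a [voxel_grid()].
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(name, mask, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), grid$shape)) {
    stop(sprintf("mask for '%s' does not conform to grid shape", name))
  }
  structure(list(name = name, mask = mask, grid = grid),
            class = "structure_mask")
}

#' The anatomical state of one image: grid plus named structure masks
#'
#' The planning-set structure names required by the pipeline are CTV,
#' BladderNeck, Bladder, Rectum, FemHeadL, FemHeadR and Body (GTV and Urethra
#' are optional, needed only for boosted 2SMART planning/evaluation).
#'
#' @param grid a [voxel_grid()].
#' @param structures named list of logical arrays (or `structure_mask`es),
#'   all on `grid`.
#' @param image_label image identity, e.g. `"pCT"`, `"CB1"`, `"CB2"`.
#' @return A `structure_set`.
#' @export
structure_set <- function(grid, structures, image_label = "pCT") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(names(structures)) || any(names(structures) == "")) {
    stop("structures must be a named list")
  }
  structures <- lapply(structures, function(s) {
    m <- if (inherits(s, "structure_mask")) s$mask else s
    if (!is.logical(m)) storage.mode(m) <- "logical"
    if (!identical(dim(m), grid$shape)) stop("all masks must share the grid shape")
    m
  })
  structure(list(grid = grid, structures = structures, image_label = image_label),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set '%s': %s\n", x$image_label,
              paste(names(x$structures), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

REQUIRED_PLANNING_STRUCTURES <- c("CTV", "BladderNeck", "Bladder", "Rectum",
                                  "FemHeadL", "FemHeadR", "Body")

#' Retrieve one structure from a set
#' @param ss a [structure_set()].
#' @param name structure name.
#' @return A [structure_mask()].
#' @export
get_structure <- function(ss, name) {
  m <- ss$structures[[name]]
  if (is.null(m)) stop(sprintf("missing structure '%s' in image '%s'", name, ss$image_label))
  structure_mask(name, m, ss$grid)
}

#' Center of mass of a binary structure
#'
#' Unweighted mean of occupied voxel-center coordinates in mm (contours, not
#' image intensities, are the input, so no intensity weighting applies).
#'
#' @param structure a [structure_mask()].
#' @return named mm triple `c(x, y, z)`.
#' @export
center_of_mass <- function(structure) {
  idx <- which(structure$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure")
  g <- structure$grid
  setNames(g$origin + (colMeans(idx) - 1) * g$spacing, c("x", "y", "z"))
}

#' Euclidean distance between two mm points
#' @param a,b mm triples.
#' @return distance in mm.
#' @export
com_distance <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

fem_bounding_box <- function(ss) {
  for (nm in c("FemHeadL", "FemHeadR")) {
    if (is.null(ss$structures[[nm]]) || !any(ss$structures[[nm]])) {
      stop(sprintf("missing or empty femoral structure '%s'", nm))
    }
  }
  idx <- which(ss$structures[["FemHeadL"]] | ss$structures[["FemHeadR"]], arr.ind = TRUE)
  g <- ss$grid
  lo <- g$origin + (apply(idx, 2, min) - 1) * g$spacing - g$spacing / 2
  hi <- g$origin + (apply(idx, 2, max) - 1) * g$spacing + g$spacing / 2
  list(lo = setNames(lo, c("x", "y", "z")), hi = setNames(hi, c("x", "y", "z")))
}

#' Femoral reference vertices
#'
#' One axis-aligned bounding box (voxel outer edges, mm) encloses the union of
#' both femoral-head masks. The left reference point FemL is the vertex that
#' is patient-left, posterior and inferior: `(x_max, y_max, z_min)`. The right
#' reference point FemR is the vertex patient-right, posterior and superior:
#' `(x_min, y_max, z_max)`. The inferior/superior asymmetry between the two
#' sides is a deliberate, documented convention of the reference-point
#' definition (see the methods vignette).
#'
#' @param ss a [structure_set()] with non-empty FemHeadL and FemHeadR.
#' @return list with mm points `FemL` and `FemR`.
#' @export
femoral_reference_points <- function(ss) {
  bb <- fem_bounding_box(ss)
  list(FemL = c(x = bb$hi[["x"]], y = bb$hi[["y"]], z = bb$lo[["z"]]),
       FemR = c(x = bb$lo[["x"]], y = bb$hi[["y"]], z = bb$hi[["z"]]))
}

fem_box_center <- function(ss) {
  bb <- fem_bounding_box(ss)
  (bb$lo + bb$hi) / 2
}

#' Select the two anatomies with the largest CTV COM separation
#'
#' Emulates condensing a multi-fraction image history into a two-fraction
#' course by picking the pair of images whose CTV centers of mass are farthest
#' apart. Ties are broken by the lowest index pair (lexicographic i < j).
#'
#' @param fraction_sets list of at least two [structure_set()]s, each with CTV.
#' @return integer pair `c(i, j)` (1-based, i < j).
#' @export
select_max_separation_pair <- function(fraction_sets) {
  n <- length(fraction_sets)
  if (n < 2L) stop("need at least two structure sets")
  coms <- t(vapply(fraction_sets,
                   function(ss) center_of_mass(get_structure(ss, "CTV")),
                   numeric(3)))
  best <- c(1L, 2L)
  best_d <- -1
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(sum((coms[i, ] - coms[j, ])^2))
      if (d > best_d + 1e-12) {
        best_d <- d
        best <- c(i, j)
      }
    }
  }
  setNames(best, c("i", "j"))
}

#' Anisotropic, direction-resolved mask expansion
#'
#' Expands a binary structure by per-direction mm margins in the fixed patient
#' frame. A voxel center enters the expansion iff it lies within the
#' direction-scaled ellipsoidal reach of some occupied voxel center, so the
#' posterior face of a target can legitimately grow less than the others
#' (e.g. 5 mm everywhere, 3 mm posteriorly). Zero margins return the identical
#' mask; the output always contains the input.
#'
#' @param structure a [structure_mask()].
#' @param margins a [margin_set()] (all components >= 0).
#' @return the expanded [structure_mask()].
#' @export
expand_mask <- function(structure, margins) {
  margins <- as_margin_set(margins, allow_zero = TRUE)
  g <- structure$grid
  out <- .dilate_margins_cpp(as.logical(structure$mask), g$shape, g$spacing,
                             as.numeric(margins))
  dim(out) <- g$shape
  structure_mask(structure$name, out, g)
}

#' Euclidean distance map from a mask (mm)
#'
#' Exact distance from every voxel center to the nearest occupied voxel center
#' (0 inside the mask, `Inf` if the mask is empty). Used by the surrogate dose
#' engine and the dose-falloff metric.
#'
#' @param structure a [structure_mask()].
#' @return numeric 3D array of mm distances.
#' @export
distance_map_mm <- function(structure) {
  g <- structure$grid
  d <- .edt_mm_cpp(as.logical(structure$mask), g$shape, g$spacing)
  d[d > 1e7] <- Inf
  dim(d) <- g$shape
  d
}

# Shift a 3D array by whole voxels; exposed voxels take `fill`.
shift_array <- function(a, shift_vox, fill = FALSE) {
  d <- dim(a)
  s <- as.integer(round(shift_vox))
  if (all(s == 0L)) return(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (abs(s[k]) >= d[k]) return(out)
    if (s[k] >= 0L) {
      dst[[k]] <- seq.int(s[k] + 1L, d[k])
      src[[k]] <- seq.int(1L, d[k] - s[k])
    } else {
      dst[[k]] <- seq.int(1L, d[k] + s[k])
      src[[k]] <- seq.int(1L - s[k], d[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

shift_structure_set <- function(ss, shift_vox, names = NULL) {
  names <- names %||% names(ss$structures)
  st <- ss$structures
  for (nm in names) st[[nm]] <- shift_array(st[[nm]], shift_vox, FALSE)
  structure_set(ss$grid, st, ss$image_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
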