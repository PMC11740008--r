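#' Geometric image features from CTV and femoral reference points
#'
#' The seven features used to predict the relative CTV position:
#' f1 = |FemL - FemR|, f2 = |CTV - FemL|, f3 = |CTV - FemR| (mm),
#' f4 = angle in degrees between the vectors (FemL - CTV) and (FemR - CTV),
#' and f5..f7 = signed per-axis components of (CTV - FemR) in the
#' left-right, anterior-posterior and superior-inferior directions. All seven
#' are invariant under rigid translation of the whole structure set.
#'
#' @param ctv CTV center of mass (mm triple).
#' @param femL,femR femoral reference vertices (mm triples), see
#'   [femoral_reference_points()].
#' @return named numeric vector `f1..f7`.
#' @export
features_from_points <- function(ctv, femL, femR) {
  ctv <- as.numeric(ctv); femL <- as.numeric(femL); femR <- as.numeric(femR)
  f1 <- sqrt(sum((femL - femR)^2))
  f2 <- sqrt(sum((ctv - femL)^2))
  f3 <- sqrt(sum((ctv - femR)^2))
  if (f2 < 1e-9 || f3 < 1e-9) stop("degenerate geometry: CTV coincides with a femoral reference point")
  cosang <- sum((femL - ctv) * (femR - ctv)) / (f2 * f3)
  cosang <- min(1, max(-1, cosang))        # numerical safety before acos
  f4 <- acos(cosang) * 180 / pi
  d <- ctv - femR
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = d[1], f6 = d[2], f7 = d[3])
}

#' Extract the seven geometric features from a structure set
#'
#' @param ss a [structure_set()] with non-empty CTV, FemHeadL and FemHeadR.
#' @return named numeric vector `f1..f7` (mm; f4 in degrees).
#' @export
extract_features <- function(ss) {
  com <- center_of_mass(get_structure(ss, "CTV"))
  ref <- femoral_reference_points(ss)
  features_from_points(com, ref$FemL, ref$FemR)
}

#' Relative CTV position: CTV center of mass minus FemL
#'
#' The regression target of the margin model: per-axis mm offsets of the CTV
#' center of mass from the left femoral reference vertex, in the left-right,
#' anterior-posterior and superior-inferior directions.
#'
#' @param ss a [structure_set()].
#' @return named mm triple `c(dx, dy, dz)`.
#' @export
relative_ctv_position <- function(ss) {
  com <- center_of_mass(get_structure(ss, "CTV"))
  ref <- femoral_reference_points(ss)
  setNames(as.numeric(com) - as.numeric(ref$FemL), c("dx", "dy", "dz"))
}
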