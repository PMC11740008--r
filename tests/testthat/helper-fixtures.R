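# Small programmatic fixtures shared across test files.

# grid centered on the origin unless stated otherwise
tiny_grid <- function(shape = c(20L, 20L, 20L), spacing = c(1, 1, 1),
                      origin = NULL) {
  if (is.null(origin)) voxel_grid(shape, spacing)
  else voxel_grid(shape, spacing, origin)
}

mask_from_indices <- function(grid, idx) {
  m <- array(FALSE, grid$shape)
  m[idx] <- TRUE
  m
}

ball_mask <- function(grid, center, radius) {
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  u <- (xs - center[1])^2
  v <- (ys - center[2])^2
  w <- (zs - center[3])^2
  outer(outer(u, v, "+"), w, "+") <= radius^2
}

box_mask <- function(grid, lo, hi) {
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  outer(outer(xs >= lo[1] & xs <= hi[1], ys >= lo[2] & ys <= hi[2], "&"),
        zs >= lo[3] & zs <= hi[3], "&")
}

# Single-voxel femoral masks placed so the union bounding box (voxel outer
# edges) has the requested extents; spacing must be 1 and extents must land on
# voxel edges of the grid.
femoral_pair_for_box <- function(grid, xlim, ylim, zlim) {
  vox_center <- function(p) p  # voxel centers at integer+0.5 handled by caller
  femR <- ball_mask(grid, c(xlim[1] + 0.5, ylim[2] - 0.5, zlim[2] - 0.5), 0.1)
  femL <- ball_mask(grid, c(xlim[2] - 0.5, ylim[2] - 0.5, zlim[1] + 0.5), 0.1)
  list(FemHeadL = femL, FemHeadR = femR)
}

# A minimal complete planning structure set on a small grid: CTV ball in the
# middle, femoral balls laterally, bladder neck cap on top of the CTV,
# bladder above, rectum tube behind, body covering everything.
mini_patient_ss <- function(shape = c(40L, 36L, 36L), spacing = c(2, 2, 2),
                            ctv_center = c(0, 0, 0), ctv_r = 8,
                            label = "pCT") {
  g <- voxel_grid(shape, spacing)
  ctv <- ball_mask(g, ctv_center, ctv_r)
  bn <- ball_mask(g, ctv_center + c(0, 0, ctv_r + 2), 5) & !ctv
  bladder <- ball_mask(g, ctv_center + c(0, -4, ctv_r + 14), 12) & !bn & !ctv
  rectum <- box_mask(g, ctv_center + c(-8, ctv_r + 6, -20),
                     ctv_center + c(8, ctv_r + 16, 20))
  femL <- ball_mask(g, c(30, 0, 0), 6)
  femR <- ball_mask(g, c(-30, 0, 0), 6)
  body <- box_mask(g, -0.5 * (shape - 1) * spacing, 0.5 * (shape - 1) * spacing)
  structure_set(g, list(CTV = ctv, BladderNeck = bn, Bladder = bladder,
                        Rectum = rectum, FemHeadL = femL, FemHeadR = femR,
                        Body = body),
                image_label = label)
}

# direction-resolved brute-force expansion oracle (independent of the C++ path)
brute_expand <- function(mask, grid, margins) {
  idx_in <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, grid$shape)
  all_idx <- which(array(TRUE, grid$shape), arr.ind = TRUE)
  m <- as.numeric(margins)  # L R A P S I
  for (r in seq_len(nrow(all_idx))) {
    v <- all_idx[r, ]
    d <- sweep(idx_in, 2, v)            # u - v per axis (voxels)
    dmm <- -sweep(d, 2, grid$spacing, "*")  # v - u in mm
    reach <- function(dc, pos, neg) ifelse(dc > 0, pos, neg)
    mx <- reach(dmm[, 1], m[1], m[2])
    my <- reach(dmm[, 2], m[4], m[3])
    mz <- reach(dmm[, 3], m[5], m[6])
    term <- function(dc, mm) ifelse(dc == 0, 0, ifelse(mm <= 0, Inf, (dc / mm)^2))
    s <- term(dmm[, 1], mx) + term(dmm[, 2], my) + term(dmm[, 3], mz)
    if (any(s <= 1 + 1e-9)) out[v[1], v[2], v[3]] <- TRUE
  }
  out
}

# sorted-voxel DVH oracle used to cross-check the implementation
oracle_dvh_D <- function(doses, voxel_cc, v_cc) {
  s <- sort(doses, decreasing = TRUE)
  cum <- seq_along(s) * voxel_cc
  s[which(cum >= v_cc - 1e-9)[1]]
}

oracle_dvh_V <- function(doses, voxel_cc, threshold) {
  sum(doses >= threshold - 1e-12) * voxel_cc
}
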