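test_that("center of mass matches voxel-center averages", {
  g <- tiny_grid(c(21L, 21L, 21L))
  # cube symmetric about the origin
  cube <- box_mask(g, c(-3, -3, -3), c(3, 3, 3))
  expect_equal(unname(center_of_mass(structure_mask("c", cube, g))),
               c(0, 0, 0))
  # single voxel with anisotropic spacing
  g2 <- voxel_grid(c(32L, 32L, 32L), c(1, 1, 2), origin = c(0, 0, 0))
  m <- mask_from_indices(g2, matrix(c(11L, 21L, 31L), nrow = 1))
  expect_equal(unname(center_of_mass(structure_mask("v", m, g2))),
               c(10, 20, 60))
  # three voxels, brute-force average
  g3 <- voxel_grid(c(8L, 8L, 8L), c(1, 1, 1), origin = c(0, 0, 0))
  m3 <- mask_from_indices(g3, rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(1L, 2L, 1L)))
  expect_equal(unname(center_of_mass(structure_mask("t", m3, g3))),
               c(1 / 3, 1 / 3, 0))
  expect_error(center_of_mass(structure_mask("e", array(FALSE, g$shape), g)),
               "empty")
})

test_that("com_distance is the Euclidean norm", {
  expect_equal(com_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(com_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3, sd = 30); b <- rnorm(3, sd = 30)
    expect_equal(com_distance(a, b), sqrt(sum((a - b)^2)))
    expect_equal(com_distance(a, b), com_distance(b, a))
  }
})

test_that("femoral reference points follow the box-vertex convention", {
  g <- voxel_grid(c(220L, 120L, 100L), c(1, 1, 1),
                  origin = c(-109.5, -59.5, -9.5))
  # femoral voxels arranged so the union box spans x [-100,100], y [-50,50],
  # z [0,80] in voxel outer edges
  fem <- femoral_pair_for_box(g, c(-100, 100), c(-50, 50), c(0, 80))
  ss <- structure_set(g, fem)
  ref <- femoral_reference_points(ss)
  expect_equal(unname(ref$FemL), c(100, 50, 0))
  expect_equal(unname(ref$FemR), c(-100, 50, 80))

  # translation equivariance
  shift <- c(0L, 5L, 0L)
  ss2 <- structure_set(g, lapply(ss$structures, function(m)
    protontwin:::shift_array(m, shift)))
  ref2 <- femoral_reference_points(ss2)
  expect_equal(unname(ref2$FemL), unname(ref$FemL) + c(0, 5, 0))
  expect_equal(unname(ref2$FemR), unname(ref$FemR) + c(0, 5, 0))

  # degenerate: both femora in the same voxel -> box collapses to that voxel
  g3 <- tiny_grid(c(10L, 10L, 10L))
  one <- mask_from_indices(g3, matrix(c(5L, 5L, 5L), nrow = 1))
  ss3 <- structure_set(g3, list(FemHeadL = one, FemHeadR = one))
  ref3 <- femoral_reference_points(ss3)
  expect_equal(unname(ref3$FemL - ref3$FemR), c(1, 0, -1))  # one voxel edge

  expect_error(femoral_reference_points(
    structure_set(g3, list(FemHeadL = one,
                           FemHeadR = array(FALSE, g3$shape)))),
    "femoral")
})

test_that("expand_mask agrees with the direction-resolved brute-force oracle", {
  g <- tiny_grid(c(16L, 16L, 16L), c(1, 1, 1))
  set.seed(5)
  for (i in 1:3) {
    m <- array(FALSE, g$shape)
    m[sample(length(m), 12)] <- TRUE
    margins <- margin_set(left = runif(1, 0, 3), right = runif(1, 0, 3),
                          anterior = runif(1, 0, 3), posterior = runif(1, 0, 3),
                          superior = runif(1, 0, 3), inferior = runif(1, 0, 3))
    got <- expand_mask(structure_mask("m", m, g), margins)$mask
    want <- brute_expand(m, g, margins)
    expect_identical(got, want)
  }
})

test_that("expand_mask geometry: identity, sphere growth, asymmetric faces", {
  g <- tiny_grid(c(41L, 41L, 41L), c(1, 1, 1))
  sph <- ball_mask(g, c(0, 0, 0), 10)
  s <- structure_mask("CTV", sph, g)
  expect_identical(expand_mask(s, margin_set(0))$mask, sph)

  grown <- expand_mask(s, margin_set(5))$mask
  expect_true(all(sph[grown == FALSE] == FALSE))  # superset
  # all voxels within 15 mm included, none beyond 15 + half-voxel diagonal
  d <- sqrt(outer(outer((seq_len(41) - 21)^2, (seq_len(41) - 21)^2, "+"),
                  (seq_len(41) - 21)^2, "+"))
  expect_true(all(grown[d <= 15 - 1]))
  expect_true(all(!grown[d > 15 + 1]))

  # cube with 5 mm margins except 3 mm posterior
  cube <- box_mask(g, c(-5, -5, -5), c(5, 5, 5))
  e <- expand_mask(structure_mask("c", cube, g),
                   margin_set(left = 5, right = 5, anterior = 5, posterior = 3,
                              superior = 5, inferior = 5))$mask
  idx <- which(e, arr.ind = TRUE)
  ys <- idx[, 2] - 21  # mm (unit spacing, center voxel 21)
  xs <- idx[, 1] - 21
  zs <- idx[, 3] - 21
  expect_equal(max(ys), 8)    # posterior face: 5 + 3
  expect_equal(min(ys), -10)  # anterior face: 5 + 5
  expect_equal(range(xs), c(-10, 10))
  expect_equal(range(zs), c(-10, 10))
})

test_that("expand_mask is monotone in the margins", {
  g <- tiny_grid(c(24L, 24L, 24L), c(1.5, 1.5, 1.5))
  sph <- ball_mask(g, c(1, -2, 0), 6)
  s <- structure_mask("m", sph, g)
  set.seed(9)
  for (i in 1:5) {
    a <- runif(6, 0, 3)
    b <- a + runif(6, 0, 3)
    ea <- expand_mask(s, as.numeric(a))$mask
    eb <- expand_mask(s, as.numeric(b))$mask
    expect_true(all(eb[ea]))  # ea subset of eb
  }
})

test_that("max-separation pair matches exhaustive search with index tie-breaks", {
  g <- tiny_grid(c(30L, 10L, 10L), c(1, 1, 1), origin = c(0, 0, 0))
  make_ss <- function(x) {
    structure_set(g, list(CTV = mask_from_indices(
      g, matrix(c(as.integer(x) + 1L, 5L, 5L), nrow = 1))), sprintf("CB%d", x))
  }
  # COMs on a line at 0, 1, 2, 3, 13 mm
  sets <- lapply(c(0, 1, 2, 3, 13), make_ss)
  expect_equal(unname(select_max_separation_pair(sets)), c(1L, 5L))
  # all identical -> first pair
  same <- lapply(c(2, 2, 2), make_ss)
  expect_equal(unname(select_max_separation_pair(same)), c(1L, 2L))
  # exactly two sets
  expect_equal(unname(select_max_separation_pair(sets[1:2])), c(1L, 2L))
  expect_error(select_max_separation_pair(sets[1]), "two")

  # oracle equivalence on random configurations
  set.seed(21)
  for (rep in 1:5) {
    xs <- sample(0:25, 6)
    sets <- lapply(xs, make_ss)
    got <- select_max_separation_pair(sets)
    d <- abs(outer(xs, xs, "-"))
    expect_equal(d[got[1], got[2]], max(d))
  }
})
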