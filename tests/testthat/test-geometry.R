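test_that("cell_matrix follows the standard Cartesian convention", {
  A <- cell_matrix(cell_parameters(0.5, 0.5, 0.5))
  expect_equal(A, 0.5 * diag(3))
  expect_equal(det(A), 0.125)

  A <- cell_matrix(cell_parameters(0.3, 0.4, 0.5))
  expect_equal(A, diag(c(0.3, 0.4, 0.5)))

  # rhombohedral 60-degree cell (fcc primitive): closed-form volume
  A <- cell_matrix(cell_parameters(0.5, 0.5, 0.5, 60, 60, 60))
  vol_closed <- 0.5^3 * sqrt(1 - 3 * cos(pi / 3)^2 + 2 * cos(pi / 3)^3)
  expect_equal(det(A), vol_closed, tolerance = 1e-12)
  # triple-product oracle on the columns
  expect_equal(det(A), sum(A[, 1] * c(
    A[2, 2] * A[3, 3] - A[3, 2] * A[2, 3],
    A[3, 2] * A[1, 3] - A[1, 2] * A[3, 3],
    A[1, 2] * A[2, 3] - A[2, 2] * A[1, 3])), tolerance = 1e-12)
  # a along x, b in the xy-plane
  expect_equal(A[2:3, 1], c(0, 0))
  expect_equal(A[3, 2], 0)
})

test_that("degenerate and invalid cells are rejected with a message", {
  expect_error(cell_parameters(-1, 0.5, 0.5), "positive")
  expect_error(cell_parameters(0.5, 0.5, 0.5, gamma = 180), "between 0 and 180")
  # alpha + beta + gamma constraint violated: flat cell
  expect_error(cell_parameters(0.5, 0.5, 0.5, 10, 10, 170), "degenerate")
})

test_that("normalization_map sends the cell onto the alpha cube", {
  W <- normalization_map(cell_parameters(0.5, 0.5, 0.5), 0.1)
  expect_equal(W, 0.2 * diag(3))

  set.seed(11)
  for (i in 1:10) {
    cell <- random_cell()
    A <- cell_matrix(cell)
    W <- normalization_map(cell, 0.1)
    expect_equal(W %*% A, 0.1 * diag(3), tolerance = 1e-12)
    # cell vector a maps to the cube edge (alpha, 0, 0)
    expect_equal(drop(W %*% A[, 1]), c(0.1, 0, 0), tolerance = 1e-12)
  }
  # normalizing an already-cubic cell of side alpha is the identity
  W <- normalization_map(cell_parameters(0.1, 0.1, 0.1), 0.1)
  expect_equal(W, diag(3), tolerance = 1e-12)
})

sorted_rows <- function(m) m[do.call(order, as.data.frame(round(m, 9))), ]

test_that("build_motif_cloud completes boundaries and re-centers", {
  cube <- cell_parameters(1, 1, 1)
  # one centroid anywhere gives the 8 cube corners
  cl0 <- build_motif_cloud(crystal_centroids(cube, c(0, 0, 0)), 0.1)
  cl3 <- build_motif_cloud(crystal_centroids(cube, c(0.3, 0.3, 0.3)), 0.1)
  expect_equal(nrow(cl0$points), 8)
  expect_equal(sorted_rows(cl3$points), sorted_rows(cl0$points),
               tolerance = 1e-12)

  # motif sizes: P 8, C 10, I 9, F 14
  sizes <- c(P = 8, C = 10, I = 9, F = 14)
  for (ty in names(sizes)) {
    cl <- build_motif_cloud(
      crystal_centroids(cube, lattice_fractional_motif(ty)), 0.1)
    expect_equal(nrow(cl$points), unname(sizes[ty]))
  }
  # body center present for I
  clI <- build_motif_cloud(
    crystal_centroids(cube, rbind(c(0, 0, 0), c(0.5, 0.5, 0.5))), 0.1)
  expect_true(any(apply(clI$points, 1, function(p)
    all(abs(p - 0.05) < 1e-12))))
})

test_that("translation invariance of the motif cloud", {
  cube <- cell_parameters(1, 1, 1)
  frac <- lattice_fractional_motif("F")
  base <- build_motif_cloud(crystal_centroids(cube, frac), 0.1)
  set.seed(5)
  for (i in 1:5) {
    sh <- runif(3)
    moved <- build_motif_cloud(
      crystal_centroids(cube, sweep(frac, 2, sh, "+")), 0.1)
    expect_equal(sorted_rows(moved$points), sorted_rows(base$points),
                 tolerance = 1e-9)
  }
})

test_that("A-centered setting gives a cloud congruent to the C motif", {
  cube <- cell_parameters(1, 1, 1)
  clA <- build_motif_cloud(
    crystal_centroids(cube, rbind(c(0, 0, 0), c(0, 0.5, 0.5))), 0.1)
  expect_equal(nrow(clA$points), 10)
  clC <- motif_points("C", 0.1, c_axis = "x")
  # congruence via sorted pairwise-distance multisets
  expect_equal(sort(as.numeric(dist(clA$points))),
               sort(as.numeric(dist(clC$points))), tolerance = 1e-12)
})

test_that("motif cloud of an affine lattice image equals the exact motif", {
  set.seed(21)
  for (ty in c("P", "C", "I", "F")) {
    cell <- random_cell()
    cr <- crystal_centroids(cell, lattice_fractional_motif(ty))
    cl <- build_motif_cloud(cr, 0.1)
    ref <- motif_points(ty, 0.1)
    expect_equal(sorted_rows(cl$points), sorted_rows(ref$points),
                 tolerance = 1e-10)
  }
})

test_that("centroids_from_atoms averages per molecule", {
  cell <- cell_parameters(1, 1, 1)
  atoms <- rbind(c(0.1, 0.1, 0.1), c(0.3, 0.1, 0.1),   # molecule 1
                 c(0.6, 0.6, 0.6), c(0.8, 0.8, 0.6))   # molecule 2
  cr <- centroids_from_atoms(cell, atoms, molecule = c(1, 1, 2, 2))
  expect_equal(sorted_rows(cr$centroids),
               sorted_rows(rbind(c(0.2, 0.1, 0.1), c(0.7, 0.7, 0.6))),
               tolerance = 1e-12)
  # mass weighting moves the centroid toward the heavy atom
  crw <- centroids_from_atoms(cell, atoms[1:2, ], molecule = c(1, 1),
                              weights = c(1, 3))
  expect_equal(unname(crw$centroids[1, 1]), 0.25, tolerance = 1e-12)
})

test_that("fractional coordinates are wrapped into [0, 1)", {
  cr <- crystal_centroids(cell_parameters(1, 1, 1),
                          rbind(c(1.2, -0.3, 2.5)))
  expect_true(all(cr$centroids >= 0 & cr$centroids < 1))
  expect_equal(unname(cr$centroids[1, ]), c(0.2, 0.7, 0.5),
               tolerance = 1e-12)
})
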