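test_that("motif point sets have the expected geometry", {
  expect_equal(nrow(motif_points("P", 0.1)$points), 8)
  expect_equal(nrow(motif_points("C", 0.1)$points), 10)
  expect_equal(nrow(motif_points("I", 0.1)$points), 9)
  f <- motif_points("F", 0.1)$points
  expect_equal(nrow(f), 14)
  expect_equal(min(dist(f)), 0.1 / sqrt(2), tolerance = 1e-12)
  i <- motif_points("I", 0.1)$points
  expect_true(any(apply(i, 1, function(p) all(abs(p - 0.05) < 1e-12))))
  expect_error(motif_points("Q"), "lattice type")
})

test_that("single-cell reference diagrams match their analytic values", {
  a <- 0.1
  # P and F single-cell clouds realize the full analytic diagrams
  for (ty in c("P", "F")) {
    dg <- reference_diagrams(ty, a)
    want <- analytic_bulk_values(ty, a)
    for (q in as.character(0:2))
      expect_equal(unname(distinct_pairs(dg[[q]])), unname(want[[q]]),
                   tolerance = 1e-9 * a)
  }
  # C and I single cells: q = 0 analytic; q = 1 carries only the
  # in-cell ring; q = 2 is empty (their cavities straddle cell faces)
  dgC <- reference_diagrams("C", a)
  expect_equal(unname(distinct_pairs(dgC[["0"]])),
               unname(analytic_bulk_values("C", a)[["0"]]),
               tolerance = 1e-9 * a)
  expect_equal(unname(distinct_pairs(dgC[["1"]])),
               cbind(a / 2, sqrt(3) * a / (2 * sqrt(2))),
               tolerance = 1e-9 * a)
  expect_equal(nrow(dgC[["2"]]), 0)
  dgI <- reference_diagrams("I", a)
  expect_equal(unname(distinct_pairs(dgI[["0"]])),
               unname(analytic_bulk_values("I", a)[["0"]]),
               tolerance = 1e-9 * a)
  expect_equal(unname(distinct_pairs(dgI[["1"]])),
               cbind(a / 2, 3 * a / (4 * sqrt(2))),
               tolerance = 1e-9 * a)
  expect_equal(nrow(dgI[["2"]]), 0)
})

test_that("reference diagrams scale linearly with the cube side", {
  for (ty in c("P", "I")) {
    d1 <- reference_diagrams(ty, 0.1)
    d2 <- reference_diagrams(ty, 0.35)
    for (q in as.character(0:2)) {
      m1 <- unclass(d1[[q]]); m2 <- unclass(d2[[q]])
      expect_equal(m2[order(m2[, 1], m2[, 2]), , drop = FALSE],
                   m1[order(m1[, 1], m1[, 2]), , drop = FALSE] * 3.5,
                   tolerance = 1e-9)
    }
  }
})

test_that("C diagrams are identical across centering axes", {
  for (q in as.character(0:2)) {
    dz <- reference_diagrams("C", 0.1, "z")[[q]]
    for (ax in c("x", "y")) {
      d <- reference_diagrams("C", 0.1, ax)[[q]]
      expect_equal(bottleneck_distance(d, dz), 0, tolerance = 1e-12)
    }
  }
})

test_that("reference ellipsoids touch nearest neighbours without overlap", {
  a <- 0.1
  for (ty in c("P", "C", "I", "F")) {
    ref <- reference_ellipsoid(ty, a)
    pts <- motif_points(ty, a)$points
    D <- as.matrix(dist(pts))
    diag(D) <- Inf
    for (i in seq_len(nrow(pts))) {
      js <- which(abs(D[i, ] - min(D[i, ])) < 1e-12)
      for (j in js) {
        u <- pts[j, ] - pts[i, ]
        # semi-axis length along a contact direction = half the distance
        ell_r <- 1 / sqrt(drop(t(u / sqrt(sum(u^2))) %*% ref$R %*%
                                 (u / sqrt(sum(u^2)))))
        expect_equal(ell_r, min(D[i, ]) / 2, tolerance = 1e-9)
      }
      # no overlap: every half-separation point lies on or outside the
      # ellipsoid quadric
      for (j in seq_len(nrow(pts))[-i]) {
        h <- (pts[j, ] - pts[i, ]) / 2
        expect_gte(drop(t(h) %*% ref$R %*% h), 1 - 1e-9)
      }
    }
  }
})

test_that("C's distinguished semi-axis follows the centering axis", {
  for (ax in c("x", "y", "z")) {
    r <- reference_ellipsoid("C", 0.1, ax)$radii
    k <- match(ax, c("x", "y", "z"))
    expect_equal(r[k], 0.05)
    expect_equal(r[-k], rep(sqrt(2) * 0.1 / 4, 2))
  }
})

test_that("packing fractions match their closed forms", {
  expect_equal(packing_fraction("F"), pi / sqrt(18), tolerance = 1e-12)
  expect_equal(packing_fraction("P"), pi / 6, tolerance = 1e-12)
  expect_equal(packing_fraction("C"), pi / 6, tolerance = 1e-12)
  expect_equal(packing_fraction("I"), sqrt(3) * pi / 8, tolerance = 1e-12)
})

test_that("bulk diagrams recover the cross-cell lattice features", {
  a <- 0.1
  for (ty in c("C", "I")) {
    dg <- lattice_bulk_diagrams(ty, a)
    want <- analytic_bulk_values(ty, a)
    for (q in as.character(0:2))
      expect_equal(unname(distinct_pairs(dg[[q]])), unname(want[[q]]),
                   tolerance = 1e-9 * a)
  }
})
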