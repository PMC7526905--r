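test_that("pairwise merge happens at half the distance", {
  d <- compute_diagrams(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_equal(unclass(d[["0"]]), cbind(birth = c(0, 0),
                                        death = c(0.05, Inf)),
               ignore_attr = "dimension")
  expect_equal(nrow(d[["1"]]), 0)
  expect_equal(nrow(d[["2"]]), 0)
})

test_that("a square's ring is born at half-side and dies at circumradius", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  d1 <- compute_diagrams(sq)[["1"]]
  expect_equal(unclass(d1), cbind(birth = 0.5, death = 1 / sqrt(2)),
               tolerance = 1e-12, ignore_attr = "dimension")
})

test_that("the cube motif has 7 merges at half-edge and one essential class", {
  d <- compute_diagrams(motif_points("P", 0.1))
  d0 <- unclass(d[["0"]])
  expect_equal(nrow(d0), 8)
  expect_equal(sum(is.infinite(d0[, 2])), 1)
  expect_equal(d0[is.finite(d0[, 2]), 2], rep(0.05, 7), tolerance = 1e-12)
})

test_that("duplicate points are rejected", {
  expect_error(compute_diagrams(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicate")
})

# sort rows by (birth, death) on a 1e-9 grid so float noise in exact
# ties cannot reorder equal-value rows between two computations
diagram_sorted <- function(d) {
  m <- unclass(d)
  m[order(round(m[, 1], 9), round(m[, 2], 9)), , drop = FALSE]
}

test_that("diagrams are invariant under rigid motions", {
  set.seed(31)
  pts <- motif_points("C", 0.1)$points
  base <- compute_diagrams(pts)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- pts %*% Q + matrix(rnorm(3), nrow(pts), 3, byrow = TRUE)
    got <- compute_diagrams(moved)
    for (q in as.character(0:2))
      expect_equal(diagram_sorted(got[[q]]), diagram_sorted(base[[q]]),
                   tolerance = 1e-9)
  }
})

test_that("diagrams are scale equivariant", {
  set.seed(32)
  pts <- matrix(runif(21), 7)
  base <- compute_diagrams(pts)
  for (s in c(0.1, 3)) {
    got <- compute_diagrams(pts * s)
    for (q in as.character(0:2)) {
      b <- diagram_sorted(base[[q]]); g <- diagram_sorted(got[[q]])
      expect_equal(g, b * s, tolerance = 1e-9)
    }
  }
})

test_that("minimum enclosing balls match the subset-enumeration oracle", {
  set.seed(33)
  for (rep in 1:100) {
    P <- matrix(rnorm(12), 4)
    idx3 <- utils::combn(4, 3)
    tri <- ellipack:::tri_meb(P, idx3)
    for (j in 1:4)
      expect_equal(tri$r[j], meb_oracle(P[idx3[, j], ]), tolerance = 1e-9)
    v4 <- ellipack:::tet_meb(P, matrix(1:4), tri$r, tri$center, 4)
    expect_equal(v4, meb_oracle(P), tolerance = 1e-9)
  }
  # exact symmetric cases
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(ellipack:::tri_meb(eq, matrix(1:3))$r, 1 / sqrt(3),
               tolerance = 1e-12)
  obtuse <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.1, 0))
  expect_equal(ellipack:::tri_meb(obtuse, matrix(1:3))$r, 0.5,
               tolerance = 1e-12)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(ellipack:::tet_meb(tet, matrix(1:4),
                                  ellipack:::tri_meb(tet, utils::combn(4, 3))$r,
                                  ellipack:::tri_meb(tet, utils::combn(4, 3))$center,
                                  4),
               sqrt(3), tolerance = 1e-12)
})

test_that("diagram Betti numbers agree with GF(2) rank computation", {
  set.seed(34)
  clouds <- c(
    lapply(1:4, function(i) matrix(runif(18), 6)),
    list(motif_points("I", 1)$points, motif_points("C", 1)$points))
  for (pts in clouds) {
    dg <- compute_diagrams(pts)
    radii <- sort(unique(c(as.numeric(dist(pts)) / 2, 0.3, 0.6)))
    probe <- radii[seq(1, length(radii), length.out = 6)] + 1e-7
    for (r in probe)
      expect_equal(betti_from_diagrams(dg, r), betti_at_radius(pts, r),
                   tolerance = 0)
  }
})

test_that("distinct_pairs deduplicates multisets", {
  d <- structure(cbind(c(0, 0, 0, 0), c(0.5, 0.5, 0.7, Inf)),
                 dimension = 0L, class = "persistence_diagram")
  got <- distinct_pairs(d)
  expect_equal(nrow(got), 3)
  expect_equal(got[, 2], c(0.5, 0.7, Inf))
})

test_that("diagram CSV serialization round-trips including infinities", {
  dg <- compute_diagrams(motif_points("F", 0.1))
  path <- tempfile(fileext = ".csv")
  write_diagrams(dg, path)
  back <- read_diagrams(path)
  for (q in as.character(0:2))
    expect_equal(diagram_sorted(back[[q]]), diagram_sorted(dg[[q]]),
                 tolerance = 1e-12)
})
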