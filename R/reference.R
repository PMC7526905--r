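## Reference motifs, diagrams and ellipsoids for the four basic cubic
## Bravais lattices: primitive (P), base-centered (C), body-centered (I)
## and face-centered (F).

LATTICE_TYPES <- c("P", "C", "I", "F")

check_lattice_type <- function(type) {
  if (!(is.character(type) && length(type) == 1 && type %in% LATTICE_TYPES))
    stop("lattice type must be one of ", paste(LATTICE_TYPES, collapse = ", "))
  type
}

axis_index <- function(c_axis) {
  i <- match(c_axis, c("x", "y", "z"))
  if (is.na(i)) stop("centering axis must be one of \"x\", \"y\", \"z\"")
  i
}

#' Fractional motif positions of a basic cubic lattice
#'
#' The distinct lattice points per unit cell, in fractional coordinates:
#' P has one (the origin), C two (origin + the center of the face pair
#' perpendicular to the centering axis), I two (origin + body center),
#' F four (origin + three face centers).
#'
#' @param type One of `"P"`, `"C"`, `"I"`, `"F"`.
#' @param c_axis Centering axis for type C, one of `"x"`, `"y"`, `"z"`.
#' @return Matrix of fractional coordinates, one row per lattice point.
#' @export
lattice_fractional_motif <- function(type, c_axis = "z") {
  check_lattice_type(type)
  switch(type,
    P = matrix(0, 1, 3),
    C = {
      fc <- c(0.5, 0.5, 0.5)
      fc[axis_index(c_axis)] <- 0
      rbind(c(0, 0, 0), fc)
    },
    I = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
    F = rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)))
}

#' Exact motif point cloud of a basic cubic lattice
#'
#' The boundary-completed point set of the lattice motif in the cube of
#' side `alpha_side`: P yields the 8 cube corners, C 10 points (corners +
#' 2 opposite face centers), I 9 (corners + body center), F 14 (corners +
#' all 6 face centers).
#'
#' @inheritParams lattice_fractional_motif
#' @param alpha_side Cube edge length in nm.
#' @return A [motif_cloud()] object.
#' @examples
#' nrow(motif_points("F", 0.1)$points)   # 14
#' @export
motif_points <- function(type, alpha_side = 0.1, c_axis = "z") {
  frac <- lattice_fractional_motif(type, c_axis)
  cube <- cell_parameters(1, 1, 1)   # unit cube; scaling via alpha_side
  build_motif_cloud(crystal_centroids(cube, frac), alpha_side = alpha_side)
}

# session cache for reference diagrams (keyed by type/alpha/axis)
.ref_diagram_cache <- new.env(parent = emptyenv())

#' Reference persistence diagrams of a basic cubic lattice
#'
#' Computes (and caches) the persistence diagrams of the exact motif
#' cloud of the given lattice type.  After deduplication the (birth,
#' death) values agree with the analytically derived lists: e.g. for
#' type P, q = 0 has distinct values (0, alpha/2) and (0, Inf); for type
#' I all non-essential q = 0 deaths sit at sqrt(3)/4 * alpha (half the
#' corner-to-body-center distance).
#'
#' @inheritParams motif_points
#' @return A `"diagram_set"` object.
#' @export
reference_diagrams <- function(type, alpha_side = 0.1, c_axis = "z") {
  check_lattice_type(type)
  key <- sprintf("%s|%.17g|%s", type, alpha_side,
                 if (type == "C") c_axis else "-")
  if (!is.null(got <- .ref_diagram_cache[[key]])) return(got)
  dg <- compute_diagrams(motif_points(type, alpha_side, c_axis))
  assign(key, dg, envir = .ref_diagram_cache)
  dg
}

#' Reference ellipsoid of a basic cubic lattice
#'
#' The shape of the identical ellipsoids densely packed at the lattice
#' points of the cube of side `alpha_side`, as the diagonal quadratic-form
#' matrix with entries `1 / r_i^2`.  P, I and F pack spheres (radius
#' alpha/2, sqrt(3)alpha/4 and sqrt(2)alpha/4 respectively); C packs
#' spheroids with semi-axes (sqrt(2)alpha/4, sqrt(2)alpha/4, alpha/2),
#' the alpha/2 axis along the centering axis.  Every semi-axis equals
#' half the nearest-neighbour distance along its direction, so contacts
#' are tight.
#'
#' @inheritParams motif_points
#' @return A list of class `"reference_ellipsoid"` with elements `R`
#'   (3x3 diagonal matrix, nm^-2), `radii` (length 3, nm), `type`,
#'   `c_axis` (NA unless type C).
#' @export
reference_ellipsoid <- function(type, alpha_side = 0.1, c_axis = "z") {
  check_lattice_type(type)
  radii <- switch(type,
    P = rep(alpha_side / 2, 3),
    I = rep(sqrt(3) * alpha_side / 4, 3),
    F = rep(sqrt(2) * alpha_side / 4, 3),
    C = {
      r <- rep(sqrt(2) * alpha_side / 4, 3)
      r[axis_index(c_axis)] <- alpha_side / 2
      r
    })
  structure(list(R = diag(radii^-2), radii = radii, type = type,
                 c_axis = if (type == "C") c_axis else NA_character_),
            class = "reference_ellipsoid")
}

#' Packing fraction of a basic cubic lattice
#'
#' Fraction of the unit cell occupied by the reference ellipsoids:
#' `Z * (4/3) pi r1 r2 r3 / alpha^3` with Z = 1, 2, 2, 4 lattice points
#' per cell for P, C, I, F.  Independent of the cube size.  For F this is
#' the closest-packing constant pi / sqrt(18) = 0.74048...; for P (and C)
#' pi / 6; for I sqrt(3) pi / 8.
#'
#' @inheritParams lattice_fractional_motif
#' @return Dimensionless packing fraction.
#' @examples
#' packing_fraction("F")   # 0.7404805
#' @export
packing_fraction <- function(type) {
  check_lattice_type(type)
  z <- c(P = 1, C = 2, I = 2, F = 4)[[type]]
  r <- reference_ellipsoid(type, alpha_side = 1)$radii
  z * (4 / 3) * pi * prod(r)
}

#' Motif cloud of a small multi-cell lattice block
#'
#' Tiles the fractional motif of a lattice type over an `nx` x `ny` x `nz`
#' block of unit cells and boundary-completes the block, returning the
#' point cloud scaled to cubes of side `alpha_side`.  Used to expose
#' bulk-lattice topological features whose representatives do not fit in a
#' single cell (interstitial holes sitting on cell faces).
#'
#' @inheritParams motif_points
#' @param cells Integer vector of length 3: cells along x, y, z.
#' @return A [motif_cloud()]-like list with `points` (nm) and `alpha_side`;
#'   note the points span `[0, cells * alpha_side]` per axis.
#' @export
lattice_block_cloud <- function(type, alpha_side = 0.1, cells = c(1, 1, 1),
                                c_axis = "z") {
  stopifnot(length(cells) == 3, all(cells >= 1))
  frac <- lattice_fractional_motif(type, c_axis)
  pts <- list()
  for (i in 0:(cells[1] - 1)) for (j in 0:(cells[2] - 1))
    for (k in 0:(cells[3] - 1))
      pts[[length(pts) + 1]] <- sweep(frac, 2, c(i, j, k), "+")
  P <- unique(do.call(rbind, pts))
  out <- vector("list", nrow(P))
  for (r in seq_len(nrow(P))) {
    f <- P[r, ]
    offs <- as.matrix(expand.grid(
      if (f[1] < 1e-9) c(0, cells[1]) else 0,
      if (f[2] < 1e-9) c(0, cells[2]) else 0,
      if (f[3] < 1e-9) c(0, cells[3]) else 0))
    out[[r]] <- sweep(offs, 2, f, "+")
  }
  P <- unique(do.call(rbind, out)) * alpha_side
  dimnames(P) <- NULL
  structure(list(points = P, alpha_side = alpha_side), class = "motif_cloud")
}

#' Bulk-lattice persistence diagrams of a basic cubic lattice
#'
#' Persistence diagrams of the lattice computed on the smallest cell block
#' whose interior contains a representative of every bulk topological
#' feature.  A single boundary-completed cell suffices for P and F, but
#' the base-centered and body-centered lattices have interstitial holes
#' centered on cell faces: their ring and cavity classes only close up
#' when two adjacent cells are present.  Blocks used: P, F 1x1x1;
#' C 2x1x1 (extension perpendicular to the centering axis); I 1x1x2.
#'
#' Deduplicated values are the analytic bulk diagrams, e.g. for type I:
#' q=1 \{(sqrt(3)a/4, 3a/(4 sqrt 2)), (a/2, 3a/(4 sqrt 2))\},
#' q=2 \{(3a/(4 sqrt 2), sqrt(5)a/4)\} for cube side a.  These differ from
#' [reference_diagrams()] (the single-cell clouds the classifier uses) in
#' exactly those bulk-only classes.
#'
#' @inheritParams motif_points
#' @return A `"diagram_set"` object.
#' @export
lattice_bulk_diagrams <- function(type, alpha_side = 0.1) {
  check_lattice_type(type)
  cells <- switch(type,
    P = c(1, 1, 1), F = c(1, 1, 1),
    C = c(2, 1, 1),      # centering axis z; extend along x
    I = c(1, 1, 2))
  compute_diagrams(lattice_block_cloud(type, alpha_side, cells))
}
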