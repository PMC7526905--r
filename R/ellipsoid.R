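#' Estimate the packed-ellipsoid shape of a classified crystal
#'
#' For a crystal assigned to lattice type Z, the identical ellipsoids
#' packed at its molecular centroids are the pre-image, under the cell
#' normalization map W, of the reference ellipsoids packed in the cube:
#' their quadratic form in crystal Cartesian coordinates is the symmetric
#' matrix `Q = t(W) R_Z W`, and the semi-axis lengths are the reciprocal
#' square roots of its eigenvalues.
#'
#' @param crystal The [crystal_centroids()] object that was classified.
#' @param assignment The [classify()] result; its type must be one of
#'   P, C, I, F (an `"OTHER"` assignment has no reference ellipsoid).
#' @return An object of class `"ellipsoid_shape"`: list with `radii`
#'   (length 3, nm, sorted r1 >= r2 >= r3), `axes` (3x3 matrix whose
#'   columns are the unit principal axes in crystal Cartesian
#'   coordinates, ordered like `radii`), `volume_nm3`, `Q`, `type`,
#'   `c_axis`.  For degenerate radii (spheres/spheroids) the eigenbasis
#'   is any orthonormal choice.
#' @examples
#' cr <- crystal_centroids(cell_parameters(0.5, 0.5, 0.5), c(0, 0, 0))
#' estimate_ellipsoid(cr, classify(cr))$radii   # 0.25 0.25 0.25
#' @export
estimate_ellipsoid <- function(crystal, assignment) {
  stopifnot(inherits(assignment, "lattice_assignment"))
  if (assignment$type == "OTHER")
    stop("no reference ellipsoid defined for an OTHER assignment")
  c_axis <- if (assignment$type == "C") {
    if (is.na(assignment$c_axis))
      stop("C-type assignment lacks a detected centering axis")
    assignment$c_axis
  } else "z"
  ref <- reference_ellipsoid(assignment$type, assignment$alpha_side, c_axis)
  W <- assignment$W
  Q <- t(W) %*% ref$R %*% W
  Q <- (Q + t(Q)) / 2
  e <- eigen(Q, symmetric = TRUE)       # eigenvalues in decreasing order
  if (any(e$values <= 0))
    stop("internal error: non-positive eigenvalue in ellipsoid form")
  ord <- 3:1                            # radii = 1/sqrt(lambda), descending
  radii <- 1 / sqrt(e$values[ord])
  axes <- e$vectors[, ord, drop = FALSE]
  structure(list(radii = radii, axes = axes,
                 volume_nm3 = (4 / 3) * pi * prod(radii),
                 Q = Q, type = assignment$type,
                 c_axis = assignment$c_axis),
            class = "ellipsoid_shape")
}

#' Volume of an ellipsoid shape
#'
#' `V = (4/3) pi r1 r2 r3`, in nm^3, or per mole of molecules in
#' cm^3/mol (multiplying by Avogadro's number; 1 nm^3 = 1e-21 cm^3).
#'
#' @param shape An `"ellipsoid_shape"` object (or anything with a
#'   `radii` element).
#' @param per_mole If `TRUE`, return cm^3/mol instead of nm^3.
#' @return Volume as a single number.
#' @export
ellipsoid_volume <- function(shape, per_mole = FALSE) {
  r <- shape$radii
  stopifnot(length(r) == 3, all(r > 0))
  v <- (4 / 3) * pi * prod(r)
  if (per_mole) v * 6.02214076e23 * 1e-21 else v
}

#' @export
print.ellipsoid_shape <- function(x, ...) {
  cat(sprintf("Ellipsoid (type %s): r1 = %.4f, r2 = %.4f, r3 = %.4f nm; V = %.4g nm^3\n",
              x$type, x$radii[1], x$radii[2], x$radii[3], x$volume_nm3))
  invisible(x)
}
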