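#' Boundary-completed motif cloud of a crystal
#'
#' Builds the finite point cloud used for topological analysis: all
#' fractional centroids are translated so that the first centroid sits at
#' the origin and wrapped into `[0, 1)`; every centroid coordinate lying
#' on the cell boundary (within `boundary_tol`) generates the periodic
#' image(s) obtained by adding 1 to that coordinate, so corners, edges and
#' faces of the cube are fully populated; finally the cloud is scaled to
#' the cube `[0, alpha_side]^3`.
#'
#' A single centroid per cell therefore yields the 8 cube corners; the
#' base-centered motif yields 10 points, body-centered 9, face-centered 14.
#'
#' @param crystal A [crystal_centroids()] object.
#' @param alpha_side Cube edge length in nm (default 0.1).
#' @param boundary_tol Fractional tolerance deciding when a coordinate
#'   "is" 0 and deserves a +1 image (default 1e-6).
#' @return An object of class `"motif_cloud"`: list with `points`
#'   (n x 3 matrix, nm) and `alpha_side`.
#' @examples
#' cr <- crystal_centroids(cell_parameters(0.5, 0.5, 0.5),
#'                         rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)))
#' nrow(build_motif_cloud(cr)$points)  # 9: corners + body center
#' @export
build_motif_cloud <- function(crystal, alpha_side = 0.1, boundary_tol = 1e-6) {
  stopifnot(inherits(crystal, "crystal_centroids"),
            alpha_side > 0, boundary_tol >= 0)
  frac <- crystal$centroids
  shift <- frac[1, ]
  frac <- wrap_frac(sweep(frac, 2, shift), tol = boundary_tol)
  pts <- vector("list", nrow(frac))
  for (i in seq_len(nrow(frac))) {
    f <- frac[i, ]
    on_bd <- f < boundary_tol           # coordinates sitting at 0
    offs <- as.matrix(expand.grid(
      if (on_bd[1]) c(0, 1) else 0,
      if (on_bd[2]) c(0, 1) else 0,
      if (on_bd[3]) c(0, 1) else 0))
    pts[[i]] <- sweep(offs, 2, f, "+")
  }
  pts <- do.call(rbind, pts) * alpha_side
  dimnames(pts) <- NULL
  motif_cloud(pts, alpha_side)
}

#' Motif cloud constructor
#'
#' Low-level constructor validating a point cloud in the closed cube
#' `[0, alpha_side]^3`: no duplicate points, all coordinates inside the
#' cube within tolerance.
#'
#' @param points n x 3 numeric matrix (nm).
#' @param alpha_side Cube edge length (nm).
#' @param tol Absolute tolerance for the cube-containment and duplicate
#'   checks (default `1e-9 * alpha_side`).
#' @return A `"motif_cloud"` object.
#' @export
motif_cloud <- function(points, alpha_side, tol = 1e-9 * alpha_side) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1, all(is.finite(points)))
  if (any(points < -tol) || any(points > alpha_side + tol))
    stop("motif cloud points fall outside the cube [0, ", alpha_side, "]^3")
  if (nrow(points) > 1) {
    d <- stats::dist(points)
    if (min(d) < tol)
      stop("motif cloud contains duplicate points (min pairwise distance ",
           format(min(d)), " nm)")
  }
  structure(list(points = points, alpha_side = alpha_side),
            class = "motif_cloud")
}

#' @export
print.motif_cloud <- function(x, ...) {
  cat(sprintf("Motif cloud: %d points in [0, %g]^3 nm\n",
              nrow(x$points), x$alpha_side))
  invisible(x)
}
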