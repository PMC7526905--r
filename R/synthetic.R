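#' Generate a synthetic crystal with a planted lattice type and ellipsoid
#'
#' Places the fractional motif of a basic cubic lattice in a (given or
#' randomly drawn) unit cell -- an affine image of the cubic arrangement
#' -- optionally jitters the fractional centroids, and computes the
#' ground-truth ellipsoid analytically: the shape whose normalized image
#' is the reference ellipsoid of the planted type.  At `eta = 0` the
#' classification pipeline must recover the planted type with score 0 and
#' the estimator must reproduce the planted radii exactly.
#'
#' @param type Planted lattice type, one of `"P"`, `"C"`, `"I"`, `"F"`.
#' @param cell Optional [cell_parameters()]; if `NULL`, a random cell is
#'   drawn (edge lengths uniform in 0.3--1.2 nm, angles uniform in
#'   70--110 degrees, rejected until the cell matrix condition number is
#'   at most `cond_max`).
#' @param eta Fractional jitter magnitude: each non-anchor centroid
#'   coordinate is perturbed by Uniform(-eta, eta) before boundary-image
#'   expansion (default 0).
#' @param seed Optional integer seed for reproducible draws.
#' @param cond_max Condition-number bound on the cell matrix (default 10).
#' @param c_axis Centering axis when `type = "C"`.
#' @param alpha_side Normalization cube side (nm) used for the planted
#'   ellipsoid (default 0.1); the planted radii do not depend on it.
#' @return A list of class `"synthetic_crystal"`: `crystal` (a
#'   [crystal_centroids()]), `shape` (the planted `"ellipsoid_shape"`),
#'   `type`, `c_axis`, `eta`.
#' @examples
#' syn <- generate_crystal("F", cell_parameters(0.4, 0.5, 0.6, 80, 95, 100))
#' classify(syn$crystal)$type   # "F"
#' @export
generate_crystal <- function(type, cell = NULL, eta = 0, seed = NULL,
                             cond_max = 10, c_axis = "z", alpha_side = 0.1) {
  check_lattice_type(type)
  stopifnot(eta >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cell)) cell <- random_cell(cond_max = cond_max)
  A <- cell_matrix(cell)
  if (kappa(A, exact = TRUE) > cond_max)
    stop("cell matrix condition number ", format(kappa(A, exact = TRUE)),
         " exceeds bound ", cond_max)
  frac <- lattice_fractional_motif(type, c_axis)
  if (eta > 0) {
    jit <- matrix(stats::runif(length(frac), -eta, eta), nrow = nrow(frac))
    jit[1, ] <- 0                       # anchor: motif is translation invariant
    frac <- wrap_frac(frac + jit)
  }
  crystal <- crystal_centroids(cell, frac,
                               id = sprintf("synthetic_%s", type))
  W <- normalization_map(cell, alpha_side)
  ref <- reference_ellipsoid(type, alpha_side, c_axis)
  Q <- t(W) %*% ref$R %*% W
  Q <- (Q + t(Q)) / 2
  e <- eigen(Q, symmetric = TRUE)
  radii <- 1 / sqrt(e$values[3:1])
  shape <- structure(list(radii = radii, axes = e$vectors[, 3:1],
                          volume_nm3 = (4 / 3) * pi * prod(radii),
                          Q = Q, type = type,
                          c_axis = if (type == "C") c_axis else NA_character_),
                     class = "ellipsoid_shape")
  structure(list(crystal = crystal, shape = shape, type = type,
                 c_axis = c_axis, eta = eta),
            class = "synthetic_crystal")
}

#' Draw a random, well-conditioned unit cell
#'
#' Edge lengths uniform in `len_range` (nm), angles uniform in
#' `ang_range` (degrees); draws are rejected until the cell matrix
#' condition number is at most `cond_max`.  Uses the current RNG state.
#'
#' @param len_range,ang_range Length-2 numeric ranges.
#' @param cond_max Condition-number bound (2-norm).
#' @return A [cell_parameters()] object.
#' @export
random_cell <- function(len_range = c(0.3, 1.2), ang_range = c(70, 110),
                        cond_max = 10) {
  for (i in 1:1000) {
    cell <- tryCatch(
      cell_parameters(stats::runif(1, len_range[1], len_range[2]),
                      stats::runif(1, len_range[1], len_range[2]),
                      stats::runif(1, len_range[1], len_range[2]),
                      stats::runif(1, ang_range[1], ang_range[2]),
                      stats::runif(1, ang_range[1], ang_range[2]),
                      stats::runif(1, ang_range[1], ang_range[2])),
      error = function(e) NULL)
    if (is.null(cell)) next
    A <- tryCatch(cell_matrix(cell), error = function(e) NULL)
    if (!is.null(A) && kappa(A, exact = TRUE) <= cond_max) return(cell)
  }
  stop("failed to draw a cell with condition number <= ", cond_max)
}

#' Generate a crystal whose centroids do not form a basic lattice
#'
#' Negative control for the classifier: one centroid at the origin plus
#' `n_extra` generic fractional positions (uniform, kept away from the
#' cell boundary and from lattice special positions by rejection).  Such
#' arrangements score far above any acceptance threshold against all four
#' references.
#'
#' @param cell Optional [cell_parameters()]; random if `NULL`.
#' @param n_extra Number of generic non-origin centroids (default 1).
#' @param seed Optional integer seed.
#' @param cond_max Condition bound for the random cell.
#' @return A [crystal_centroids()] object.
#' @export
generate_generic_crystal <- function(cell = NULL, n_extra = 1, seed = NULL,
                                     cond_max = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cell)) cell <- random_cell(cond_max = cond_max)
  extra <- matrix(stats::runif(3 * n_extra, 0.1, 0.9), ncol = 3)
  crystal_centroids(cell, rbind(c(0, 0, 0), extra), id = "generic")
}
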