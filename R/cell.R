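#' Unit-cell parameters
#'
#' Constructs and validates a set of unit-cell parameters for a crystal:
#' three edge lengths (nm) and three inter-axial angles (degrees).
#'
#' @param a,b,c Cell edge lengths in nm; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, strictly between
#'   0 and 180.  `alpha` is the angle between **b** and **c**, `beta`
#'   between **a** and **c**, `gamma` between **a** and **b**.
#'
#' @return An object of class `"cell_parameters"`: a named list with
#'   elements `a`, `b`, `c` (nm) and `alpha`, `beta`, `gamma` (degrees).
#'
#' @details The parameters must describe a non-degenerate parallelepiped:
#' the squared-volume factor
#' \eqn{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#'      2\cos\alpha\cos\beta\cos\gamma}
#' must be positive.
#'
#' @examples
#' cell_parameters(0.5, 0.5, 0.5)                  # cubic, 0.5 nm
#' cell_parameters(0.4, 0.5, 0.6, 80, 95, 100)     # triclinic
#' @export
cell_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(alpha), is.numeric(beta), is.numeric(gamma))
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("cell lengths must be positive and finite: ",
         paste(sprintf("%s=%g", names(lens), lens), collapse = ", "))
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees: ",
         paste(sprintf("%s=%g", names(angs), angs), collapse = ", "))
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  vol2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol2 <= 1e-12)
    stop(sprintf(
      "degenerate cell (volume factor %.3g <= 0) for angles alpha=%g, beta=%g, gamma=%g",
      vol2, alpha, beta, gamma))
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("Unit cell: a=%g b=%g c=%g nm;  alpha=%g beta=%g gamma=%g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Cartesian cell matrix
#'
#' Returns the 3x3 matrix whose columns are the cell vectors in the
#' standard crystallographic Cartesian convention: **a** along x, **b**
#' in the xy-plane, **c** completing a right-handed frame.  The Cartesian
#' position of a fractional coordinate `f` is `A %*% f`, and `det(A)` is
#' the cell volume (nm^3).
#'
#' @param cell A [cell_parameters()] object.
#' @return A 3x3 numeric matrix (columns = cell vectors, nm).
#' @examples
#' A <- cell_matrix(cell_parameters(0.5, 0.5, 0.5))
#' det(A)   # 0.125 nm^3
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "cell_parameters"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  # c-vector components from the metric tensor
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - cx^2 - cy^2
  if (cz2 <= 0)
    stop("degenerate cell: c vector has non-positive out-of-plane component")
  A <- matrix(c(cell$a, 0, 0,
                cell$b * cg, cell$b * sg, 0,
                cx, cy, sqrt(cz2)), nrow = 3)
  if (abs(det(A)) <= 1e-12)
    stop("degenerate cell: volume ", det(A), " nm^3")
  A
}

#' Affine normalization map of a unit cell onto the reference cube
#'
#' The linear map `W` that sends the crystal's cell vectors onto the edges
#' of the axis-aligned cube of side `alpha_side`, i.e. `W = alpha_side *
#' solve(cell_matrix(cell))`.  A fractional coordinate `f` maps to
#' `alpha_side * f` under `W` applied to its Cartesian position.
#'
#' @param cell A [cell_parameters()] object.
#' @param alpha_side Edge length of the target cube in nm (default 0.1).
#' @return A 3x3 numeric matrix `W` with `W %*% cell_matrix(cell) ==
#'   alpha_side * diag(3)`.
#' @export
normalization_map <- function(cell, alpha_side = 0.1) {
  stopifnot(is.numeric(alpha_side), length(alpha_side) == 1, alpha_side > 0)
  alpha_side * solve(cell_matrix(cell))
}

wrap_frac <- function(x, tol = 1e-9) {
  w <- x - floor(x)
  # pull values within tol of 1 back to 0 so wrapping is stable
  w[w > 1 - tol] <- 0
  w
}

#' Crystal centroid description
#'
#' Bundles a unit cell with the fractional coordinates of the molecular
#' centroids it contains -- the pipeline's input object.
#'
#' @param cell A [cell_parameters()] object.
#' @param centroids Numeric matrix with 3 columns (or a length-3 vector),
#'   one row per molecular centroid, in fractional coordinates.  Values
#'   are wrapped into `[0, 1)`.
#' @param smiles Optional SMILES string of the (single) molecule type.
#' @param id Optional provenance label.
#' @return An object of class `"crystal_centroids"`.
#' @seealso [centroids_from_atoms()] to derive centroids from atom tables.
#' @export
crystal_centroids <- function(cell, centroids, smiles = NULL, id = NULL) {
  stopifnot(inherits(cell, "cell_parameters"))
  if (is.null(dim(centroids))) centroids <- matrix(centroids, ncol = 3)
  centroids <- unname(as.matrix(centroids))
  if (ncol(centroids) != 3 || nrow(centroids) < 1)
    stop("centroids must be an n x 3 matrix with n >= 1")
  if (any(!is.finite(centroids)))
    stop("centroids contain non-finite values")
  structure(list(cell = cell,
                 centroids = wrap_frac(centroids),
                 smiles = smiles, id = id),
            class = "crystal_centroids")
}

#' @export
print.crystal_centroids <- function(x, ...) {
  cat(sprintf("Crystal%s: %d centroid(s) per cell\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "", nrow(x$centroids)))
  print(x$cell)
  invisible(x)
}

#' Molecular centroids from an atom table
#'
#' Computes one centroid per molecule as the (optionally mass-weighted)
#' mean of atomic Cartesian positions, then converts back to fractional
#' coordinates.  The atom-to-molecule assignment must be given explicitly;
#' no bond perception is attempted.
#'
#' @param cell A [cell_parameters()] object.
#' @param frac_atoms n x 3 matrix of fractional atomic coordinates.
#' @param molecule Length-n vector assigning each atom to a molecule.
#' @param weights Optional length-n numeric atomic weights (e.g. masses);
#'   default unweighted.
#' @param ... Passed on to [crystal_centroids()].
#' @return A [crystal_centroids()] object with one centroid per molecule.
#' @export
centroids_from_atoms <- function(cell, frac_atoms, molecule, weights = NULL,
                                 ...) {
  frac_atoms <- as.matrix(frac_atoms)
  stopifnot(ncol(frac_atoms) == 3, length(molecule) == nrow(frac_atoms))
  if (is.null(weights)) weights <- rep(1, nrow(frac_atoms))
  stopifnot(length(weights) == nrow(frac_atoms), all(weights > 0))
  A <- cell_matrix(cell)
  xyz <- frac_atoms %*% t(A)
  cent <- do.call(rbind, lapply(split(seq_along(molecule), molecule), function(i) {
    w <- weights[i]
    colSums(xyz[i, , drop = FALSE] * w) / sum(w)
  }))
  frac <- cent %*% t(solve(A))
  crystal_centroids(cell, frac, ...)
}
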