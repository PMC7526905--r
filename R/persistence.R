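## Persistent homology of small 3D point clouds under a ball-growth (Cech)
## filtration.  The filtration value of a simplex is the radius of the
## minimum enclosing ball of its vertices, so a feature involving two
## points at distance d appears at r = d/2 -- the ball-RADIUS scale.
## Clouds here are tiny (boundary-completed lattice motifs, <= ~32
## points), so the exact Cech complex up to dimension 3 is enumerated and
## reduced with the standard Z/2 boundary-matrix algorithm.  Homology is
## computed for q = 0, 1, 2; dimension-3 simplices are needed only to
## kill 2-cycles (the 3-skeleton of a simplex has trivial H2 at full
## filtration, so no spurious essential classes arise from truncation).

# Minimum enclosing balls of all point triples (vectorized).  idx is a
# 3 x T index matrix; returns radii and centers.  Obtuse (and degenerate)
# triangles are enclosed by the ball on their longest edge; acute ones by
# their circumcircle (barycentric circumcenter formula).
tri_meb <- function(points, idx) {
  P1 <- points[idx[1, ], , drop = FALSE]
  P2 <- points[idx[2, ], , drop = FALSE]
  P3 <- points[idx[3, ], , drop = FALSE]
  a2 <- rowSums((P2 - P3)^2)            # squared side opposite P1
  b2 <- rowSums((P1 - P3)^2)
  c2 <- rowSums((P1 - P2)^2)
  long2 <- pmax(a2, b2, c2)
  obtuse <- 2 * long2 >= a2 + b2 + c2 - 1e-14
  # acute circumcenter: barycentric weights a^2(b^2+c^2-a^2), ...
  wA <- a2 * (b2 + c2 - a2)
  wB <- b2 * (c2 + a2 - b2)
  wC <- c2 * (a2 + b2 - c2)
  ws <- wA + wB + wC
  ws[ws == 0] <- 1                      # degenerate rows use the edge ball
  ctr <- (P1 * wA + P2 * wB + P3 * wC) / ws
  mid <- (P2 + P3) / 2
  useb <- b2 >= a2 & b2 >= c2
  usec <- c2 >= a2 & c2 >= b2 & !useb
  mid[useb, ] <- (P1[useb, , drop = FALSE] + P3[useb, , drop = FALSE]) / 2
  mid[usec, ] <- (P1[usec, , drop = FALSE] + P2[usec, , drop = FALSE]) / 2
  ctr[obtuse, ] <- mid[obtuse, , drop = FALSE]
  r <- ifelse(obtuse, sqrt(long2) / 2,
              sqrt(pmax(rowSums((ctr - P1)^2), 0)))
  list(r = r, center = ctr)
}

# Lexicographic rank of 3-subsets {a < b < c} of 1..n in combn(n, 3)
# column order (vectorized over equal-length a, b, c).
rank_comb3 <- function(n, a, b, c) {
  before_a <- choose(n, 3) - choose(n - a + 1, 3)
  before_b <- choose(n - a, 2) - choose(n - b + 1, 2)
  before_a + before_b + (c - b - 1) + 1
}

# Minimum enclosing balls of all point quadruples.  The MEB of 4 points
# is either the MEB of one of its 4 faces (when that ball already
# contains the opposite vertex) or the circumsphere of all 4; take the
# smallest valid candidate.  Circumspheres are solved in closed form
# (Cramer) across all quadruples.
tet_meb <- function(points, idx4, tri_r, tri_ctr, n) {
  T4 <- ncol(idx4)
  cand <- matrix(Inf, T4, 5)
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  opp <- c(4, 3, 2, 1)
  for (f in seq_along(faces)) {
    fr <- rank_comb3(n, idx4[faces[[f]][1], ], idx4[faces[[f]][2], ],
                     idx4[faces[[f]][3], ])
    rf <- tri_r[fr]
    d2 <- rowSums((tri_ctr[fr, , drop = FALSE] -
                   points[idx4[opp[f], ], , drop = FALSE])^2)
    ok <- d2 <= (rf * (1 + 1e-9))^2 + 1e-18
    cand[ok, f] <- rf[ok]
  }
  # circumsphere: solve 2 B y = d with B rows p_i - p_1
  P1 <- points[idx4[1, ], , drop = FALSE]
  B1 <- points[idx4[2, ], , drop = FALSE] - P1
  B2 <- points[idx4[3, ], , drop = FALSE] - P1
  B3 <- points[idx4[4, ], , drop = FALSE] - P1
  d1 <- rowSums(B1^2); d2_ <- rowSums(B2^2); d3 <- rowSums(B3^2)
  # det of rows (B1; B2; B3)
  cx <- B2[, 2] * B3[, 3] - B2[, 3] * B3[, 2]
  cy <- B2[, 3] * B3[, 1] - B2[, 1] * B3[, 3]
  cz <- B2[, 1] * B3[, 2] - B2[, 2] * B3[, 1]
  det <- B1[, 1] * cx + B1[, 2] * cy + B1[, 3] * cz
  scale2 <- pmax(d1, d2_, d3)
  nondeg <- abs(det) > 1e-12 * scale2^1.5 + 1e-300
  # Cramer for y in (B1;B2;B3) y = (d1;d2;d3)/2, then center = P1 + t(B) y
  # solve via adjugate: y_i = det_i / det with column replacements; here
  # it is easier to solve for the center offset u with B u = d/2 where
  # B has ROWS B1,B2,B3: u = B^{-1} (d/2).
  e1x <- B2[, 2] * B3[, 3] - B2[, 3] * B3[, 2]
  e2x <- B1[, 3] * B3[, 2] - B1[, 2] * B3[, 3]
  e3x <- B1[, 2] * B2[, 3] - B1[, 3] * B2[, 2]
  e1y <- B2[, 3] * B3[, 1] - B2[, 1] * B3[, 3]
  e2y <- B1[, 1] * B3[, 3] - B1[, 3] * B3[, 1]
  e3y <- B1[, 3] * B2[, 1] - B1[, 1] * B2[, 3]
  e1z <- B2[, 1] * B3[, 2] - B2[, 2] * B3[, 1]
  e2z <- B1[, 2] * B3[, 1] - B1[, 1] * B3[, 2]
  e3z <- B1[, 1] * B2[, 2] - B1[, 2] * B2[, 1]
  h1 <- d1 / 2; h2 <- d2_ / 2; h3 <- d3 / 2
  ux <- (e1x * h1 + e2x * h2 + e3x * h3) / det
  uy <- (e1y * h1 + e2y * h2 + e3y * h3) / det
  uz <- (e1z * h1 + e2z * h2 + e3z * h3) / det
  r4 <- sqrt(ux^2 + uy^2 + uz^2)
  cand[nondeg, 5] <- r4[nondeg]
  apply(cand, 1, min)
}

# Enumerate the Cech filtration: all simplices of dimension 0..maxdim with
# their filtration values, sorted by (value, dimension).
cech_filtration <- function(points, maxdim = 3) {
  n <- nrow(points)
  maxdim <- min(maxdim, n - 1)
  verts <- lapply(seq_len(n), identity)
  vals <- rep(0, n)
  dims <- rep(0L, n)
  if (maxdim >= 1) {
    idx2 <- utils::combn(n, 2)
    v2 <- sqrt(rowSums((points[idx2[1, ], , drop = FALSE] -
                        points[idx2[2, ], , drop = FALSE])^2)) / 2
    verts <- c(verts, lapply(seq_len(ncol(idx2)), function(j) idx2[, j]))
    vals <- c(vals, v2)
    dims <- c(dims, rep(1L, ncol(idx2)))
  }
  if (maxdim >= 2) {
    idx3 <- utils::combn(n, 3)
    tri <- tri_meb(points, idx3)
    verts <- c(verts, lapply(seq_len(ncol(idx3)), function(j) idx3[, j]))
    vals <- c(vals, tri$r)
    dims <- c(dims, rep(2L, ncol(idx3)))
    if (maxdim >= 3) {
      idx4 <- utils::combn(n, 4)
      v4 <- tet_meb(points, idx4, tri$r, tri$center, n)
      verts <- c(verts, lapply(seq_len(ncol(idx4)), function(j) idx4[, j]))
      vals <- c(vals, v4)
      dims <- c(dims, rep(3L, ncol(idx4)))
    }
  }
  ord <- order(vals, dims)
  list(simplices = verts[ord], values = vals[ord], dims = dims[ord])
}

# Z/2 persistence pairing by column reduction.  Columns are stored as
# packed 30-bit words (no sign bit issues with R integers); the working
# column lives in a dense word buffer, reduced columns are kept sparse
# (word index + word value).  Pivot = highest set bit.
reduce_filtration <- function(filt) {
  ns <- length(filt$simplices)
  nw <- (ns + 29L) %/% 30L
  # facet lookup via exact numeric subset keys (vertex sets as bit sums;
  # exact in doubles for the small clouds handled here)
  keys <- vapply(filt$simplices, function(s) sum(2^(s - 1)), 0)
  sizes <- lengths(filt$simplices)
  facet_of <- vector("list", ns)
  for (j in which(sizes > 1)) {
    s <- filt$simplices[[j]]
    facet_of[[j]] <- match(keys[j] - 2^(s - 1), keys)
  }
  pivot_owner <- integer(ns)            # 0 = free
  stored_w <- vector("list", ns)
  stored_v <- vector("list", ns)
  pos_lo <- integer(0); pos_hi <- integer(0)   # pairs (birth idx, death idx)
  buffer <- integer(nw)
  for (j in seq_len(ns)) {
    fidx <- facet_of[[j]]
    if (is.null(fidx)) next             # vertices have empty boundary
    buffer[] <- 0L
    for (i in fidx) {
      w <- (i - 1L) %/% 30L + 1L
      buffer[w] <- bitwXor(buffer[w], bitwShiftL(1L, (i - 1L) %% 30L))
    }
    tw <- (max(fidx) - 1L) %/% 30L + 1L
    repeat {
      while (tw >= 1L && buffer[tw] == 0L) tw <- tw - 1L
      if (tw == 0L) break               # column emptied: j is positive
      low <- (tw - 1L) * 30L + as.integer(floor(log2(buffer[tw]) + 1e-9)) + 1L
      owner <- pivot_owner[low]
      if (owner == 0L) {
        pivot_owner[low] <- j
        pos_lo <- c(pos_lo, low); pos_hi <- c(pos_hi, j)
        wi <- which(buffer != 0L)
        stored_w[[j]] <- wi; stored_v[[j]] <- buffer[wi]
        break
      }
      buffer[stored_w[[owner]]] <- bitwXor(buffer[stored_w[[owner]]],
                                           stored_v[[owner]])
    }
  }
  pairs <- cbind(pos_lo, pos_hi, deparse.level = 0)
  paired <- c(pos_lo, pos_hi)
  essential <- setdiff(which(filt$dims < 3), paired)  # dim-3 positives ignored
  list(pairs = pairs, essential = essential)
}

new_diagram <- function(mat, q) {
  colnames(mat) <- c("birth", "death")
  structure(mat, dimension = as.integer(q), class = "persistence_diagram")
}

#' Persistence diagram accessor helpers
#'
#' @param x A `"persistence_diagram"` object (a two-column matrix of
#'   (birth, death) pairs with attribute `dimension`).
#' @param ... Ignored.
#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram, q = %d, %d pair(s)\n",
              attr(x, "dimension"), nrow(x)))
  if (nrow(x) > 0) print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Persistence diagrams of a motif cloud
#'
#' Computes the persistence diagrams in homology dimensions q = 0
#' (connected components), 1 (rings) and 2 (cavities) of the union of
#' growing balls centered at the cloud's points, via an exact Čech
#' filtration.  All values are on the ball-radius scale in nm: two points
#' at distance d merge at r = d/2.  Zero-persistence pairs are dropped;
#' the single essential connected component is reported as `(0, Inf)`.
#'
#' @param cloud A [motif_cloud()] object, or a plain n x 3 matrix of
#'   points (nm).
#' @return An object of class `"diagram_set"`: a list of three
#'   `"persistence_diagram"` matrices named `"0"`, `"1"`, `"2"`.
#' @examples
#' d <- compute_diagrams(rbind(c(0, 0, 0), c(0.1, 0, 0)))
#' d[["0"]]   # (0, 0.05) and (0, Inf)
#' @export
compute_diagrams <- function(cloud) {
  pts <- if (inherits(cloud, "motif_cloud")) cloud$points else as.matrix(cloud)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 1)
  if (nrow(pts) > 1 && min(stats::dist(pts)) < 1e-12)
    stop("duplicate points in cloud: persistence multiplicity undefined")
  filt <- cech_filtration(pts, maxdim = 3)
  red <- reduce_filtration(filt)
  dg <- lapply(0:2, function(q) {
    rows <- matrix(numeric(0), ncol = 2)
    if (nrow(red$pairs) > 0) {
      sel <- filt$dims[red$pairs[, 1]] == q
      if (any(sel)) {
        b <- filt$values[red$pairs[sel, 1]]
        d <- filt$values[red$pairs[sel, 2]]
        keep <- d - b > 1e-12
        rows <- cbind(b[keep], d[keep])
      }
    }
    ess <- red$essential[filt$dims[red$essential] == q]
    if (length(ess) > 0)
      rows <- rbind(rows, cbind(filt$values[ess], Inf))
    new_diagram(rows[order(rows[, 1], rows[, 2]), , drop = FALSE], q)
  })
  names(dg) <- as.character(0:2)
  structure(dg, class = "diagram_set")
}

#' @export
print.diagram_set <- function(x, ...) {
  for (q in names(x)) print(x[[q]])
  invisible(x)
}

#' Distinct (birth, death) values of a diagram
#'
#' Deduplicates a diagram's pairs to tolerance `tol`, for comparison with
#' analytically derived value lists (which omit multiplicities).
#'
#' @param diagram A `"persistence_diagram"` object.
#' @param tol Absolute tolerance for considering two pairs equal.
#' @return A two-column matrix of distinct (birth, death) values, sorted.
#' @export
distinct_pairs <- function(diagram, tol = 1e-9) {
  m <- unclass(diagram)
  if (nrow(m) == 0) return(m)
  # quantize to the tolerance grid so near-identical values sort together
  kb <- round(m[, 1] / tol)
  kd <- round(m[, 2] / tol)              # Inf stays Inf
  ord <- order(kb, kd)
  m <- m[ord, , drop = FALSE]
  db <- diff(kb[ord]); dd <- diff(kd[ord])
  keep <- c(TRUE, !(db == 0 & (dd == 0 | is.nan(dd))))   # Inf-Inf = NaN
  m[keep, , drop = FALSE]
}
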