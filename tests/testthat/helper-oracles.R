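# Independent oracles used across the test suite.  Each implements the
# quantity under test by a different algorithm than the package:
# minimum enclosing balls by support-subset enumeration, bottleneck
# distance by exhaustive matching enumeration, and Betti numbers by
# GF(2) Gaussian elimination on fixed-scale boundary matrices.

# MEB radius of m <= 4 points by enumerating support subsets: the MEB is
# the smallest circumball (center in the subset's affine hull) of some
# subset of size 2..4 that encloses all points.
meb_oracle <- function(P) {
  m <- nrow(P)
  if (m == 1) return(0)
  if (m == 2) return(sqrt(sum((P[1, ] - P[2, ])^2)) / 2)
  best <- Inf
  for (k in 2:m) {
    idx <- utils::combn(m, k)
    for (j in seq_len(ncol(idx))) {
      S <- P[idx[, j], , drop = FALSE]
      B <- sweep(S[-1, , drop = FALSE], 2, S[1, ])
      G <- B %*% t(B)
      y <- tryCatch(solve(2 * G, rowSums(B^2)), error = function(e) NULL)
      if (is.null(y)) next
      ctr <- S[1, ] + drop(t(B) %*% y)
      r <- sqrt(sum((ctr - S[1, ])^2))
      if (r < best &&
          max(rowSums(sweep(P, 2, ctr)^2)) <= (r * (1 + 1e-9))^2 + 1e-18)
        best <- r
    }
  }
  best
}

# Bottleneck distance by exhaustive enumeration of partial matchings
# (every X point matched to an unused Y point or deleted to the
# diagonal; leftover Y points deleted).  Exponential; use only on
# diagrams with few off-diagonal points.
bottleneck_oracle <- function(X, Y) {
  X <- matrix(as.numeric(unclass(X)), ncol = 2)
  Y <- matrix(as.numeric(unclass(Y)), ncol = 2)
  infx <- is.infinite(X[, 2]); infy <- is.infinite(Y[, 2])
  if (sum(infx) != sum(infy)) return(Inf)
  d_inf <- if (any(infx)) max(abs(sort(X[infx, 1]) - sort(Y[infy, 1]))) else 0
  Xf <- X[!infx, , drop = FALSE]; Yf <- Y[!infy, , drop = FALSE]
  m <- nrow(Xf); n <- nrow(Yf)
  best <- Inf
  rec <- function(i, used, cur) {
    if (cur >= best) return(invisible())
    if (i > m) {
      rest <- if (n > 0) ((Yf[, 2] - Yf[, 1]) / 2)[!used] else numeric(0)
      tot <- max(c(cur, rest, 0))
      if (tot < best) best <<- tot
      return(invisible())
    }
    rec(i + 1, used, max(cur, (Xf[i, 2] - Xf[i, 1]) / 2))
    if (n > 0) for (jj in which(!used)) {
      cost <- max(abs(Xf[i, 1] - Yf[jj, 1]), abs(Xf[i, 2] - Yf[jj, 2]))
      used[jj] <- TRUE
      rec(i + 1, used, max(cur, cost))
      used[jj] <- FALSE
    }
  }
  rec(1, rep(FALSE, n), 0)
  max(best, d_inf)
}

# random diagram with k finite pairs and optionally one essential class
random_diagram <- function(k, q = 0, essential = FALSE) {
  b <- stats::runif(k, 0, 1)
  d <- b + stats::runif(k, 0.02, 1)
  m <- cbind(b, d)
  if (essential) m <- rbind(m, c(stats::runif(1, 0, 0.3), Inf))
  structure(m, dimension = as.integer(q), class = "persistence_diagram",
            dimnames = list(NULL, c("birth", "death")))
}

# rank of a 0/1 matrix over GF(2) by Gaussian elimination
gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2 != 0
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col])
    piv <- piv[piv > r]
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    hit <- which(M[, col]); hit <- hit[hit != r]
    if (length(hit) > 0)
      M[hit, ] <- M[hit, , drop = FALSE] != matrix(M[r, ], length(hit),
                                                   ncol(M), byrow = TRUE)
    if (r == nrow(M)) break
  }
  r
}

# Betti numbers (q = 0, 1, 2) of the Cech complex at a fixed radius,
# from boundary-matrix ranks: beta_q = n_q - rank d_q - rank d_{q+1}
betti_at_radius <- function(points, r) {
  filt <- ellipack:::cech_filtration(points, maxdim = 3)
  keep <- which(filt$values <= r + 1e-12)
  simp <- filt$simplices[keep]
  dims <- filt$dims[keep]
  by_dim <- lapply(0:3, function(d) simp[dims == d])
  keyify <- function(ss) vapply(ss, function(s) paste(sort(s), collapse = ","), "")
  ranks <- c(0, vapply(1:3, function(d) {
    hi <- by_dim[[d + 1]]
    lo_keys <- keyify(by_dim[[d]])
    if (length(hi) == 0 || length(lo_keys) == 0) return(0L)
    B <- matrix(0L, length(lo_keys), length(hi))
    for (j in seq_along(hi)) {
      s <- hi[[j]]
      faces <- vapply(seq_along(s),
                      function(k) paste(sort(s[-k]), collapse = ","), "")
      B[match(faces, lo_keys), j] <- 1L
    }
    gf2_rank(B)
  }, 0L))
  vapply(0:2, function(q)
    length(by_dim[[q + 1]]) - ranks[q + 1] - ranks[q + 2], 0)
}

# Betti numbers at radius r implied by a diagram set (alive = born at or
# before r, not yet dead); zero-persistence pairs never count
betti_from_diagrams <- function(dg, r) {
  vapply(0:2, function(q) {
    m <- unclass(dg[[as.character(q)]])
    if (nrow(m) == 0) return(0)
    sum(m[, 1] <= r + 1e-12 & m[, 2] > r + 1e-12)
  }, 0)
}

# exact analytic bulk-lattice diagram values (distinct pairs, cube side
# alpha): derived from sphere-covering geometry of each lattice
analytic_bulk_values <- function(type, a = 0.1) {
  switch(type,
    P = list(`0` = rbind(c(0, a / 2), c(0, Inf)),
             `1` = rbind(c(a / 2, a / sqrt(2))),
             `2` = rbind(c(a / sqrt(2), sqrt(3) * a / 2))),
    C = list(`0` = rbind(c(0, sqrt(2) * a / 4), c(0, a / 2), c(0, Inf)),
             `1` = rbind(c(sqrt(2) * a / 4, a / 2),
                         c(a / 2, sqrt(3) * a / (2 * sqrt(2)))),
             `2` = rbind(c(sqrt(3) * a / (2 * sqrt(2)), a / sqrt(2)))),
    I = list(`0` = rbind(c(0, sqrt(3) * a / 4), c(0, Inf)),
             `1` = rbind(c(sqrt(3) * a / 4, 3 * a / (4 * sqrt(2))),
                         c(a / 2, 3 * a / (4 * sqrt(2)))),
             `2` = rbind(c(3 * a / (4 * sqrt(2)), sqrt(5) * a / 4))),
    F = list(`0` = rbind(c(0, sqrt(2) * a / 4), c(0, Inf)),
             `1` = rbind(c(sqrt(2) * a / 4, a / sqrt(6))),
             `2` = rbind(c(a / sqrt(6), sqrt(3) * a / 4),
                         c(a / sqrt(6), a / 2))))
}
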