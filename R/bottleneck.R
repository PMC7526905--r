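## Bottleneck distance between persistence diagrams.
##
## The distance is the smallest t such that there is a partial matching of
## the two diagrams in which every matched pair is within L-infinity
## distance t and every unmatched point is within t of the diagonal (its
## deletion cost is (death - birth)/2).  Points with infinite death
## (essential classes) must be matched to each other: if the two diagrams
## carry different numbers of them the distance is +Inf, otherwise they are
## matched in birth order and contribute |birth_X - birth_Y|.
##
## Computed exactly: the optimum is attained at one of finitely many
## candidate costs (pairwise L-inf costs and deletion costs); binary
## search over the sorted candidates with a bipartite perfect-matching
## feasibility test (the standard diagram-plus-diagonal-copies graph).

# maximum bipartite matching (Kuhn's algorithm); adj = list over left
# vertices of integer vectors of right neighbours
max_bipartite_matching <- function(adj, n_right) {
  match_r <- integer(n_right)            # 0 = unmatched
  seen <- logical(n_right)
  dfs <- function(u) {
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <<- TRUE
      if (match_r[v] == 0L || dfs(match_r[v])) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(adj)) {
    seen[] <- FALSE
    if (dfs(u)) size <- size + 1L
  }
  size
}

#' Bottleneck distance between two persistence diagrams
#'
#' @param X,Y `"persistence_diagram"` objects (two-column (birth, death)
#'   matrices) of the same homology dimension, or plain matrices.
#' @return The bottleneck distance in nm; `Inf` if the diagrams carry
#'   different numbers of essential (infinite-death) classes.
#' @examples
#' X <- rbind(c(0, 1)); Y <- rbind(c(0, 4))
#' bottleneck_distance(X, Y)   # 2: deleting both beats matching (cost 3)
#' @export
bottleneck_distance <- function(X, Y) {
  qx <- attr(X, "dimension"); qy <- attr(Y, "dimension")
  if (!is.null(qx) && !is.null(qy) && qx != qy)
    stop("diagrams have different homology dimensions (q = ",
         qx, " vs q = ", qy, ")")
  X <- matrix(as.numeric(unclass(X)), ncol = 2)
  Y <- matrix(as.numeric(unclass(Y)), ncol = 2)
  infx <- is.infinite(X[, 2]); infy <- is.infinite(Y[, 2])
  if (sum(infx) != sum(infy)) return(Inf)
  d_inf <- 0
  if (any(infx)) {
    bx <- sort(X[infx, 1]); by <- sort(Y[infy, 1])
    d_inf <- max(abs(bx - by))
  }
  Xf <- X[!infx, , drop = FALSE]; Yf <- Y[!infy, , drop = FALSE]
  m <- nrow(Xf); n <- nrow(Yf)
  if (m == 0 && n == 0) return(d_inf)
  delx <- (Xf[, 2] - Xf[, 1]) / 2
  dely <- (Yf[, 2] - Yf[, 1]) / 2
  cost <- matrix(0, m, n)
  if (m > 0 && n > 0)
    for (i in seq_len(m))
      cost[i, ] <- pmax(abs(Xf[i, 1] - Yf[, 1]), abs(Xf[i, 2] - Yf[, 2]))
  cand <- sort(unique(c(0, delx, dely, cost)))
  feasible <- function(t) {
    # left: m diagram-X points then n diagonal copies (for Y)
    # right: n diagram-Y points then m diagonal copies (for X)
    adj <- vector("list", m + n)
    for (i in seq_len(m)) {
      nb <- if (n > 0) which(cost[i, ] <= t) else integer(0)
      if (delx[i] <= t) nb <- c(nb, n + i)
      adj[[i]] <- nb
    }
    for (j in seq_len(n)) {
      nb <- seq_len(m) + n          # diagonal matches diagonal freely
      if (dely[j] <= t) nb <- c(j, nb)
      adj[[m + j]] <- nb
    }
    max_bipartite_matching(adj, m + n) == m + n
  }
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  max(cand[lo], d_inf)
}
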