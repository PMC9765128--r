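## Dense bounded-variable linear programming.
##
## FBA problems here are small (tens to hundreds of reactions), dense-ish
## and frequently degenerate, so the solver favours robustness over speed:
## a two-phase primal simplex on bounded variables with Bland's rule
## (anti-cycling) and a full QR refactorization of the basis at every
## iteration, so the basic solution is always recomputed from scratch and
## rounding never accumulates.

#' Solve `max/min c'x` subject to `A x = b`, `lb <= x <= ub`
#'
#' @param A Constraint matrix (m x n), dense.
#' @param b Right-hand side (length m).
#' @param obj Objective coefficients (length n).
#' @param lb,ub Finite variable bounds.
#' @param maximize Direction; `TRUE` maximizes.
#' @param tol Pivot/feasibility tolerance.
#' @param max_iter Simplex iteration cap across both phases.
#' @return List with `status` (`"optimal"`, `"infeasible"`,
#'   `"iteration_limit"`, `"singular_basis"`), and for optimal solutions
#'   `x` and `obj` (objective value in the requested direction).
#' @export
lp_solve <- function(A, b, obj, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n,
            length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  cc0 <- if (maximize) obj else -obj

  resid <- b - as.vector(A %*% lb)
  sgn <- ifelse(resid >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, nrow = m))
  N <- n + m
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  at_ub <- rep(FALSE, N)
  bas <- n + seq_len(m)
  phase <- 1L
  cc <- c(rep(0, n), rep(-1, m))
  allow <- rep(TRUE, N)

  for (it in seq_len(max_iter)) {
    nonbas <- setdiff(seq_len(N), bas)
    xN <- ifelse(at_ub[nonbas], uball[nonbas], lball[nonbas])
    B <- Aall[, bas, drop = FALSE]
    qB <- qr(B)
    if (qB$rank < m) return(list(status = "singular_basis"))
    xB <- as.vector(qr.coef(qB, b - Aall[, nonbas, drop = FALSE] %*% xN))
    y <- qr.coef(qr(t(B)), cc[bas])
    cand <- nonbas[allow[nonbas]]
    d <- cc[cand] - as.vector(crossprod(Aall[, cand, drop = FALSE], y))
    good <- (!at_ub[cand] & d > tol) | (at_ub[cand] & d < -tol)
    if (!any(good)) {
      if (phase == 1L) {
        if (sum(abs(xB[bas > n])) > 1e-7) return(list(status = "infeasible"))
        phase <- 2L
        cc <- c(cc0, rep(0, m))
        uball[n + seq_len(m)] <- 0           # artificials pinned at zero
        allow[n + seq_len(m)] <- FALSE
        next
      }
      x <- numeric(N); x[bas] <- xB; x[nonbas] <- xN
      xx <- pmin(pmax(x[seq_len(n)], lb), ub)
      val <- sum(cc0 * xx)
      return(list(status = "optimal", x = xx,
                  obj = if (maximize) val else -val, iterations = it))
    }
    j <- min(cand[good])                      # Bland: lowest-index entering
    dirj <- if (at_ub[j]) -1 else 1
    w <- as.vector(qr.coef(qB, Aall[, j]))
    dB <- -w * dirj
    t_flip <- uball[j] - lball[j]
    ts <- rep(Inf, m); toub <- rep(FALSE, m)
    dec <- dB < -tol
    inc <- dB > tol & is.finite(uball[bas])
    ts[dec] <- (xB[dec] - lball[bas[dec]]) / (-dB[dec])
    ts[inc] <- (uball[bas[inc]] - xB[inc]) / dB[inc]
    toub[inc] <- TRUE
    tmin <- max(min(ts, t_flip), 0)
    if (!is.finite(tmin)) return(list(status = "unbounded"))
    elig <- which(ts <= tmin + tol)
    if (length(elig) == 0L) {                 # entering hits its other bound
      at_ub[j] <- !at_ub[j]
      next
    }
    leave <- elig[which.min(bas[elig])]       # Bland: lowest-index leaving
    at_ub[bas[leave]] <- toub[leave]
    bas[leave] <- j
  }
  list(status = "iteration_limit")
}

## Enumerate all vertices of {v : S v = d, lb <= v <= ub} by exhausting
## bases: for each column subset of size rank(S) with independent columns,
## try every assignment of the remaining variables to a bound and keep the
## consistent, in-bound solutions. Exponential; intended as an independent
## reference for networks of a dozen or so reactions.

#' Brute-force vertex enumeration of a flux polytope
#'
#' An independent reference for [solve_fba()] and [flux_variability()]:
#' every vertex of the steady-state polytope is constructed by basis
#' enumeration, so the optimum and the optimal-face flux ranges follow by
#' direct inspection, without linear programming.
#'
#' @param S Stoichiometric matrix (dense or sparse).
#' @param lb,ub Finite flux bounds.
#' @param d Right-hand side (defaults to the steady-state zero vector).
#' @param tol Consistency/bound tolerance.
#' @return Matrix with one row per distinct vertex.
#' @export
enumerate_vertices <- function(S, lb, ub, d = NULL, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(d)) d <- rep(0, nrow(S))
  r <- qr(S)$rank
  verts <- list()
  for (Bidx in utils::combn(n, r, simplify = FALSE)) {
    SB <- S[, Bidx, drop = FALSE]
    qb <- qr(SB)
    if (qb$rank < r) next
    Nidx <- setdiff(seq_len(n), Bidx)
    k <- length(Nidx)
    grid <- if (k > 0)
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    else matrix(FALSE, 1, 0)
    VN <- matrix(rep(lb[Nidx], nrow(grid)), ncol = nrow(grid))
    UBm <- matrix(rep(ub[Nidx], nrow(grid)), ncol = nrow(grid))
    if (k > 0) VN[t(grid)] <- UBm[t(grid)]
    RHS <- d - S[, Nidx, drop = FALSE] %*% VN
    VB <- qr.coef(qb, RHS)
    resid <- SB %*% VB - RHS
    ok <- colSums(abs(resid)) < tol * (1 + colSums(abs(RHS)))
    ok <- ok & apply(VB >= lb[Bidx] - tol & VB <= ub[Bidx] + tol, 2, all)
    for (i in which(ok)) {
      v <- numeric(n); v[Bidx] <- VB[, i]; v[Nidx] <- VN[, i]
      verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

#' Random small flux network for solver validation
#'
#' Draws a random stoichiometric matrix with 3-5 metabolites and 7-10
#' reactions (small integer coefficients, full row rank), random finite
#' bounds that keep the zero flux vector feasible, and a random sparse
#' objective. Small enough for [enumerate_vertices()] to be exhaustive.
#'
#' @param seed Integer seed.
#' @return List with `S`, `lb`, `ub`, `obj`.
#' @export
random_flux_network <- function(seed) {
  set.seed(seed)
  m <- sample(3:5, 1)
  n <- sample(7:10, 1)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      k <- sample(1:2, 1)
      rows <- sample(m, min(k + 1, m))
      S[rows[1], j] <- -sample(1:2, 1)
      for (rr in rows[-1]) S[rr, j] <- sample(1:2, 1)
    }
    if (qr(S)$rank == m) break
  }
  lb <- ifelse(stats::runif(n) < 0.3, -stats::runif(n, 1, 10), 0)
  ub <- stats::runif(n, 1, 10)
  obj <- numeric(n)
  obj[sample(n, sample(1:2, 1))] <- 1
  list(S = S, lb = lb, ub = ub, obj = obj)
}
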