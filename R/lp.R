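#' Solve a box-constrained linear program with equality constraints
#'
#' Solves `max/min obj'v` subject to `A v = b` and `lb <= v <= ub` with a
#' dense two-phase bounded-variable primal simplex. Bland's smallest-index
#' rule is used throughout, so the method cannot cycle on the degenerate
#' vertices that flux-variability objectives routinely produce.
#'
#' This is the single optimization primitive behind [fba()], [fva()] and
#' [gimme_reduce()]. Problem sizes in this package are those of curated core
#' networks (tens of reactions), for which a dense tableau is both fast and
#' numerically transparent.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A dense constraint matrix (rows = equality constraints).
#' @param b right-hand side, length `nrow(A)`.
#' @param lb,ub finite lower/upper variable bounds (`lb <= ub`).
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot tolerance.
#' @param maxit iteration cap per phase.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"maxit"`), and for optimal solves `v` (solution vector, named after
#'   `colnames(A)`) and `value` (objective value).
#' @export
#' @examples
#' # max x + y  s.t.  x - y = 0, 0 <= x,y <= 2
#' lp_solve(c(1, 1), matrix(c(1, -1), 1), 0, c(0, 0), c(2, 2))$value  # 4
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, maxit = 20000L) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(b) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub + tol)) {
    stop("lp_solve: lower bound exceeds upper bound for variable(s) ",
         paste(which(lb > ub + tol), collapse = ", "))
  }
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve: bounds must be finite; cap unconstrained directions")
  }
  # drop linearly dependent equality rows (common with redundant metabolites)
  qt <- qr(t(A))
  if (qt$rank < nrow(A)) {
    keep <- qt$pivot[seq_len(qt$rank)]
    # consistency of dropped rows is implied when b lies in the row space;
    # for S v = 0 problems b is always consistent by construction
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  }
  # shift to 0 <= x <= u
  u <- ub - lb
  bshift <- as.vector(b - A %*% lb)
  cc <- if (maximize) -obj else obj
  res <- .simplex_box(cc, A, bshift, u, tol = tol, maxit = maxit)
  if (res$status != "optimal") return(list(status = res$status))
  v <- res$x + lb
  names(v) <- colnames(A)
  list(status = "optimal", v = v, value = sum(obj * v))
}

# min c'x  s.t.  A x = b, 0 <= x <= u  (u may be Inf). Two-phase, Bland.
.simplex_box <- function(c_, A, b, u, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # pure box problem: each variable sits at the bound favoured by its cost
    x <- ifelse(c_ < 0, u, 0)
    if (any(c_ < -tol & !is.finite(u))) return(list(status = "unbounded"))
    return(list(status = "optimal", x = x))
  }
  sgn <- ifelse(b >= 0, 1, -1)
  A1 <- cbind(A, diag(sgn, m, m))
  uu <- c(u, rep(Inf, m))
  run <- function(cc, basis, at_upper, uu) {
    N <- n + m
    for (it in seq_len(maxit)) {
      nb <- setdiff(seq_len(N), basis)
      Binv <- tryCatch(solve(A1[, basis, drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      xN <- ifelse(at_upper[nb], uu[nb], 0)
      xB <- as.vector(Binv %*% (b - A1[, nb, drop = FALSE] %*% xN))
      y <- as.vector(crossprod(Binv, cc[basis]))
      d <- cc[nb] - as.vector(crossprod(A1[, nb, drop = FALSE], y))
      elig <- (!at_upper[nb] & d < -tol) | (at_upper[nb] & d > tol)
      if (!any(elig)) {
        x <- numeric(N); x[basis] <- xB; x[nb] <- xN
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      }
      j <- min(nb[elig])                        # Bland: smallest index enters
      dirj <- if (at_upper[j]) -1 else 1
      w <- as.vector(Binv %*% A1[, j]) * dirj   # xB moves by -w * t
      rmin <- Inf; leave <- 0L
      for (i in seq_len(m)) {
        r <- Inf
        if (w[i] > tol) {
          r <- max(xB[i], 0) / w[i]
        } else if (w[i] < -tol && is.finite(uu[basis[i]])) {
          r <- max(uu[basis[i]] - xB[i], 0) / (-w[i])
        }
        if (r < rmin - tol ||
            (r < rmin + tol && is.finite(r) &&
             (leave == 0L || basis[i] < basis[leave]))) {
          rmin <- min(rmin, r); leave <- i
        }
      }
      tstep <- min(uu[j], rmin)
      if (!is.finite(tstep)) return(list(status = "unbounded"))
      if (is.finite(uu[j]) && uu[j] <= rmin) {  # bound flip, basis unchanged
        at_upper[j] <- !at_upper[j]
        next
      }
      at_upper[basis[leave]] <- w[leave] < 0    # leaves at its upper bound
      at_upper[j] <- FALSE
      basis[leave] <- j
    }
    list(status = "maxit")
  }
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)
  c1 <- c(rep(0, n), rep(1, m))
  r1 <- run(c1, basis, at_upper, uu)
  if (r1$status != "optimal") {
    return(list(status = if (r1$status == "unbounded") "infeasible"
                else r1$status))
  }
  if (sum(c1 * r1$x) > 1e-7) return(list(status = "infeasible"))
  uu[n + seq_len(m)] <- 0                        # lock artificials at zero
  c2 <- c(c_, rep(0, m))
  r2 <- run(c2, r1$basis, r1$at_upper, uu)
  if (r2$status != "optimal") return(list(status = r2$status))
  list(status = "optimal", x = r2$x[seq_len(n)],
       value = sum(c_ * r2$x[seq_len(n)]))
}
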