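# Two-phase bounded-variable primal simplex.
#
# Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
# with finite lower bounds and possibly infinite upper bounds.  Problems in
# this package are tiny (tens of variables, tens of rows), so the basis
# inverse is applied by dense solve() at every iteration; robustness and
# determinism matter far more than speed here.  Bland's smallest-index rule
# is used throughout, which guarantees finite termination under degeneracy.

# Internal state of a simplex run: basis (variable index per row) and vstat
# (per-variable: 0 nonbasic at lower, 1 nonbasic at upper, 2 basic).

.simplex_xvec <- function(A, b, lb, ub, basis, vstat) {
  n <- ncol(A)
  x <- numeric(n)
  at_lb <- which(vstat == 0L)
  at_ub <- which(vstat == 1L)
  x[at_lb] <- lb[at_lb]
  x[at_ub] <- ub[at_ub]
  rhs <- b - A[, -basis, drop = FALSE] %*% x[-basis]
  B <- A[, basis, drop = FALSE]
  xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(xb)) return(NULL)
  # one step of iterative refinement keeps the basic values accurate to
  # ~1e-14 relative, which the infeasibility test below relies on
  r <- rhs - B %*% xb
  xb <- xb + tryCatch(solve(B, r), error = function(e) 0)
  x[basis] <- as.vector(xb)
  x
}

# One phase of the simplex from a given (basis, vstat).  Returns status
# "optimal" / "unbounded" / "error" plus the final state.
.simplex_iterate <- function(A, b, cvec, lb, ub, basis, vstat,
                             tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  ctol <- tol * (1 + max(abs(cvec)))
  fixed <- (ub - lb) <= 0          # zero-range variables never enter
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "error", basis = basis, vstat = vstat))
    }
    B <- A[, basis, drop = FALSE]
    x <- .simplex_xvec(A, b, lb, ub, basis, vstat)
    if (is.null(x)) return(list(status = "error", basis = basis, vstat = vstat))
    y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "error", basis = basis, vstat = vstat))
    d <- cvec - as.vector(crossprod(A, y))
    enter_lb <- which(vstat == 0L & !fixed & d < -ctol)
    enter_ub <- which(vstat == 1L & !fixed & d > ctol)
    cand <- c(enter_lb, enter_ub)
    if (length(cand) == 0L) {
      return(list(status = "optimal", basis = basis, vstat = vstat, x = x))
    }
    e <- min(cand)                              # Bland
    tdir <- if (vstat[e] == 0L) 1 else -1       # increase from lb / decrease from ub
    w <- as.vector(solve(B, A[, e]))
    # basic variables move by -theta * tdir * w; pivot eligibility is
    # relative to the column magnitude so that cancellation noise in
    # B^{-1} A_e (machine eps times the largest entry) never gets picked
    ptol <- 1e-9 * max(abs(w), 1)
    step <- tdir * w
    theta <- if (is.finite(ub[e]) ) ub[e] - lb[e] else Inf
    leave_row <- 0L                             # 0 => bound flip of entering var
    leave_to <- NA_integer_
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (step[i] > ptol) {
        lim <- (x[bi] - lb[bi]) / step[i]
        if (lim < theta - ptol ||
            (lim < theta + ptol && leave_row > 0L && bi < basis[leave_row])) {
          theta <- max(lim, 0)
          leave_row <- i
          leave_to <- 0L
        }
      } else if (step[i] < -ptol && is.finite(ub[bi])) {
        lim <- (ub[bi] - x[bi]) / (-step[i])
        if (lim < theta - ptol ||
            (lim < theta + ptol && leave_row > 0L && bi < basis[leave_row])) {
          theta <- max(lim, 0)
          leave_row <- i
          leave_to <- 1L
        }
      }
    }
    if (!is.finite(theta)) {
      return(list(status = "unbounded", basis = basis, vstat = vstat))
    }
    if (leave_row == 0L) {
      # entering variable runs to its opposite bound
      vstat[e] <- if (vstat[e] == 0L) 1L else 0L
    } else {
      lv <- basis[leave_row]
      vstat[lv] <- leave_to
      vstat[e] <- 2L
      basis[leave_row] <- e
    }
  }
}

#' @noRd
# Full two-phase solve.  Returns list(status, x, objective, basis, vstat,
# nart) where x/objective are only present for status "optimal".
# When `warm` (a list with basis/vstat from a previous solve of the *same*
# constraint system) is given, phase I is skipped.
.lp_solve <- function(A, b, cvec, lb, ub, maximize = FALSE,
                      warm = NULL, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n,
            length(lb) == n, length(ub) == n, all(lb <= ub + 1e-12))
  # equilibrate rows: scaling by max(|coefficients|, |rhs|) makes every
  # nonzero right-hand side O(1), so phase-I infeasibility is always
  # detected relative to the row's own magnitude (essential when rate
  # coefficients span many orders of magnitude within one column)
  rsc <- pmax(apply(abs(A), 1, max), abs(b), 1e-12)
  As <- A / rsc
  bs <- b / rsc
  # artificial columns
  Ae <- cbind(As, diag(ifelse(bs >= 0, 1, -1), m))
  art <- n + seq_len(m)
  lbe <- c(lb, rep(0, m))
  obj_min <- if (maximize) -cvec else cvec

  if (is.null(warm)) {
    # phase I from x = lb
    r0 <- bs - As %*% lb
    ube <- c(ub, rep(Inf, m))
    basis <- art
    vstat <- c(rep(0L, n), rep(2L, m))
    # artificial signs must match residual at x = lb, not at x = 0
    sgn <- ifelse(as.vector(r0) >= 0, 1, -1)
    Ae[, art] <- diag(sgn, m)
    c1 <- c(rep(0, n), rep(1, m))
    ph1 <- .simplex_iterate(Ae, bs, c1, lbe, ube, basis, vstat, tol = tol)
    if (ph1$status != "optimal") {
      return(list(status = if (ph1$status == "error") "error" else "error"))
    }
    # rows are equilibrated (|coefficients| and |rhs| at most 1), so the
    # phase-I optimum of an infeasible system is bounded below by the data's
    # smallest relative rate ratio (>= ~1e-9 for rate spans up to 1e8),
    # while solver noise stays below ~1e-12 thanks to refinement
    infeas <- sum(ph1$x[art])
    if (infeas > 1e-10 * (1 + max(abs(bs)))) {
      return(list(status = "infeasible", infeasibility = infeas))
    }
    basis <- ph1$basis
    vstat <- ph1$vstat
  } else {
    sgn <- warm$sgn
    Ae[, art] <- diag(sgn, m)
    basis <- warm$basis
    vstat <- warm$vstat
  }
  # phase II: artificials pinned to zero
  ube2 <- c(ub, rep(0, m))
  c2 <- c(obj_min, rep(0, m))
  ph2 <- .simplex_iterate(Ae, bs, c2, lbe, ube2, basis, vstat, tol = tol)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "error"))
  x <- ph2$x[seq_len(n)]
  # clamp solver noise onto bounds
  x <- pmin(pmax(x, lb), ifelse(is.finite(ub), ub, x))
  obj <- sum(cvec * x)
  sgn_out <- if (is.null(warm)) sgn else warm$sgn
  list(status = "optimal", x = x, objective = obj,
       basis = ph2$basis, vstat = ph2$vstat, sgn = sgn_out)
}
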