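#' Build a linear or mixed-integer linear program
#'
#' A minimal, solver-agnostic container for the optimization problems used by
#' the realization algorithms: a linear objective, equality constraints
#' `A_eq x = rhs`, per-variable bounds, and optional integrality flags.
#' Inequality constraints are expressed by the caller through slack variables,
#' which keeps the solver core small and easy to verify.
#'
#' @param objective numeric vector of objective coefficients.
#' @param A_eq numeric matrix of equality-constraint coefficients
#'   (one row per constraint).
#' @param rhs numeric right-hand side, one entry per row of `A_eq`.
#' @param lower,upper numeric vectors of variable bounds. `lower` must be
#'   finite; entries of `upper` may be `Inf`. Defaults: `0` and `Inf`.
#' @param integer logical vector flagging integer-constrained variables
#'   (default: none).
#' @param maximize if `TRUE` the objective is maximized.
#' @return an object of class `linear_program`.
#' @seealso [solve.linear_program()], [check_feasibility()]
#' @export
#' @examples
#' lp <- linear_program(c(1, 0), matrix(c(1, 1), 1), 5, maximize = TRUE)
#' solve(lp)$objective_value
linear_program <- function(objective, A_eq, rhs,
                           lower = NULL, upper = NULL,
                           integer = NULL, maximize = FALSE) {
  A_eq <- as.matrix(A_eq)
  n <- ncol(A_eq)
  if (length(objective) != n) stop("objective length does not match A_eq")
  if (length(rhs) != nrow(A_eq)) stop("rhs length does not match A_eq")
  lower <- if (is.null(lower)) rep(0, n) else rep_len(lower, n)
  upper <- if (is.null(upper)) rep(Inf, n) else rep_len(upper, n)
  integer <- if (is.null(integer)) rep(FALSE, n) else rep_len(integer, n)
  if (any(!is.finite(lower))) stop("lower bounds must be finite")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  structure(
    list(objective = as.numeric(objective), A_eq = A_eq, rhs = as.numeric(rhs),
         lower = as.numeric(lower), upper = as.numeric(upper),
         integer = as.logical(integer), maximize = isTRUE(maximize)),
    class = "linear_program")
}

#' @export
print.linear_program <- function(x, ...) {
  kind <- if (any(x$integer)) "mixed-integer linear program" else "linear program"
  cat(sprintf("<%s: %d variables (%d integer), %d equality constraints, %s>\n",
              kind, ncol(x$A_eq), sum(x$integer), nrow(x$A_eq),
              if (x$maximize) "maximize" else "minimize"))
  invisible(x)
}

#' Solve a linear or mixed-integer linear program
#'
#' Linear programs are solved by a deterministic two-phase bounded-variable
#' primal simplex (Bland's rule); integer-constrained programs by depth-first
#' branch and bound on the LP relaxation, branching on the most fractional
#' variable with the down-branch explored first. Identical input always
#' yields an identical result.
#'
#' @param a a [linear_program()].
#' @param b unused (signature of the `solve` generic).
#' @param ... unused.
#' @return a list of class `solve_result` with elements `status` (one of
#'   `"optimal"`, `"infeasible"`, `"unbounded"`, `"error"`), `values`
#'   (the variable assignment, present only when optimal) and
#'   `objective_value`.
#' @export
solve.linear_program <- function(a, b, ...) {
  p <- a
  if (any(p$integer)) {
    res <- .milp_solve(p)
  } else {
    r <- .lp_solve(p$A_eq, p$rhs, p$objective, p$lower, p$upper,
                   maximize = p$maximize)
    res <- list(status = r$status,
                values = if (r$status == "optimal") r$x else NULL,
                objective_value = if (r$status == "optimal") r$objective else NA_real_)
  }
  structure(res, class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result: %s", x$status))
  if (identical(x$status, "optimal")) {
    cat(sprintf(", objective %.6g", x$objective_value))
  }
  cat(">\n")
  invisible(x)
}

#' Check feasibility of an equality-constrained system
#'
#' Solves the program with a zero objective and reports whether an assignment
#' satisfying all constraints and bounds exists. This is the primitive behind
#' the core-reaction test: a reaction is core precisely when the realization
#' constraint system with that reaction's rate pinned to zero is infeasible.
#'
#' @param p a [linear_program()]; its objective is ignored.
#' @return `TRUE` if feasible, `FALSE` if infeasible.
#'   Solver failure raises an error rather than returning a silent answer.
#' @export
check_feasibility <- function(p) {
  stopifnot(inherits(p, "linear_program"))
  p$objective <- numeric(ncol(p$A_eq))
  p$maximize <- FALSE
  p$integer <- rep(FALSE, ncol(p$A_eq))
  r <- solve(p)
  if (r$status == "optimal") return(TRUE)
  if (r$status == "infeasible") return(FALSE)
  stop("solver failure while checking feasibility (status: ", r$status, ")")
}

# Depth-first branch and bound for small MILPs (tens of binaries at most).
.milp_solve <- function(p, int_tol = 1e-6) {
  obj_min <- if (p$maximize) -p$objective else p$objective
  best <- NULL
  best_obj <- Inf
  # node: list(lower, upper)
  stack <- list(list(lower = p$lower, upper = p$upper))
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- .lp_solve(p$A_eq, p$rhs, obj_min, node$lower, node$upper,
                   maximize = FALSE)
    if (r$status == "infeasible") next
    if (r$status == "unbounded") return(list(status = "unbounded"))
    if (r$status != "optimal") return(list(status = "error"))
    if (is.finite(best_obj) &&
        r$objective >= best_obj - 1e-9 * (1 + abs(best_obj))) next
    xv <- r$x
    frac <- abs(xv - round(xv))
    frac[!p$integer] <- 0
    if (max(frac) == 0) {
      best <- xv
      best_obj <- r$objective
      next
    }
    if (max(frac) <= int_tol) {
      # integral up to noise only: verify by re-solving with the integers
      # fixed at their rounded values (a tiny positive indicator under a
      # large linking bound can look integral yet carry real flow)
      fl <- node$lower
      fu <- node$upper
      fl[p$integer] <- fu[p$integer] <- round(xv[p$integer])
      rf <- .lp_solve(p$A_eq, p$rhs, obj_min, fl, fu, maximize = FALSE)
      if (rf$status == "optimal") {
        best <- rf$x
        best_obj <- rf$objective
        next
      }
      # rounding infeasible: branch on the largest (still nonzero)
      # fractionality, which strictly shrinks the integer box
    }
    j <- which.max(frac)                      # most fractional; ties -> lowest index
    lo <- node
    lo$upper[j] <- floor(xv[j])
    hi <- node
    hi$lower[j] <- floor(xv[j]) + 1
    # LIFO stack: push up-branch first so the down-branch is explored first
    stack[[length(stack) + 1L]] <- hi
    stack[[length(stack) + 1L]] <- lo
  }
  if (is.null(best)) return(list(status = "infeasible", objective_value = NA_real_))
  list(status = "optimal", values = best,
       objective_value = if (p$maximize) -best_obj else best_obj)
}
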