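# Realization algorithms.
#
# All of them search the set of Kirchhoff matrices A with Y A = M, columns
# summing to zero and nonnegative off-diagonal entries, optionally with
# selected entries pinned to zero (excluded reactions).  Both the equality
# system and the bounds are separable by column of A, so every linear
# program below is a small per-column problem: for column q the decision
# variables are the off-diagonal entries a_p = A[p, q] >= 0, the diagonal is
# eliminated through the column-sum condition, and the constraints read
#   sum_{p != q} (Y[, p] - Y[, q]) a_p = M[, q].
# The per-edge maximization, the core-reaction feasibility test and the
# minimal-cardinality search all act on one column at a time; the full
# m(m-1) sweep is the union of the per-column sweeps.

# ---- constraint-set handling -------------------------------------------

.parse_exclusions <- function(exclude, net) {
  if (is.null(exclude) || (is.data.frame(exclude) && nrow(exclude) == 0) ||
      (is.character(exclude) && length(exclude) == 0)) {
    return(data.frame(source = character(0), target = character(0),
                      si = integer(0), ti = integer(0)))
  }
  if (is.character(exclude)) {
    parts <- strsplit(exclude, "->", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed excluded reaction: '", exclude[bad][1], "'")
    exclude <- data.frame(source = trimws(vapply(parts, `[`, "", 1)),
                          target = trimws(vapply(parts, `[`, "", 2)))
  }
  exclude <- as.data.frame(exclude)
  stopifnot(all(c("source", "target") %in% names(exclude)))
  canon <- function(f) {
    format_complex(parse_complex(f, net$species))
  }
  src <- vapply(exclude$source, canon, "")
  tgt <- vapply(exclude$target, canon, "")
  si <- match(src, net$complexes)
  ti <- match(tgt, net$complexes)
  if (anyNA(si) || anyNA(ti)) {
    miss <- unique(c(src[is.na(si)], tgt[is.na(ti)]))
    stop("excluded reaction references unknown complex: ",
         paste(miss, collapse = ", "))
  }
  if (any(si == ti)) stop("excluded reaction must not be a self-loop")
  data.frame(source = src, target = tgt, si = si, ti = ti)
}

# ---- the per-column LP --------------------------------------------------

# Realization problem container: everything the per-column solvers need.
.realization_problem <- function(net, exclude = NULL, tol_zero = 1e-7,
                                 ubound = NULL) {
  stopifnot(inherits(net, "crn"))
  Y <- net$Y
  M <- invariant_matrix(net)
  A0 <- net$A
  diag(A0) <- 0
  # upper bounds are per column: rate coefficients in column q of any
  # realization live at the scale of M[, q], so a 1000x margin is
  # "appropriately large" without wrecking the conditioning of columns
  # whose natural scale is many orders below the network's largest rate
  col_scale <- pmax(1, apply(abs(M), 2, max))
  col_ub <- if (is.null(ubound)) {
    1000 * pmax(1, apply(abs(M), 2, max), apply(A0, 2, max))
  } else {
    rep_len(ubound, ncol(Y))
  }
  excl <- .parse_exclusions(exclude, net)
  m <- ncol(Y)
  list(net = net, Y = Y, M = M, m = m, n = nrow(Y),
       labels = net$complexes, excl = excl,
       ubound = max(col_ub), col_ub = col_ub, tol_zero = tol_zero,
       col_scale = col_scale,
       col_tol = tol_zero * col_scale)
}

# Column subproblem: candidate target indices P (exclusions dropped),
# constraint matrix C (n x |P|) and scaled rhs.
.col_problem <- function(prob, q) {
  P <- setdiff(seq_len(prob$m), q)
  drop <- prob$excl$ti[prob$excl$si == q]
  P <- setdiff(P, drop)
  C <- prob$Y[, P, drop = FALSE] - prob$Y[, q]
  # no pre-scaling of the rhs: the solver equilibrates rows itself, and a
  # uniform column scale would squash small rates below feasibility
  # tolerances when the column mixes magnitudes; s kept for interface
  s <- 1
  list(q = q, P = P, C = C, rhs = prob$M[, q], s = s,
       ub = rep(prob$col_ub[q], length(P)))
}

# Feasibility (phase I) of a column subproblem; returns warm-start state.
.col_phase1 <- function(cp) {
  if (length(cp$P) == 0) {
    feas <- max(abs(cp$rhs)) <= 1e-9
    return(list(feasible = feas, warm = NULL, x = numeric(0)))
  }
  r <- .lp_solve(cp$C, cp$rhs, numeric(length(cp$P)), numeric(length(cp$P)),
                 cp$ub)
  if (r$status == "infeasible") return(list(feasible = FALSE))
  if (r$status != "optimal") stop("LP solver failure on column ", cp$q)
  list(feasible = TRUE,
       warm = list(basis = r$basis, vstat = r$vstat, sgn = r$sgn),
       x = r$x)
}

# Maximize one off-diagonal entry of a column, reusing the phase-I basis.
.col_edge_max <- function(cp, warm, k) {
  obj <- numeric(length(cp$P))
  obj[k] <- 1
  r <- .lp_solve(cp$C, cp$rhs, obj, numeric(length(cp$P)), cp$ub,
                 maximize = TRUE, warm = warm)
  if (r$status != "optimal") stop("LP solver failure on column ", cp$q)
  r
}

.support_tibble <- function(prob, pairs) {
  # pairs: data.frame/list with si (source index) and ti (target index)
  ord <- order(pairs$si, pairs$ti)
  tibble::tibble(source = prob$labels[pairs$si][ord],
                 target = prob$labels[pairs$ti][ord])
}

.assemble_network <- function(prob, cols) {
  # cols: list over q of list(P, x, s, keep); entries outside `keep` are
  # structural zeros and are dropped outright (they carry solver noise only)
  A <- matrix(0, prob$m, prob$m, dimnames = list(prob$labels, prob$labels))
  for (q in seq_len(prob$m)) {
    cq <- cols[[q]]
    if (is.null(cq) || length(cq$P) == 0) next
    x <- pmax(cq$x, 0) * cq$s
    x[!cq$keep] <- 0
    A[cq$P, q] <- x
  }
  diag(A) <- -colSums(A)
  crn_from_matrices(prob$Y, A, species = prob$net$species)
}

.not_realizable <- function(q, prob) {
  stop("not realizable with the given complex set: the constrained ",
       "realization problem is infeasible (column of complex '",
       prob$labels[q], "')", call. = FALSE)
}

# ---- dense realization --------------------------------------------------

#' Maximal rate coefficient of one reaction over all equivalent realizations
#'
#' Solves the single linear program that maximizes the Kirchhoff entry of
#' the reaction `source -> target` subject to dynamical equivalence with
#' `net` (and any exclusions). A strictly positive maximum means the
#' reaction belongs to the dense realization.
#'
#' @param net a `crn` object.
#' @param source,target complex formulas of the reaction.
#' @param exclude excluded reactions: a data frame with columns
#'   `source`, `target`, or a character vector like `"X1 -> X2"`.
#' @param tol_zero relative zero-detection tolerance (scaled per column of
#'   the invariant matrix).
#' @param ubound upper bound on rate coefficients in the LPs; default
#'   `1000 * max(1, max|M|, max input rate)`. Dense membership does not
#'   depend on it, returned rate values can.
#' @return the maximal rate (0 when the reaction cannot occur in any
#'   equivalent realization).
#' @export
edge_max_rate <- function(net, source, target, exclude = NULL,
                          tol_zero = 1e-7, ubound = NULL) {
  prob <- .realization_problem(net, exclude, tol_zero, ubound)
  q <- match(format_complex(parse_complex(source, net$species)), prob$labels)
  p <- match(format_complex(parse_complex(target, net$species)), prob$labels)
  if (is.na(q) || is.na(p)) stop("unknown complex in edge")
  if (q == p) stop("self-loop edges are not part of a reaction graph")
  cp <- .col_problem(prob, q)
  k <- match(p, cp$P)
  if (is.na(k)) stop("edge is excluded by the constraint set")
  ph1 <- .col_phase1(cp)
  if (!ph1$feasible) .not_realizable(q, prob)
  r <- .col_edge_max(cp, ph1$warm, k)
  r$objective * cp$s
}

#' Dense realization: the unique super-structure of all equivalent networks
#'
#' Runs the linear-programming sweep over every ordered complex pair: each
#' candidate reaction's rate coefficient is maximized subject to dynamical
#' equivalence, the per-edge optimizers are averaged into strictly positive
#' lower bounds for the reactions found present, and a final feasibility
#' program assembles a Kirchhoff matrix realizing all of them at once. The
#' resulting unweighted graph contains the graph of every dynamically
#' equivalent (constrained) realization as a subgraph, and its structure is
#' unique.
#'
#' @inheritParams edge_max_rate
#' @return object of class `dense_realization` with fields `network` (a
#'   `crn` carrying one dense Kirchhoff matrix), `support` (tibble of
#'   reactions present), `edge_max` (tibble of per-edge maximal rates) and
#'   `epsilon` (the lower bounds used in the final assembly).
#' @export
#' @examples
#' dense <- dense_realization(example_positive_feedback())
#' glance(dense)
dense_realization <- function(net, exclude = NULL, tol_zero = 1e-7,
                              ubound = NULL) {
  prob <- .realization_problem(net, exclude, tol_zero, ubound)
  cols <- vector("list", prob$m)
  emax <- list(si = integer(0), ti = integer(0), val = numeric(0))
  eps <- list(si = integer(0), ti = integer(0), val = numeric(0))
  for (q in seq_len(prob$m)) {
    cp <- .col_problem(prob, q)
    ph1 <- .col_phase1(cp)
    if (!ph1$feasible) .not_realizable(q, prob)
    np <- length(cp$P)
    if (np == 0) {
      cols[[q]] <- list(P = integer(0), x = numeric(0), s = cp$s,
                        keep = logical(0))
      next
    }
    fmax <- numeric(np)
    xsum <- numeric(np)
    for (k in seq_len(np)) {
      r <- .col_edge_max(cp, ph1$warm, k)
      fmax[k] <- r$objective
      xsum <- xsum + r$x
    }
    xbar <- xsum / np                      # average of the sweep optimizers
    tol_s <- prob$col_tol[q] / cp$s
    present <- fmax > tol_s
    # clip the averaged lower bounds so they stay well above solver noise
    # yet never exceed the averaged value itself (feasibility by convexity)
    lb <- numeric(np)
    lb[present] <- pmin(xbar[present], 10 * tol_s)
    fin <- .lp_solve(cp$C, cp$rhs, numeric(np), lb, cp$ub)
    if (fin$status != "optimal") {
      # fall back to the plain average, which is feasible by convexity
      fin <- list(x = xbar)
    }
    cols[[q]] <- list(P = cp$P, x = fin$x, s = cp$s, keep = present)
    emax$si <- c(emax$si, rep(q, np)); emax$ti <- c(emax$ti, cp$P)
    emax$val <- c(emax$val, fmax * cp$s)
    eps$si <- c(eps$si, rep(q, np)); eps$ti <- c(eps$ti, cp$P)
    eps$val <- c(eps$val, lb * cp$s)
  }
  present <- emax$val > prob$tol_zero * prob$col_scale[emax$si]
  sup <- .support_tibble(prob, list(si = emax$si[present], ti = emax$ti[present]))
  ord <- order(emax$si, emax$ti)
  structure(
    list(network = .assemble_network(prob, cols),
         support = sup,
         edge_max = tibble::tibble(source = prob$labels[emax$si][ord],
                                   target = prob$labels[emax$ti][ord],
                                   max_rate = emax$val[ord]),
         epsilon = tibble::tibble(source = prob$labels[eps$si][ord],
                                  target = prob$labels[eps$ti][ord],
                                  epsilon = eps$val[ord]),
         exclude = prob$excl[c("source", "target")],
         tol_zero = tol_zero, ubound = prob$ubound),
    class = "dense_realization")
}

#' @export
print.dense_realization <- function(x, ...) {
  cat(sprintf("<dense realization: %d reactions over %d complexes>\n",
              nrow(x$support), length(x$network$complexes)))
  print(x$support, n = min(nrow(x$support), 12))
  invisible(x)
}

# ---- core reactions -----------------------------------------------------

#' Core reactions: reactions present in every equivalent realization
#'
#' For each reaction of the dense realization, checks the feasibility of the
#' realization constraint system with that single rate coefficient pinned to
#' zero. Infeasibility means no dynamically equivalent realization can omit
#' the reaction, making it a core reaction; the remaining dense reactions
#' are non-core.
#'
#' @inheritParams edge_max_rate
#' @param dense optionally, a precomputed [dense_realization()] for `net`
#'   under the same exclusions (recomputed when missing).
#' @return object of class `core_report` with tibbles `core` and `non_core`
#'   partitioning the dense support.
#' @export
#' @examples
#' glance(core_reactions(example_positive_feedback()))
core_reactions <- function(net, exclude = NULL, tol_zero = 1e-7,
                           ubound = NULL, dense = NULL) {
  prob <- .realization_problem(net, exclude, tol_zero, ubound)
  if (is.null(dense)) {
    dense <- dense_realization(net, exclude, tol_zero, ubound)
  }
  sup <- dense$support
  si <- match(sup$source, prob$labels)
  ti <- match(sup$target, prob$labels)
  is_core <- logical(nrow(sup))
  for (q in unique(si)) {
    cp <- .col_problem(prob, q)
    rows <- which(si == q)
    for (r in rows) {
      k <- match(ti[r], cp$P)
      ub <- cp$ub
      ub[k] <- 0                      # pin this reaction to zero
      res <- .lp_solve(cp$C, cp$rhs, numeric(length(cp$P)),
                       numeric(length(cp$P)), ub)
      if (res$status == "infeasible") {
        is_core[r] <- TRUE
      } else if (res$status != "optimal") {
        stop("LP solver failure in core test on column ", q)
      }
    }
  }
  structure(
    list(core = sup[is_core, ], non_core = sup[!is_core, ],
         dense = dense, exclude = prob$excl[c("source", "target")]),
    class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("<core reactions: %d core, %d non-core of %d dense reactions>\n",
              nrow(x$core), nrow(x$non_core),
              nrow(x$core) + nrow(x$non_core)))
  invisible(x)
}

# ---- sparse realization -------------------------------------------------

# Per-column minimal-cardinality MILP over the column's dense support.
# `umax` gives the per-edge maximal rates from the dense sweep (scaled like
# cp$rhs); they are the tightest valid linking bounds x_e <= U_e delta_e,
# which keeps the relaxation's delta values well away from the integrality
# tolerance. Returns list(cardinality, x, delta, D) plus, when
# enumerate = TRUE, all minimal supports found via no-good cuts.
.col_sparse <- function(prob, cp, D, umax, enumerate = FALSE,
                        max_count = Inf) {
  nd <- length(D)
  if (nd == 0) {
    return(list(cardinality = 0L, x = numeric(0), D = integer(0),
                supports = list(integer(0))))
  }
  kD <- match(D, cp$P)
  C <- cp$C[, kD, drop = FALSE]
  ubx <- pmin(cp$ub[kD], umax * (1 + 1e-6) + 1e-12)
  n <- nrow(C)
  # variables: x (nd), delta (nd, binary), slack (nd) for x - U delta <= 0
  A_eq <- rbind(cbind(C, matrix(0, n, 2 * nd)),
                cbind(diag(nd), diag(-ubx, nd), diag(nd)))
  rhs <- c(cp$rhs, numeric(nd))
  lower <- rep(0, 3 * nd)
  upper <- c(ubx, rep(1, nd), rep(Inf, nd))
  integer <- c(rep(FALSE, nd), rep(TRUE, nd), rep(FALSE, nd))
  objective <- c(rep(0, nd), rep(1, nd), rep(0, nd))
  base <- linear_program(objective, A_eq, rhs, lower, upper, integer)
  r0 <- solve(base)
  if (r0$status != "optimal") {
    stop("MILP failure in sparse computation on column ", cp$q)
  }
  card <- as.integer(round(r0$objective_value))
  out <- list(cardinality = card, x = r0$values[seq_len(nd)],
              delta = round(r0$values[nd + seq_len(nd)]) == 1, D = D)
  if (!enumerate) return(out)
  # enumerate all supports of exactly minimal cardinality via no-good cuts
  supports <- list()
  lp <- base
  lp$A_eq <- rbind(lp$A_eq, c(rep(0, nd), rep(1, nd), rep(0, nd)))
  lp$rhs <- c(lp$rhs, card)
  repeat {
    r <- solve(lp)
    if (r$status == "infeasible") break
    if (r$status != "optimal") stop("MILP failure while enumerating supports")
    delta <- round(r$values[nd + seq_len(nd)])
    sel <- which(delta == 1)
    supports[[length(supports) + 1L]] <- sort(D[sel])
    if (length(supports) >= max_count) break
    # no-good cut: sum_{e in S} delta_e <= |S| - 1, via a slack variable
    cut <- numeric(ncol(lp$A_eq))
    cut[nd + sel] <- 1
    lp$A_eq <- cbind(lp$A_eq, 0)
    lp$A_eq <- rbind(lp$A_eq, c(cut, 1))
    lp$rhs <- c(lp$rhs, length(sel) - 1)
    lp$objective <- c(lp$objective, 0)
    lp$lower <- c(lp$lower, 0)
    lp$upper <- c(lp$upper, Inf)
    lp$integer <- c(lp$integer, FALSE)
  }
  out$supports <- supports
  out
}

.dense_by_column <- function(prob, dense) {
  si <- match(dense$support$source, prob$labels)
  ti <- match(dense$support$target, prob$labels)
  em <- dense$edge_max
  mk <- stats::setNames(em$max_rate, paste(em$source, "->", em$target))
  key <- paste(dense$support$source, "->", dense$support$target)
  lapply(seq_len(prob$m), function(q) {
    sel <- which(si == q)
    sel <- sel[order(ti[sel])]
    list(D = ti[sel], umax = unname(mk[key[sel]]))
  })
}

#' Sparse realization: minimal number of reactions
#'
#' Finds a dynamically equivalent (constrained) realization with the
#' globally minimal number of reactions by mixed-integer linear
#' programming with binary presence indicators, restricted to the dense
#' support (legitimate because every realization's graph is a subgraph of
#' the dense one). Sparse realizations are generally not structurally
#' unique; use [enumerate_sparse_supports()] to obtain all minimal
#' structures.
#'
#' @inheritParams core_reactions
#' @return object of class `sparse_realization` with fields `network`,
#'   `support` and `cardinality`.
#' @export
#' @examples
#' sparse_realization(example_positive_feedback())$cardinality
sparse_realization <- function(net, exclude = NULL, tol_zero = 1e-7,
                               ubound = NULL, dense = NULL) {
  prob <- .realization_problem(net, exclude, tol_zero, ubound)
  if (is.null(dense)) dense <- dense_realization(net, exclude, tol_zero, ubound)
  byq <- .dense_by_column(prob, dense)
  cols <- vector("list", prob$m)
  si <- integer(0); ti <- integer(0)
  card <- 0L
  for (q in seq_len(prob$m)) {
    cp <- .col_problem(prob, q)
    cs <- .col_sparse(prob, cp, byq[[q]]$D, byq[[q]]$umax / cp$s)
    card <- card + cs$cardinality
    keep <- if (length(cs$D)) cs$delta else logical(0)
    cols[[q]] <- list(P = cs$D, x = cs$x, s = cp$s, keep = keep)
    si <- c(si, rep(q, sum(keep))); ti <- c(ti, cs$D[keep])
  }
  sup <- .support_tibble(prob, list(si = si, ti = ti))
  structure(
    list(network = .assemble_network(prob, cols), support = sup,
         cardinality = card, dense = dense,
         exclude = prob$excl[c("source", "target")]),
    class = "sparse_realization")
}

#' @export
print.sparse_realization <- function(x, ...) {
  cat(sprintf("<sparse realization: %d reactions (minimum possible)>\n",
              x$cardinality))
  print(x$support, n = min(nrow(x$support), 12))
  invisible(x)
}

#' Enumerate all minimal reaction structures
#'
#' Lists every distinct unweighted support attaining the minimal reaction
#' count of [sparse_realization()]. Within each Kirchhoff column the
#' alternative minimal supports are enumerated by adding no-good cuts to the
#' cardinality-fixed MILP; the global structures are the combinations of the
#' per-column alternatives (the realization constraints do not couple
#' columns).
#'
#' @inheritParams core_reactions
#' @param max_count stop after this many structures.
#' @return list of support tibbles, canonically ordered and deduplicated.
#' @export
#' @examples
#' length(enumerate_sparse_supports(example_positive_feedback()))
enumerate_sparse_supports <- function(net, exclude = NULL, max_count = 100,
                                      tol_zero = 1e-7, ubound = NULL,
                                      dense = NULL) {
  stopifnot(max_count >= 1)
  prob <- .realization_problem(net, exclude, tol_zero, ubound)
  if (is.null(dense)) dense <- dense_realization(net, exclude, tol_zero, ubound)
  byq <- .dense_by_column(prob, dense)
  per_col <- vector("list", prob$m)
  for (q in seq_len(prob$m)) {
    cp <- .col_problem(prob, q)
    cs <- .col_sparse(prob, cp, byq[[q]]$D, byq[[q]]$umax / cp$s,
                      enumerate = TRUE, max_count = max_count)
    per_col[[q]] <- cs$supports
  }
  # cartesian product of per-column alternatives
  combos <- list(list())
  for (q in seq_len(prob$m)) {
    alt <- per_col[[q]]
    combos <- unlist(lapply(combos, function(cmb) {
      lapply(alt, function(s) c(cmb, list(s)))
    }), recursive = FALSE)
    if (length(combos) > max_count) {
      combos <- combos[seq_len(max_count)]
    }
  }
  lapply(combos, function(cmb) {
    si <- rep(seq_len(prob$m), lengths(cmb))
    ti <- unlist(cmb)
    if (is.null(ti)) ti <- integer(0)
    .support_tibble(prob, list(si = si, ti = ti))
  })
}

# ---- structural uniqueness ---------------------------------------------

#' Is the reaction structure uniquely determined by the dynamics?
#'
#' A network's (constrained) structure is unique precisely when its
#' (constrained) dense and sparse realizations have identical unweighted
#' graphs; since every realization's graph sits between the sparse and the
#' dense one, the test reduces to comparing the dense support size with the
#' minimal cardinality.
#'
#' @inheritParams core_reactions
#' @return object of class `uniqueness_test`: a list with `unique`
#'   (logical), `dense_support`, `sparse_support` (tibbles) and
#'   `cardinality`.
#' @export
#' @examples
#' is_structure_unique(example_positive_feedback())$unique
is_structure_unique <- function(net, exclude = NULL, tol_zero = 1e-7,
                                ubound = NULL) {
  dense <- dense_realization(net, exclude, tol_zero, ubound)
  sparse <- sparse_realization(net, exclude, tol_zero, ubound, dense = dense)
  structure(
    list(unique = nrow(dense$support) == sparse$cardinality,
         dense_support = dense$support,
         sparse_support = sparse$support,
         cardinality = sparse$cardinality),
    class = "uniqueness_test")
}

#' @export
print.uniqueness_test <- function(x, ...) {
  cat(sprintf("<structure %s: dense %d reactions, minimal %d>\n",
              if (x$unique) "UNIQUE" else "not unique",
              nrow(x$dense_support), x$cardinality))
  invisible(x)
}
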