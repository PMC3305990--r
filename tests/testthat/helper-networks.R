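# Shared fixtures and independent oracles for the test suite.

edge_key <- function(sup) {
  if (nrow(sup) == 0) return(character(0))
  sort(paste(sup$source, "->", sup$target))
}

# paste() promotes zero-length vectors to "", so guard explicitly
key_pairs <- function(src, targets) {
  if (length(targets) == 0) return(character(0))
  paste(src, "->", targets)
}

same_support <- function(a, b) identical(edge_key(a), edge_key(b))

# one reaction, two complexes: everything about it is forced
single_reaction_net <- function(rate = 2.5) {
  crn(data.frame(source = "X1", target = "X2", rate = rate))
}

# A 4-complex network with structural redundancy, small enough for
# exhaustive verification: production of A at rate kp and degradation of B
# at rate kd, written through complexes {B, 0, A, A + B}.  The Kirchhoff
# column of B can realize the same dynamics through several reaction
# subsets, so dense > sparse and the sparse structure is non-unique.
redundant_small_net <- function(kp = 0.5, kd = 0.1) {
  net <- crn(data.frame(source = c("B", "B"),
                        target = c("0", "A + B"),
                        rate = c(kd, kp)),
             species = c("A", "B"))
  add_complex(net, "A")   # unused complex that enables alternative routes
}

# seeded random mass-action network on a fixed small complex set
random_small_net <- function(seed) {
  set.seed(seed)
  species <- c("X1", "X2", "X3")
  complexes <- c("X1", "X2", "X3", "X1 + X2", "2 X2", "0")
  m <- length(complexes)
  pairs <- expand.grid(s = seq_len(m), t = seq_len(m))
  pairs <- pairs[pairs$s != pairs$t, ]
  take <- pairs[sample.int(nrow(pairs), 7), ]
  rx <- data.frame(source = complexes[take$s], target = complexes[take$t],
                   rate = round(runif(7, 0.5, 5), 3))
  rx <- rx[!duplicated(rx[c("source", "target")]), ]
  crn(rx, species = species)
}

# ---- independent LP feasibility oracle (pracma's simplex, with bounds
# supplied as inequality rows, never the package's own solver) ------------

oracle_feasible <- function(C, b, ub) {
  n <- ncol(C)
  if (n == 0) return(max(abs(b)) < 1e-9)
  # scale rows for pracma's benefit; equivalence is exact
  rsc <- pmax(apply(abs(cbind(C, b)), 1, max), 1e-12)
  r <- tryCatch(
    suppressWarnings(pracma::linprog(
      cc = rep(0, n), A = diag(n), b = ub,
      Aeq = C / rsc, beq = b / rsc, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(r)) return(NA)
  if (r$errno == 1) {
    # confirm: pracma can return nonsense on degenerate input
    ok <- max(abs(C %*% r$x - b)) <= 1e-6 * max(1, max(abs(b)))
    return(isTRUE(ok))
  }
  if (r$errno == -4) return(FALSE)
  NA
}

# Exhaustive per-column realization analysis for tiny networks: for every
# subset of candidate reactions of each Kirchhoff column, test feasibility
# with the oracle; derive minimal supports and core edges by enumeration.
brute_force_column <- function(net, q, ub = NULL) {
  Y <- net$Y
  M <- Y %*% net$A
  m <- ncol(Y)
  P <- setdiff(seq_len(m), q)
  C <- Y[, P, drop = FALSE] - Y[, q]
  b <- M[, q]
  if (is.null(ub)) ub <- 1000 * max(1, max(abs(b)))
  feas_subset <- function(S) {
    oracle_feasible(C[, S, drop = FALSE], b, rep(ub, length(S)))
  }
  subsets <- lapply(0:(2^length(P) - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_along(P) - 1)) > 0)
  })
  feas <- vapply(subsets, feas_subset, logical(1))
  stopifnot(!anyNA(feas))
  sizes <- lengths(subsets)[feas]
  min_size <- min(sizes)
  minimal <- subsets[feas][lengths(subsets[feas]) == min_size]
  # an edge is core when every feasible subset contains it (in particular,
  # the subset dropping just that edge is infeasible)
  in_all <- Reduce(intersect, subsets[feas])
  # dense membership: the edge's rate can be strictly positive in some
  # feasible assignment (checked by maximizing it with the oracle solver)
  dense <- P[vapply(seq_along(P), function(k) {
    rsc <- pmax(apply(abs(cbind(C, b)), 1, max), 1e-12)
    r <- tryCatch(suppressWarnings(pracma::linprog(
      cc = as.numeric(seq_along(P) == k), A = diag(length(P)),
      b = rep(ub, length(P)), Aeq = C / rsc, beq = b / rsc,
      maximize = TRUE, maxiter = 500)), error = function(e) NULL)
    !is.null(r) && r$errno == 1 && r$fval > 1e-7 * max(1, max(abs(b)))
  }, logical(1))]
  list(P = P, min_size = min_size,
       minimal_targets = lapply(minimal, function(S) sort(P[S])),
       core_targets = sort(P[in_all]),
       dense_targets = sort(dense))
}
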