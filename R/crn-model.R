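# Core data model for mass-action chemical reaction networks.
#
# A network is the pair (Y, A_k): Y is the n x m complex composition matrix
# (species by complexes, nonnegative integers), and A_k is the m x m
# Kirchhoff matrix whose off-diagonal entry [A_k]_{i,j} is the rate
# coefficient of the reaction C_j -> C_i and whose columns sum to zero.
# The species ODEs under mass-action kinetics are xdot = Y A_k psi(x) with
# psi_j(x) = prod_i x_i^{Y_ij}.

#' Parse a complex formula
#'
#' Complexes are written as `"2 X1 + X2"`; a bare `"0"` denotes the zero
#' (empty) complex used for inflow/outflow and degradation reactions.
#'
#' @param text a single complex formula string.
#' @param species character vector of valid species names.
#' @return named integer vector of stoichiometric coefficients over `species`.
#' @export
#' @examples
#' parse_complex("2 X1 + X2", c("X1", "X2", "X3"))
parse_complex <- function(text, species) {
  v <- stats::setNames(integer(length(species)), species)
  s <- trimws(text)
  if (s == "0") return(v)
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  for (tm in terms) {
    tm <- trimws(tm)
    if (tm == "") stop("malformed complex: '", text, "'")
    mm <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z._][A-Za-z0-9._]*)$", tm))[[1]]
    if (length(mm) == 0) stop("malformed stoichiometry in complex: '", text, "'")
    coef <- if (mm[2] == "") 1L else as.integer(mm[2])
    sp <- mm[3]
    if (!sp %in% species) stop("unknown species '", sp, "' in complex '", text, "'")
    if (coef < 1L) stop("nonpositive stoichiometric coefficient in complex: '", text, "'")
    v[sp] <- v[sp] + coef
  }
  v
}

#' Format a complex composition vector as a formula string
#'
#' Inverse of [parse_complex()]: coefficients of one are omitted and the zero
#' complex prints as `"0"`.
#'
#' @param v named integer vector of stoichiometric coefficients.
#' @return a single string.
#' @export
format_complex <- function(v) {
  nz <- which(v > 0)
  if (length(nz) == 0) return("0")
  paste(ifelse(v[nz] > 1, paste(v[nz], names(v)[nz]), names(v)[nz]),
        collapse = " + ")
}

.complex_labels <- function(Y) {
  unname(apply(Y, 2, function(col) {
    format_complex(stats::setNames(col, rownames(Y)))
  }))
}

.validate_Y <- function(Y) {
  if (any(Y < 0) || any(Y != round(Y))) {
    stop("complex composition matrix must contain nonnegative integers")
  }
  labs <- .complex_labels(Y)
  if (anyDuplicated(labs)) {
    stop("duplicate complexes: ", paste(labs[duplicated(labs)], collapse = ", "))
  }
  if (sum(colSums(Y) == 0) > 1) stop("at most one zero complex is allowed")
  invisible(TRUE)
}

.validate_kirchhoff <- function(A, tol = 1e-8) {
  m <- nrow(A)
  if (ncol(A) != m) stop("Kirchhoff matrix must be square")
  off <- A
  diag(off) <- 0
  if (any(off < -tol * max(1, max(abs(A))))) {
    stop("off-diagonal Kirchhoff entries must be nonnegative")
  }
  cs <- colSums(A)
  if (any(abs(cs) > tol * max(1, max(abs(A))))) {
    stop("Kirchhoff matrix columns must sum to zero")
  }
  if (any(diag(A) > tol * max(1, max(abs(A))))) {
    stop("Kirchhoff diagonal entries must be nonpositive")
  }
  invisible(TRUE)
}

#' Construct a mass-action reaction network from a reaction table
#'
#' The first argument is a data frame with one row per reaction and columns
#' `source`, `target` (complex formulas such as `"2 X1"`, `"X2 + X3"`, `"0"`)
#' and `rate` (positive mass-action rate coefficient). Complexes are
#' deduplicated and kept in order of first appearance, which preserves the
#' numbering of hand-written models.
#'
#' @param reactions data frame with columns `source`, `target`, `rate`.
#' @param species character vector fixing the species universe and order;
#'   defaults to the species in order of first appearance.
#' @return an object of class `crn` with fields `species`, `complexes`
#'   (labels), `Y` (composition matrix) and `A` (Kirchhoff matrix).
#' @seealso [reactions()], [invariant_matrix()], [dense_realization()]
#' @export
#' @examples
#' net <- crn(data.frame(source = "2 X1", target = "X2", rate = 1))
#' reactions(net)
crn <- function(reactions, species = NULL) {
  reactions <- as.data.frame(reactions)
  need <- c("source", "target", "rate")
  if (!all(need %in% names(reactions))) {
    stop("`reactions` must have columns source, target, rate")
  }
  if (is.null(species)) {
    toks <- unlist(regmatches(
      c(rbind(reactions$source, reactions$target)),
      gregexpr("[A-Za-z._][A-Za-z0-9._]*", c(rbind(reactions$source, reactions$target)))))
    species <- unique(toks)
  }
  if (length(species) == 0) stop("no species found")
  labels <- character(0)
  cols <- list()
  idx_of <- function(formula) {
    v <- parse_complex(formula, species)
    lab <- format_complex(v)
    i <- match(lab, labels)
    if (is.na(i)) {
      labels <<- c(labels, lab)
      cols[[length(cols) + 1L]] <<- v
      i <- length(labels)
    }
    i
  }
  nr <- nrow(reactions)
  si <- integer(nr)
  ti <- integer(nr)
  for (r in seq_len(nr)) {
    si[r] <- idx_of(reactions$source[r])
    ti[r] <- idx_of(reactions$target[r])
    if (si[r] == ti[r]) {
      stop("self-loop reaction not allowed: '", reactions$source[r],
           " -> ", reactions$target[r], "'")
    }
    if (!is.finite(reactions$rate[r]) || reactions$rate[r] <= 0) {
      stop("reaction rate must be positive: '", reactions$source[r],
           " -> ", reactions$target[r], "'")
    }
  }
  if (anyDuplicated(cbind(si, ti))) {
    d <- which(duplicated(cbind(si, ti)))[1]
    stop("duplicate reaction: '", reactions$source[d], " -> ",
         reactions$target[d], "'")
  }
  m <- length(labels)
  Y <- matrix(0L, length(species), m, dimnames = list(species, labels))
  for (j in seq_len(m)) Y[, j] <- cols[[j]]
  A <- matrix(0, m, m, dimnames = list(labels, labels))
  for (r in seq_len(nr)) A[ti[r], si[r]] <- reactions$rate[r]
  diag(A) <- -colSums(A)
  new_crn(species, Y, A)
}

#' Construct a network directly from its matrices
#'
#' @param Y n x m nonnegative-integer composition matrix (species in rows).
#' @param A m x m Kirchhoff matrix: nonnegative off-diagonal rate
#'   coefficients, columns summing to zero. `A[i, j]` is the rate of the
#'   reaction from complex `j` to complex `i`.
#' @param species optional species names (default `rownames(Y)` or `X1..Xn`).
#' @return a `crn` object.
#' @export
crn_from_matrices <- function(Y, A, species = NULL) {
  Y <- as.matrix(Y)
  if (is.null(species)) {
    species <- rownames(Y)
    if (is.null(species)) species <- paste0("X", seq_len(nrow(Y)))
  }
  rownames(Y) <- species
  new_crn(species, Y, as.matrix(A))
}

new_crn <- function(species, Y, A) {
  .validate_Y(Y)
  .validate_kirchhoff(A)
  if (ncol(Y) != nrow(A)) stop("Y and A dimensions are inconsistent")
  labels <- .complex_labels(Y)
  colnames(Y) <- labels
  dimnames(A) <- list(labels, labels)
  structure(list(species = species, complexes = labels, Y = Y, A = A),
            class = "crn")
}

#' @export
print.crn <- function(x, ...) {
  rx <- reactions(x)
  cat(sprintf("<crn: %d species, %d complexes, %d reactions>\n",
              length(x$species), length(x$complexes), nrow(rx)))
  if (nrow(rx) > 0) print(rx, n = min(nrow(rx), 12))
  invisible(x)
}

#' List the reactions of a network as a tibble
#'
#' @param net a `crn` object.
#' @param tol entries of the Kirchhoff matrix at or below `tol` are treated
#'   as absent reactions.
#' @return tibble with columns `source`, `target`, `rate`, ordered by source
#'   then target complex index.
#' @export
reactions <- function(net, tol = 0) {
  stopifnot(inherits(net, "crn"))
  m <- length(net$complexes)
  idx <- which(net$A > tol & row(net$A) != col(net$A), arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(source = net$complexes[idx[, 2]],
                 target = net$complexes[idx[, 1]],
                 rate = net$A[idx])
}

#' Extend the complex set of a network
#'
#' Appends complexes that take part in no reaction (their Kirchhoff column
#' and row are zero). The dynamics are unchanged, but realization
#' computations may then use the new complexes, which can enlarge the dense
#' realization and change the core reaction set.
#'
#' @param net a `crn` object.
#' @param ... complex formula strings to append.
#' @return a `crn` with the enlarged complex set.
#' @export
#' @examples
#' net <- example_positive_feedback()
#' extended <- add_complex(net, "X2 + X4")
add_complex <- function(net, ...) {
  stopifnot(inherits(net, "crn"))
  formulas <- c(...)
  Y <- net$Y
  A <- net$A
  for (f in formulas) {
    v <- parse_complex(f, net$species)
    lab <- format_complex(v)
    if (lab %in% .complex_labels(Y)) {
      stop("complex already present: '", lab, "'")
    }
    Y <- cbind(Y, v)
    A <- rbind(cbind(A, 0), 0)
  }
  new_crn(net$species, Y, A)
}

#' Evaluate the mass-action monomial map
#'
#' Computes `psi_j(x) = prod_i x_i^{Y[i,j]}` for every complex `j`. The zero
#' complex yields 1 (empty product).
#'
#' @param net a `crn` object, or a composition matrix `Y`.
#' @param x nonnegative state vector, one entry per species.
#' @return numeric vector with one entry per complex.
#' @export
monomial_vector <- function(net, x) {
  Y <- if (inherits(net, "crn")) net$Y else as.matrix(net)
  if (length(x) != nrow(Y)) {
    stop("state vector length ", length(x), " does not match species count ",
         nrow(Y))
  }
  if (any(x < 0)) stop("state vector must be nonnegative")
  apply(Y, 2, function(col) prod(x^col))
}

#' The invariant (monomial-coefficient) matrix of a network
#'
#' Returns `M = Y %*% A`: entry `M[i, j]` is the coefficient of the monomial
#' of complex `j` in the ODE of species `i`. Every realization of the same
#' dynamics over the same complex set shares this matrix, which is why all
#' realization computations are linear problems in the Kirchhoff entries.
#'
#' @param net a `crn` object.
#' @return numeric matrix (species by complexes).
#' @export
invariant_matrix <- function(net) {
  stopifnot(inherits(net, "crn"))
  net$Y %*% net$A
}

#' Evaluate the mass-action dynamics
#'
#' Computes the species derivative `Y A psi(x)` at a state.
#'
#' @param net a `crn` object.
#' @param x nonnegative state vector.
#' @return numeric vector of species derivatives.
#' @export
evaluate_dynamics <- function(net, x) {
  stopifnot(inherits(net, "crn"))
  as.vector(invariant_matrix(net) %*% monomial_vector(net$Y, x))
}

#' Reaction support of a Kirchhoff matrix
#'
#' The unweighted reaction graph: the set of ordered complex pairs whose
#' rate coefficient strictly exceeds `tol` (solver noise on structural zeros
#' is excluded by the strict inequality).
#'
#' @param net a `crn` object or an m x m Kirchhoff matrix with complex
#'   labels as dimnames.
#' @param tol positive absolute threshold.
#' @return tibble with columns `source`, `target`, ordered canonically.
#' @export
support <- function(net, tol = 1e-9) {
  stopifnot(tol > 0)
  A <- if (inherits(net, "crn")) net$A else as.matrix(net)
  labels <- colnames(A)
  idx <- which(A > tol & row(A) != col(A), arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(source = labels[idx[, 2]], target = labels[idx[, 1]])
}

edge_keys <- function(sup) paste(sup$source, "->", sup$target)

#' Merge two complex sets
#'
#' Builds the union of the two complex sets (deduplicated; first matrix's
#' order first, then unseen columns of the second) together with the index
#' maps from each input into the union.
#'
#' @param Y1,Y2 composition matrices over the same species universe
#'   (identical rownames, any order).
#' @return list with elements `Y` (union matrix), `map1`, `map2` (integer
#'   vectors: column `j` of input `i` is column `map_i[j]` of the union).
#' @export
merge_complex_sets <- function(Y1, Y2) {
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  if (is.null(rownames(Y1)) || is.null(rownames(Y2)) ||
      !setequal(rownames(Y1), rownames(Y2))) {
    stop("complex matrices must share the same species universe")
  }
  Y2 <- Y2[rownames(Y1), , drop = FALSE]
  l1 <- .complex_labels(Y1)
  l2 <- .complex_labels(Y2)
  labels <- c(l1, setdiff(l2, l1))
  Y <- cbind(Y1, Y2[, match(setdiff(l2, l1), l2), drop = FALSE])
  colnames(Y) <- labels
  list(Y = Y, map1 = match(l1, labels), map2 = match(l2, labels))
}

#' Test dynamical equivalence of two networks
#'
#' Two mass-action networks are dynamically equivalent when they generate
#' identical species ODEs. Over a merged complex set this reduces to
#' equality of the invariant matrices, so the test is purely algebraic (no
#' numerical integration is involved).
#'
#' @param net1,net2 `crn` objects over the same species set (order may
#'   differ).
#' @param tol relative tolerance on the max-norm of the difference of the
#'   zero-padded invariant matrices.
#' @return `TRUE` or `FALSE`.
#' @export
check_dynamical_equivalence <- function(net1, net2, tol = 1e-8) {
  stopifnot(inherits(net1, "crn"), inherits(net2, "crn"))
  if (!setequal(net1$species, net2$species)) {
    stop("networks must share the same species set")
  }
  Y2 <- net2$Y[net1$species, , drop = FALSE]
  mg <- merge_complex_sets(net1$Y, Y2)
  m <- ncol(mg$Y)
  n <- nrow(mg$Y)
  M1 <- matrix(0, n, m)
  M2 <- matrix(0, n, m)
  M1[, mg$map1] <- invariant_matrix(net1)
  M2[, mg$map2] <- invariant_matrix(net2)[net1$species, , drop = FALSE]
  max(abs(M1 - M2)) <= tol * max(1, max(abs(M1)))
}
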