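# Programmatic constructors for the example systems used throughout the
# package: a gene-regulatory positive feedback motif, a yeast cell-cycle
# biochemical switch, a five-node repressilator with auto-activation, and a
# seeded sampler for rate coefficients where the literature source gives the
# structure but not the parameter values.

#' Seeded sampler for random positive rate coefficients
#'
#' Draws are uniform on `[low, high)` and strictly positive; an identical
#' seed always yields the identical sequence. The global RNG state is left
#' untouched.
#'
#' @param seed integer seed.
#' @param low,high interval bounds, `0 < low < high`.
#' @return object of class `rate_sampler`.
#' @export
#' @examples
#' draw_rates(random_rates(1), 3)
random_rates <- function(seed, low = 0.5, high = 20.5) {
  if (!(is.numeric(low) && is.numeric(high) && 0 < low && low < high)) {
    stop("rate sampler bounds must satisfy 0 < low < high")
  }
  structure(list(seed = as.integer(seed), low = low, high = high),
            class = "rate_sampler")
}

#' Draw rate coefficients from a sampler
#'
#' @param sampler a [random_rates()] sampler.
#' @param n number of draws.
#' @return numeric vector of length `n` in `[low, high)`.
#' @export
draw_rates <- function(sampler, n) {
  stopifnot(inherits(sampler, "rate_sampler"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sampler$seed)
  stats::runif(n, sampler$low, sampler$high)
}

#' @export
print.rate_sampler <- function(x, ...) {
  cat(sprintf("<rate sampler: uniform [%g, %g), seed %d>\n",
              x$low, x$high, x$seed))
  invisible(x)
}

#' Positive feedback motif (5 species, 11 complexes, 9 reactions)
#'
#' A gene-regulation motif in which a protein promotes its own transcription
#' after dimerization: `X1` protein monomer, `X2` dimer, `X3`/`X4`
#' unoccupied/occupied promoter, `X5` mRNA. The nine reactions are
#' dimerization and re-dimerization (`k1`, `k2`), promoter binding and
#' dissociation (`k3`, `k4`), activated and basal transcription (`k5`,
#' `k6`), mRNA and monomer degradation (`k7`, `k8`) and translation (`k9`).
#' The default rates are the published parametrization of the motif.
#'
#' @param rates numeric vector `c(k1, ..., k9)` of positive rate
#'   coefficients.
#' @param extended if `TRUE`, the complex `X2 + X4` is appended to the
#'   complex set (it takes part in no reaction of the original model, but
#'   enlarges the space of equivalent realizations).
#' @return a `crn` object.
#' @export
#' @examples
#' net <- example_positive_feedback()
#' reactions(net)
example_positive_feedback <- function(rates = c(1e7, 1e7, 1e7, 1e7, 1.7,
                                                0.025, 0.1, 0.05, 0.5),
                                      extended = FALSE) {
  stopifnot(length(rates) == 9)
  if (any(!is.finite(rates) | rates <= 0)) stop("rates must be positive")
  k <- rates
  rx <- data.frame(
    source = c("2 X1", "X2", "X2 + X3", "X4", "X4", "X3", "X5", "X1", "X5"),
    target = c("X2", "2 X1", "X4", "X2 + X3", "X4 + X5", "X3 + X5", "0",
               "0", "X1 + X5"),
    rate = k)
  net <- crn(rx, species = paste0("X", 1:5))
  if (extended) net <- add_complex(net, "X2 + X4") else net
}

# 17 complexes of the yeast switch model over species X1..X9, one row per
# complex (transcribed from the published composition matrix).
.yeast_switch_Yt <- function() {
  digits <- paste0(
    "010000000000000000100000000101000000000100000001000000011000000",
    "000010000001100000000000001001010000010001000000000100100001000",
    "000011000000000010000101000")
  matrix(as.integer(strsplit(digits, "")[[1]]), nrow = 17, ncol = 9,
         byrow = TRUE)
}

#' Yeast cell-cycle biochemical switch (9 species, 17 complexes, 18 reactions)
#'
#' A switching device in yeast cell-cycle regulation built from the
#' cyclin-dependent kinase inhibitor Sic1, the cyclin Clb and the
#' phosphatase Cdc14. Species `X1..X9` are, in order: Sic1, Sic1P, Clb,
#' Clb·Sic1, Clb·Sic1P, Cdc14, Sic1P·Cdc14, Clb·Sic1P·Cdc14 and
#' Clb·Sic1·Clb. The source publishes the structure but not the rate
#' coefficients, so rates are drawn from a seeded [random_rates()] sampler;
#' every structural result of the realization algorithms is invariant to
#' the draw (and the test-suite checks this at two seeds).
#'
#' @param sampler a [random_rates()] sampler supplying the 18 rate
#'   coefficients.
#' @return a `crn` object.
#' @export
example_yeast_switch <- function(sampler = random_rates(1)) {
  Y <- t(.yeast_switch_Yt())
  rownames(Y) <- paste0("X", 1:9)
  # reaction list: [A]_{ti, si} pairs in the published order k1..k18
  ti <- c(2L, 2L, 3L, 4L, 5L, 6L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L,
          15L, 16L, 17L)
  si <- c(1L, 3L, 2L, 5L, 4L, 5L, 8L, 8L, 7L, 10L, 9L, 10L, 13L, 12L, 13L,
          16L, 15L, 16L)
  k <- draw_rates(sampler, 18)
  m <- 17L
  A <- matrix(0, m, m)
  A[cbind(ti, si)] <- k
  diag(A) <- -colSums(A)
  crn_from_matrices(Y, A)
}

#' Five-node repressilator with auto-activation (25 species, 51 complexes)
#'
#' A ring of five genes in which each protein activates its own gene and
#' represses the next gene around the ring (repression pairs
#' `(i, j) in {(1,5), (2,1), (3,2), (4,3), (5,4)}`). Gene states are `Gi`
#' (free), `GiA` (activator bound), `GiR` (repressor bound) and `GiAR`
#' (both bound); `Pi` are the proteins. Per gene the model has four
#' reversible binding pairs, protein production from the activated states
#' (including leak production from `GiAR`), and first-order protein
#' degradation through the zero complex: 11 reactions per gene, 55 in
#' total over 51 distinct complexes. Rates are drawn from a seeded sampler
#' as the literature source does not publish them; structural results are
#' invariant to the draw.
#'
#' @param sampler a [random_rates()] sampler supplying the 55 rate
#'   coefficients (in gene order, `k[i,1] .. k[i,11]`).
#' @return a `crn` object.
#' @export
example_repressilator <- function(sampler = random_rates(1)) {
  pairs <- cbind(i = 1:5, j = c(5, 1, 2, 3, 4))
  k <- draw_rates(sampler, 55)
  src <- character(0); tgt <- character(0)
  for (r in 1:5) {
    i <- pairs[r, "i"]; j <- pairs[r, "j"]
    G <- paste0("G", i); GA <- paste0("G", i, "A"); GR <- paste0("G", i, "R")
    GAR <- paste0("G", i, "AR"); Pi <- paste0("P", i); Pj <- paste0("P", j)
    s <- c(paste(G, "+", Pi),  GA,                    # auto-activation 1
           GA,                                        # production 1
           paste(G, "+", Pj),  GR,                    # repression 1
           paste(GR, "+", Pi), GAR,                   # auto-activation 2
           paste(GA, "+", Pj), GAR,                   # repression 2
           GAR,                                       # production 2
           Pi)                                        # degradation
    t <- c(GA, paste(G, "+", Pi),
           paste(GA, "+", Pi),
           GR, paste(G, "+", Pj),
           GAR, paste(GR, "+", Pi),
           GAR, paste(GA, "+", Pj),
           paste(GAR, "+", Pi),
           "0")
    src <- c(src, s); tgt <- c(tgt, t)
  }
  species <- as.vector(t(outer(1:5, c("G%d", "G%dA", "G%dR", "G%dAR", "P%d"),
                               function(i, f) sprintf(f, i))))
  crn(data.frame(source = src, target = tgt, rate = k), species = species)
}
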