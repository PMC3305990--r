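# Core data model: complexes, Kirchhoff matrices, monomial maps, dynamics
# and the algebraic dynamical-equivalence test.

sp5 <- paste0("X", 1:5)

# invariant matrix of the positive feedback motif written down directly
# from its printed ODEs (independent of the package's Y %*% A product)
feedback_M_by_hand <- function(k) {
  cx <- c("2 X1", "X2", "X2 + X3", "X4", "X4 + X5", "X3", "X3 + X5",
          "X5", "0", "X1", "X1 + X5")
  M <- matrix(0, 5, length(cx), dimnames = list(sp5, cx))
  M["X1", "2 X1"] <- -2 * k[1]; M["X2", "2 X1"] <- k[1]
  M["X1", "X2"] <- 2 * k[2];    M["X2", "X2"] <- -k[2]
  M["X2", "X2 + X3"] <- -k[3];  M["X3", "X2 + X3"] <- -k[3]
  M["X4", "X2 + X3"] <- k[3]
  M["X2", "X4"] <- k[4]; M["X3", "X4"] <- k[4]; M["X4", "X4"] <- -k[4]
  M["X5", "X4"] <- k[5]
  M["X5", "X3"] <- k[6]
  M["X5", "X5"] <- -k[7]; M["X1", "X5"] <- k[9]
  M["X1", "X1"] <- -k[8]
  M
}

test_that("complex formulas parse and format round-trip", {
  v <- parse_complex("2 X1 + X2", sp5)
  expect_equal(unname(v[1:2]), c(2L, 1L))
  expect_equal(format_complex(v), "2 X1 + X2")
  expect_equal(format_complex(parse_complex("0", sp5)), "0")
  expect_error(parse_complex("2 Z9", sp5), "unknown species")
  expect_error(parse_complex("X1 + + X2", sp5), "malformed")
})

test_that("network construction enforces the model invariants", {
  expect_error(crn(data.frame(source = "X1", target = "X1", rate = 1)),
               "self-loop")
  expect_error(crn(data.frame(source = "X1", target = "X2", rate = -2)),
               "positive")
  expect_error(crn(data.frame(source = c("X1", "X1"),
                              target = c("X2", "X2"), rate = c(1, 2))),
               "duplicate")
  # Kirchhoff columns of any constructed network sum to zero
  net <- example_positive_feedback()
  expect_lt(max(abs(colSums(net$A))), 1e-8 * max(1, max(abs(net$A))))
  expect_true(all(diag(net$A) <= 0))
})

test_that("monomial map follows mass-action exponents", {
  net <- example_positive_feedback()
  psi <- monomial_vector(net, c(3, 1, 1, 1, 1))
  expect_equal(unname(psi[match("2 X1", net$complexes)]), 9)
  expect_equal(unname(psi[match("0", net$complexes)]), 1)  # empty product
  # all-ones state maps to all ones for any composition matrix
  for (seed in 1:5) {
    set.seed(seed)
    Y <- matrix(sample(0:3, 12, replace = TRUE), 3)
    rownames(Y) <- paste0("S", 1:3)
    expect_equal(unname(monomial_vector(Y, rep(1, 3))), rep(1, ncol(Y)))
  }
  expect_error(monomial_vector(net, c(1, 2)), "does not match")
  expect_error(monomial_vector(net, c(-1, 1, 1, 1, 1)), "nonnegative")
})

test_that("invariant matrix matches coefficients read off the ODEs", {
  one <- single_reaction_net(rate = 1)
  expect_equal(unname(invariant_matrix(one)),
               matrix(c(-1, 1, 0, 0), 2))
  k <- c(1e7, 1e7, 1e7, 1e7, 1.7, 0.025, 0.1, 0.05, 0.5)
  net <- example_positive_feedback(rates = k)
  M <- invariant_matrix(net)
  expect_equal(M, feedback_M_by_hand(k)[, colnames(M)])
  # entry-by-entry recomputation of the matrix product
  brute <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      brute[i, j] <- sum(net$Y[i, ] * net$A[, j])
    }
  }
  expect_equal(unname(M), brute)
})

test_that("dynamics evaluation equals M times the monomial vector", {
  net <- example_positive_feedback()
  M <- invariant_matrix(net)
  set.seed(1)
  for (t in 1:20) {
    x <- runif(5, 0, 2)
    expect_equal(evaluate_dynamics(net, x),
                 as.vector(M %*% monomial_vector(net, x)))
  }
  # detailed balance of a symmetric reversible pair
  rev <- crn(data.frame(source = c("X1", "X2"), target = c("X2", "X1"),
                        rate = c(3, 3)))
  expect_equal(evaluate_dynamics(rev, c(0.7, 0.7)), c(0, 0))
})

test_that("support extraction applies a strict threshold", {
  net <- example_positive_feedback()
  expect_equal(nrow(support(net)), 9)
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  expect_equal(nrow(support(A, tol = 1e-9)), 0)
  A["b", "a"] <- 1e-6
  A["a", "a"] <- -1e-6
  expect_equal(nrow(support(A, tol = 1e-6)), 0)   # exactly at tol: excluded
  expect_equal(nrow(support(A, tol = 0.9e-6)), 1)
})

test_that("complex-set merging is a deduplicated, mapped union", {
  net <- example_positive_feedback()
  ext <- example_positive_feedback(extended = TRUE)
  mg <- merge_complex_sets(net$Y, ext$Y)
  expect_equal(ncol(mg$Y), 12)
  expect_equal(mg$map1, seq_len(11))
  same <- merge_complex_sets(net$Y, net$Y)
  expect_equal(same$map1, same$map2)
  expect_equal(ncol(same$Y), 11)
  # idempotent and order-insensitive
  mg2 <- merge_complex_sets(ext$Y, net$Y)
  expect_setequal(colnames(mg2$Y), colnames(mg$Y))
  mg3 <- merge_complex_sets(mg$Y, mg$Y)
  expect_equal(ncol(mg3$Y), ncol(mg$Y))
  # disjoint complex sets concatenate
  a <- crn(data.frame(source = "X1", target = "X2", rate = 1),
           species = sp5)
  b <- crn(data.frame(source = "X3", target = "2 X4", rate = 1),
           species = sp5)
  expect_equal(ncol(merge_complex_sets(a$Y, b$Y)$Y), 4)
})

test_that("dynamical equivalence is reflexive and perturbation-sensitive", {
  net <- example_positive_feedback()
  expect_true(check_dynamical_equivalence(net, net))
  # adding an unused complex never changes the dynamics
  expect_true(check_dynamical_equivalence(net,
                                          add_complex(net, "X2 + X4")))
  # perturbing one rate by 10x the (relative) tolerance is detected,
  # while a perturbation below the tolerance is not
  tol <- 1e-8
  scale <- max(abs(invariant_matrix(net)))
  rx <- reactions(net)
  j <- which.max(rx$rate)
  rx_hi <- rx; rx_hi$rate[j] <- rx_hi$rate[j] + 10 * tol * scale
  expect_false(check_dynamical_equivalence(
    net, crn(rx_hi, species = net$species), tol = tol))
  rx_lo <- rx; rx_lo$rate[j] <- rx_lo$rate[j] + 0.1 * tol * scale
  expect_true(check_dynamical_equivalence(
    net, crn(rx_lo, species = net$species), tol = tol))
  other <- crn(data.frame(source = "A", target = "B", rate = 1))
  expect_error(check_dynamical_equivalence(net, other), "species")
})
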