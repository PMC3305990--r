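# The LP/MILP backend is the foundation of every realization computation,
# so it is cross-checked against an independent solver (pracma's simplex)
# and against exhaustive enumeration.

test_that("trivial programs solve to their known optima", {
  lp <- linear_program(c(1, 0), matrix(c(1, 1), 1), 5, maximize = TRUE)
  r <- solve(lp)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 5)

  infeas <- linear_program(1, matrix(1, 1, 1), -1)  # x = -1, x >= 0
  expect_equal(solve(infeas)$status, "infeasible")

  unb <- linear_program(c(0, -1), matrix(c(1, -1), 1), 0)
  expect_equal(solve(unb)$status, "unbounded")
})

test_that("random equality-constrained LPs agree with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(42)
  checked <- 0
  for (t in 1:150) {
    n <- sample(3:8, 1)
    m <- sample(2:(n - 1), 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    feas <- runif(1) < 0.7
    b <- if (feas) as.vector(A %*% runif(n, 0, 3)) else round(rnorm(m), 2) * 10
    cc <- round(rnorm(n), 2)
    mine <- solve(linear_program(cc, A, b, lower = rep(0, n),
                                 upper = rep(10, n)))
    pr <- tryCatch(suppressWarnings(pracma::linprog(
      cc, A = diag(n), b = rep(10, n), Aeq = A, beq = b,
      maximize = FALSE, maxiter = 2000)), error = function(e) NULL)
    if (is.null(pr) || !(pr$errno %in% c(1, -4))) next
    checked <- checked + 1
    if (pr$errno == 1) {
      expect_equal(mine$status, "optimal")
      expect_lt(abs(mine$objective_value - pr$fval),
                1e-6 * (1 + abs(pr$fval)))
    } else {
      expect_equal(mine$status, "infeasible")
    }
  }
  expect_gt(checked, 100)
})

test_that("optimal solutions satisfy their constraints tightly", {
  set.seed(7)
  for (t in 1:20) {
    n <- 6
    A <- matrix(sample(-2:2, 3 * n, replace = TRUE), 3, n)
    b <- as.vector(A %*% runif(n, 0, 2))
    r <- solve(linear_program(runif(n, -1, 1), A, b, lower = rep(0, n),
                              upper = rep(50, n)))
    expect_equal(r$status, "optimal")
    expect_true(all(abs(A %*% r$values - b) <= 1e-8 * (1 + abs(b))))
    expect_true(all(r$values >= -1e-10 & r$values <= 50 + 1e-10))
  }
})

test_that("row scaling does not change solvability", {
  A <- rbind(c(1, 1, 0), c(0, 1, -1))
  b <- c(4, 1)
  base <- solve(linear_program(c(1, 0, 0), A, b, upper = rep(10, 3)))
  for (s in c(1e-4, 1, 1e5)) {
    r <- solve(linear_program(c(1, 0, 0), A * s, b * s, upper = rep(10, 3)))
    expect_equal(r$status, base$status)
    expect_equal(r$objective_value, base$objective_value, tolerance = 1e-8)
  }
})

test_that("solver output is deterministic", {
  A <- rbind(c(1, 2, 1, 0), c(0, 1, -1, 2))
  lp <- linear_program(c(1, -1, 2, 0), A, c(3, 1), upper = rep(10, 4))
  r1 <- solve(lp)
  r2 <- solve(lp)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$objective_value, r2$objective_value)
})

test_that("check_feasibility matches full solves", {
  expect_true(check_feasibility(
    linear_program(0, matrix(1, 1, 1), 1, upper = 2)))
  expect_false(check_feasibility(
    linear_program(0, matrix(1, 1, 1), 3, upper = 2)))
  # objective is irrelevant for feasibility
  expect_true(check_feasibility(
    linear_program(100, matrix(1, 1, 1), 1, upper = 2, maximize = TRUE)))
})

test_that("small MILPs agree with exhaustive enumeration", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (t in 1:12) {
    # min sum(delta) s.t. C x = b, 0 <= x <= U delta, delta binary
    nx <- sample(3:5, 1)
    C <- matrix(sample(-2:2, 2 * nx, replace = TRUE), 2, nx)
    xtrue <- ifelse(runif(nx) < 0.6, runif(nx, 0.5, 2), 0)
    b <- as.vector(C %*% xtrue)
    U <- 100
    A_eq <- rbind(cbind(C, matrix(0, 2, 2 * nx)),
                  cbind(diag(nx), diag(-U, nx), diag(nx)))
    lp <- linear_program(
      c(rep(0, nx), rep(1, nx), rep(0, nx)),
      A_eq, c(b, rep(0, nx)),
      lower = rep(0, 3 * nx),
      upper = c(rep(U, nx), rep(1, nx), rep(Inf, nx)),
      integer = c(rep(FALSE, nx), rep(TRUE, nx), rep(FALSE, nx)))
    got <- solve(lp)
    # oracle: smallest subset of columns giving a feasible nonnegative
    # solution, by exhaustive subset search with the independent solver
    best <- Inf
    for (mask in 0:(2^nx - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(nx) - 1)) > 0)
      f <- oracle_feasible(C[, S, drop = FALSE], b, rep(U, length(S)))
      if (isTRUE(f)) best <- min(best, length(S))
    }
    expect_equal(got$status, "optimal")
    expect_equal(got$objective_value, best, tolerance = 1e-9)
  }
})
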