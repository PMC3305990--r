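# Realization algorithms: dense LP sweep, core-reaction feasibility test,
# sparse MILP, enumeration and structural uniqueness, verified against
# exhaustive subset enumeration on small instances.

test_that("a single-reaction network is completely rigid", {
  net <- single_reaction_net(rate = 2.5)
  expect_equal(edge_max_rate(net, "X1", "X2"), 2.5, tolerance = 1e-9)
  d <- dense_realization(net)
  expect_true(same_support(d$support, support(net)))
  s <- sparse_realization(net, dense = d)
  expect_equal(s$cardinality, 1L)
  co <- core_reactions(net, dense = d)
  expect_equal(nrow(co$core), 1)
  expect_equal(nrow(co$non_core), 0)
  expect_true(is_structure_unique(net)$unique)
})

test_that("edge maxima scale linearly with the dynamics", {
  net1 <- example_positive_feedback()
  k2 <- c(1e7, 1e7, 1e7, 1e7, 1.7, 0.025, 0.1, 0.05, 0.5) * 2
  net2 <- example_positive_feedback(rates = k2)
  f1 <- edge_max_rate(net1, "X2", "2 X1")
  f2 <- edge_max_rate(net2, "X2", "2 X1")
  expect_equal(f2, 2 * f1, tolerance = 1e-7)
  # every original reaction fits inside the dense structure
  rx <- reactions(net1)
  for (i in seq_len(nrow(rx))) {
    expect_gt(edge_max_rate(net1, rx$source[i], rx$target[i]), 0)
  }
})

test_that("full exclusion pins the dense realization to the original", {
  net <- example_positive_feedback()
  m <- length(net$complexes)
  all_pairs <- expand.grid(si = seq_len(m), ti = seq_len(m))
  all_pairs <- all_pairs[all_pairs$si != all_pairs$ti, ]
  keys <- paste(net$complexes[all_pairs$si], "->", net$complexes[all_pairs$ti])
  orig <- support(net)
  excl <- setdiff(keys, paste(orig$source, "->", orig$target))
  d <- dense_realization(net, exclude = excl)
  expect_true(same_support(d$support, orig))
  expect_true(is_structure_unique(net, exclude = excl)$unique)
})

test_that("infeasible constrained problems raise a distinct error", {
  net <- single_reaction_net()
  expect_error(dense_realization(net, exclude = "X1 -> X2"),
               "not realizable")
  expect_error(edge_max_rate(net, "X1", "X2", exclude = "X1 -> X2"),
               "excluded")
})

test_that("small-instance results match exhaustive subset enumeration", {
  skip_if_not_installed("pracma")
  net <- redundant_small_net()
  prob_labels <- net$complexes
  d <- dense_realization(net)
  co <- core_reactions(net, dense = d)
  sp <- sparse_realization(net, dense = d)
  en <- enumerate_sparse_supports(net, dense = d)

  # exhaustive per-column analysis with the independent oracle
  total_min <- 0L
  oracle_core <- character(0)
  oracle_dense <- character(0)
  col_minimals <- list()
  for (q in seq_along(prob_labels)) {
    bf <- brute_force_column(net, q)
    total_min <- total_min + bf$min_size
    oracle_core <- c(oracle_core,
                     key_pairs(prob_labels[q], prob_labels[bf$core_targets]))
    oracle_dense <- c(oracle_dense,
                      key_pairs(prob_labels[q], prob_labels[bf$dense_targets]))
    col_minimals[[q]] <- bf$minimal_targets
  }
  expect_equal(sort(paste(d$support$source, "->", d$support$target)),
               sort(oracle_dense))
  expect_equal(sp$cardinality, total_min)
  expect_equal(sort(paste(co$core$source, "->", co$core$target)),
               sort(oracle_core))
  expect_equal(length(en), prod(pmax(1, lengths(col_minimals))))
})

test_that("the redundant fixture shows dense > sparse with alternatives", {
  net <- redundant_small_net()
  d <- dense_realization(net)
  sp <- sparse_realization(net, dense = d)
  en <- enumerate_sparse_supports(net, dense = d)
  expect_gt(nrow(d$support), sp$cardinality)
  expect_gt(length(en), 1)
  expect_false(is_structure_unique(net)$unique)
  # the original structure must be among the minimal ones
  expect_true(any(vapply(en, same_support, logical(1), support(net))))
})

test_that("dense support is invariant to complex order and bound scale", {
  net <- example_positive_feedback()
  d <- dense_realization(net)
  # same model entered with the reaction list in reverse order
  rx <- reactions(net)
  net_rev <- crn(rx[rev(seq_len(nrow(rx))), ], species = net$species)
  d_rev <- dense_realization(net_rev)
  expect_true(same_support(d$support, d_rev$support))
  # a 10x larger upper bound must not flip any membership decision
  d_u <- dense_realization(net, ubound = 10 * d$ubound)
  expect_true(same_support(d$support, d_u$support))
})

test_that("exclusions shrink dense supports and never reduce hardness", {
  net <- redundant_small_net()
  d0 <- dense_realization(net)
  s0 <- sparse_realization(net, dense = d0)
  # exclude one non-core dense edge at a time
  co <- core_reactions(net, dense = d0)
  for (i in seq_len(nrow(co$non_core))) {
    excl <- paste(co$non_core$source[i], "->", co$non_core$target[i])
    d1 <- dense_realization(net, exclude = excl)
    expect_true(all(paste(d1$support$source, "->", d1$support$target) %in%
                      paste(d0$support$source, "->", d0$support$target)))
    s1 <- sparse_realization(net, exclude = excl, dense = d1)
    expect_gte(s1$cardinality, s0$cardinality)
  }
})

test_that("random small networks satisfy the structural laws", {
  for (seed in 1:8) {
    net <- random_small_net(seed)
    d <- dense_realization(net)
    sp <- sparse_realization(net, dense = d)
    co <- core_reactions(net, dense = d)
    dk <- paste(d$support$source, "->", d$support$target)
    # the original structure is a subgraph of the dense one
    orig <- support(net)
    expect_true(all(paste(orig$source, "->", orig$target) %in% dk),
                label = paste("P1 original seed", seed))
    # sparse sits inside dense, core inside sparse
    sk <- paste(sp$support$source, "->", sp$support$target)
    ck <- paste(co$core$source, "->", co$core$target)
    expect_true(all(sk %in% dk), label = paste("P1 sparse seed", seed))
    expect_true(all(ck %in% sk), label = paste("core seed", seed))
    # returned realizations are dynamically equivalent to the input
    expect_true(check_dynamical_equivalence(net, d$network, tol = 1e-6))
    expect_true(check_dynamical_equivalence(net, sp$network, tol = 1e-6))
    # column conservation of solver-built Kirchhoff matrices
    for (A in list(d$network$A, sp$network$A)) {
      expect_lt(max(abs(colSums(A))), 1e-8 * max(1, max(abs(A))))
    }
  }
})

test_that("realization results are deterministic", {
  net <- random_small_net(3)
  d1 <- dense_realization(net)
  d2 <- dense_realization(net)
  expect_identical(d1$support, d2$support)
  expect_identical(d1$network$A, d2$network$A)
  e1 <- enumerate_sparse_supports(net)
  e2 <- enumerate_sparse_supports(net)
  expect_identical(e1, e2)
})
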