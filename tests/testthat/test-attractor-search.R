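test_that("inhibitory degree counts in- plus out-edges, self-loops once", {
  # no inhibitory edges at all
  act_only <- signed_network(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_identical(inhibitory_degree(act_only), c(0L, 0L))
  # mutual inhibition: one in-edge and one out-edge each
  expect_identical(inhibitory_degree(mutual_inhibition_net()), c(2L, 2L))
  # a pure self-inhibition loop is one connection, not two
  expect_identical(inhibitory_degree(signed_network(matrix(-1L, 1, 1))), 1L)
  expect_error(inhibitory_degree(mutual_inhibition_net(), 3), "out of range")
})

test_that("yeast inhibitory-degree ranking is consistent with the known branch order", {
  deg <- inhibitory_degree(yeast_net())
  # the cell-cycle search visits nodes in the order below; inhibitory degree
  # must be non-increasing along it (ties may order arbitrarily)
  visit_order <- c(10, 9, 8, 5, 7, 4, 6, 3, 2, 11, 1)
  expect_true(all(diff(deg[visit_order]) <= 0))
  expect_equal(which.max(deg), 10L)
})

test_that("branch node selection maximises inhibitory degree, ties to lowest index", {
  net <- yeast_net()
  s <- rep(NA_integer_, 11); s[1] <- 0L
  expect_equal(select_branch_node(net, s), 10L)
  # all degrees zero: tie broken by smallest undetermined index
  ne <- empty_net(6)
  s <- rep(0L, 6); s[c(2, 5)] <- NA
  expect_equal(select_branch_node(ne, s), 2L)
  # a single unknown node is returned regardless of degree
  s <- rep(1L, 6); s[4] <- NA
  expect_equal(select_branch_node(ne, s), 4L)
  expect_error(select_branch_node(ne, rep(0L, 6)), "no undetermined")
})

test_that("fixed-point propagation reproduces the cell-cycle worked cases", {
  net <- yeast_net()

  # from full ignorance only the node with a bare self-degradation loop and
  # no activator can be pinned (it must be off)
  p <- propagate(net, strrep("?", 11))
  expect_equal(p$status, "consistent")
  expect_equal(format_state(p$state), "0??????????")
  expect_true(any(p$fired$rule == "5" & p$fired$node == 1L))

  # S1 = 0, S10 = 1 is contradictory: activating 10 forces 7 on, which
  # inhibits 10 back off
  s <- rep(NA_integer_, 11); s[1] <- 0L; s[10] <- 1L
  expect_equal(propagate(net, s)$status, "contradiction")

  # S1 = 0, S9 = 1, S10 = 0 cascades to exactly two free nodes (2 and 5)
  s <- rep(NA_integer_, 11); s[1] <- 0L; s[9] <- 1L; s[10] <- 0L
  p <- propagate(net, s)
  expect_equal(p$status, "consistent")
  expect_equal(format_state(p$state), "0?00?000100")

  # no premise can fire on an empty network
  p <- propagate(empty_net(5), "1??0?")
  expect_equal(p$status, "consistent")
  expect_equal(format_state(p$state), "1??0?")
  expect_equal(nrow(p$fired), 0L)
})

test_that("propagation is monotone: determined values never flip, l0 never grows", {
  for (seed in 1:30) {
    n <- sample(4:10, 1)
    net <- rand_net(n, sample(1:5, 1), runif(1), seed = 400 + seed)
    s <- rep(NA_integer_, n)
    fix <- sample(n, sample(0:n, 1))
    s[fix] <- sample(0:1, length(fix), replace = TRUE)
    p <- propagate(net, s)
    if (p$status == "consistent") {
      known <- !is.na(s)
      expect_identical(p$state[known], s[known])
      expect_lte(sum(is.na(p$state)), sum(is.na(s)))
    }
  }
})

test_that("propagation is sound: every determination is entailed by the fixed points", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    net <- rand_net(n, sample(1:4, 1), runif(1, 0.2, 0.8), seed = 500 + seed)
    dec <- regulatory_decomposition(net)
    s <- rep(NA_integer_, n)
    fix <- sample(n, sample(0:2, 1))
    s[fix] <- sample(0:1, length(fix), replace = TRUE)
    p <- propagate(dec, s)

    # brute-force completions of s that are fixed points
    S <- sibnet:::all_states(n)
    ok <- rep(TRUE, nrow(S))
    for (j in which(!is.na(s))) ok <- ok & (S[, j] == s[j])
    fixed <- ok & (rowSums(sibnet:::si_step_matrix(dec, S) != S) == 0L)

    if (p$status == "contradiction") {
      expect_equal(sum(fixed), 0L)
    } else if (any(fixed)) {
      for (j in which(!is.na(p$state))) {
        expect_true(all(S[fixed, j] == p$state[j]))
      }
    }
  }
})

test_that("enumeration handles degenerate networks exactly", {
  # every state of an edgeless network is fixed
  for (n in c(2, 4, 6)) {
    res <- enumerate_singleton_attractors(empty_net(n))
    expect_equal(length(res$bitstrings), 2^n)
    expect_false(res$capped)
  }
  # mutual inhibition: all but (1,1)
  res <- enumerate_singleton_attractors(mutual_inhibition_net())
  expect_equal(res$bitstrings, c("00", "01", "10"))
  # single self-inhibited / self-activated node
  expect_equal(brute_force_singleton_attractors(
    signed_network(matrix(-1L, 1, 1)))$bitstrings, "0")
  expect_equal(brute_force_singleton_attractors(
    signed_network(matrix(1L, 1, 1)))$bitstrings, "1")
  expect_equal(enumerate_singleton_attractors(
    signed_network(matrix(-1L, 1, 1)))$bitstrings, "0")
  expect_equal(enumerate_singleton_attractors(
    signed_network(matrix(1L, 1, 1)))$bitstrings, "1")
})

test_that("rule-based enumeration equals the brute-force oracle on random networks", {
  for (seed in 1:60) {
    n <- sample(4:10, 1)
    net <- rand_net(n, sample(c(1, 2, 3, 5), 1),
                    sample(c(0.2, 0.4, 0.8), 1), seed = 600 + seed)
    fast <- enumerate_singleton_attractors(net)
    slow <- brute_force_singleton_attractors(net)
    expect_identical(fast$bitstrings, slow$bitstrings)
    expect_false(any(duplicated(fast$bitstrings)))
    expect_equal(fast$stats$found, length(fast$bitstrings))
  }
})

test_that("the brute-force oracle refuses oversized networks", {
  big <- empty_net(25)
  expect_error(brute_force_singleton_attractors(big), "max_nodes")
})

test_that("the attractor cap stops the search and flags the result", {
  res <- enumerate_singleton_attractors(empty_net(8), max_attractors = 10)
  expect_true(res$capped)
  expect_equal(length(res$bitstrings), 10L)
})

test_that("search effort grows with the number of attractors across an ensemble", {
  ns <- integer(); eff <- integer()
  for (seed in 1:40) {
    net <- rand_net(10, 3, 0.4, seed = 700 + seed)
    res <- enumerate_singleton_attractors(net)
    ns <- c(ns, length(res$bitstrings))
    eff <- c(eff, res$stats$nodes_expanded)
  }
  expect_gt(stats::cor(ns, eff), 0.5)
})
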