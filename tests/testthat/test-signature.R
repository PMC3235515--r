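test_that("count_words matches hand-enumerated double-stranded counts", {
  # "ACGT" is its own reverse complement: every window is seen twice
  ct <- count_words("ACGT", k = 2)
  expect_equal(ct$node_counts[["AC"]], 2)
  expect_equal(ct$node_counts[["CG"]], 2)
  expect_equal(ct$node_counts[["GT"]], 2)
  expect_equal(sum(ct$node_counts), 6)
  expect_equal(ct$edge_counts[["ACG"]], 2)
  expect_equal(ct$edge_counts[["CGT"]], 2)
  expect_equal(ct$total_edges, 4)

  ct <- count_words("AAAAA", k = 2)
  expect_equal(ct$node_counts[["AA"]], 4)
  expect_equal(ct$node_counts[["TT"]], 4)
  expect_equal(ct$edge_counts[["AAA"]], 3)
  expect_equal(ct$edge_counts[["TTT"]], 3)

  # too short for any (k+1)-window
  ct <- count_words("AC", k = 2)
  expect_equal(ct$node_counts[["AC"]], 1)
  expect_equal(ct$node_counts[["GT"]], 1)
  expect_equal(ct$total_edges, 0)

  expect_error(count_words("ACGT", k = 0), "k must be")
})

test_that("counts are strand-symmetric and never span ambiguity splits", {
  set.seed(31)
  for (k in 2:4) {
    x <- random_acgt(800)
    ct <- count_words(x, k)
    for (counts in list(ct$node_counts, ct$edge_counts)) {
      rc <- vapply(names(counts), reverse_complement, character(1))
      expect_identical(unname(counts), unname(counts[rc]))
    }
  }
  # the N split removes the spanning windows
  ct <- count_words("ACGTNNACG", k = 2)
  ct2a <- count_words("ACGT", k = 2)
  ct2b <- count_words("ACG", k = 2)
  expect_equal(ct$edge_counts, ct2a$edge_counts + ct2b$edge_counts)
})

test_that("build_chain reproduces the hand-built homopolymer chain", {
  chain <- build_chain(count_words("AAAAA", k = 2), lambda = 0.01)
  expect_setequal(chain$nodes, c("AA", "TT"))
  expect_equal(chain$P_raw["AA", "AA"], 1)
  expect_equal(chain$P_raw["TT", "TT"], 1)
  expect_equal(length(chain$component_mass), 2)
  expect_equal(unname(sort(chain$component_mass)), c(0.5, 0.5))
  # two distinct singleton components
  expect_equal(length(unique(chain$membership)), 2)
})

test_that("damped rows sum to 1 and component masses sum to 1", {
  set.seed(57)
  for (k in 2:4) {
    chain <- build_chain(count_words(random_acgt(1200), k), lambda = 0.01)
    expect_lt(max(abs(rowSums(chain$P) - 1)), 1e-12)
    expect_lt(abs(sum(chain$component_mass) - 1), 1e-12)
    expect_true(all(chain$P >= 0))
  }
  expect_error(build_chain(count_words("AC", 2)), "too short")
  expect_error(build_chain(count_words("ACGTAC", 2), lambda = 0),
               "lambda")
})

test_that("uniform edge counts give the uniform chain over all words", {
  k <- 2
  counts <- structure(list(
    k = k,
    node_counts = stats::setNames(rep(8L, 4^k), dbcbin:::kmer_words(k)),
    edge_counts = stats::setNames(rep(2L, 4^(k + 1)),
                                  dbcbin:::kmer_words(k + 1)),
    total_edges = 2L * 4^(k + 1)), class = "kmer_count_table")
  chain <- build_chain(counts, lambda = 0.01)
  expect_equal(length(chain$nodes), 4^k)
  # raw rows: 1/4 on each of the 4 legal successors
  expect_true(all(abs(chain$P_raw[chain$P_raw > 0] - 0.25) < 1e-15))
  expect_equal(unname(chain$component_mass), 1)
  pi_vec <- stationary_distribution(chain)
  expect_lt(max(abs(pi_vec - 4^(-k))), 1e-12)
  expect_equal(unname(connectivity_weights(chain)), rep(1, 4^k))
})

test_that("strongly connected components agree with a BFS oracle", {
  set.seed(83)
  for (rep in 1:5) {
    k <- sample(2:3, 1)
    ct <- count_words(paste0(random_acgt(60), "NN", random_acgt(60)), k)
    chain <- build_chain(ct)
    e <- ct$edge_counts[ct$edge_counts > 0]
    oracle <- scc_oracle(chain$nodes, substr(names(e), 1, k),
                         substr(names(e), 2, k + 1))
    # same partition: membership labels may differ, the grouping must not
    expect_equal(length(unique(chain$membership)), length(unique(oracle)))
    expect_true(all(tapply(oracle[chain$nodes], chain$membership,
                           function(g) length(unique(g))) == 1))
  }
})

test_that("power iteration matches the eigen-decomposition oracle", {
  set.seed(29)
  for (k in 2:4) {
    for (rep in 1:5) {
      chain <- build_chain(count_words(random_acgt(1500), k))
      pi_vec <- stationary_distribution(chain, tol = 1e-12)
      expect_true(all(pi_vec >= 0))
      expect_lt(abs(sum(pi_vec) - 1), 1e-12)
      # stationarity residual
      expect_lt(max(abs(as.vector(pi_vec %*% chain$P) - pi_vec)), 1e-10)
      # independent oracle
      expect_lt(max(abs(pi_vec - stationary_eigen_oracle(chain$P))), 1e-8)
    }
  }
  # the homopolymer chain has the exchange-symmetric stationary law
  chain <- build_chain(count_words("AAAAA", 2), lambda = 0.3)
  pi_vec <- stationary_distribution(chain)
  expect_equal(unname(pi_vec[c("AA", "TT")]), c(0.5, 0.5), tolerance = 1e-12)
  # iteration cap is an error, never a silent truncation
  set.seed(30)
  slow <- build_chain(count_words(random_acgt(500), 3))
  expect_error(stationary_distribution(slow, tol = 1e-12, max_iter = 3),
               "did not converge")
})

test_that("connectivity weights equal the component mass of each node", {
  ct <- count_words("AAAAA", 2)
  chain <- build_chain(ct)
  w <- connectivity_weights(chain)
  expect_equal(unname(w[c("AA", "TT")]), c(0.5, 0.5))
  # weights constant within a component, equal to the stored mass
  set.seed(11)
  chain <- build_chain(count_words(random_acgt(400), 3))
  w <- connectivity_weights(chain)
  expect_equal(unname(w),
               unname(chain$component_mass[as.character(chain$membership)]))
})

test_that("compute_signature reproduces the worked homopolymer example", {
  s <- compute_signature("AAAAA", k = 2)
  expect_equal(sum(s$s > 0), 2)
  expect_equal(s$s[["AA"]], 0.5)
  expect_equal(s$s[["TT"]], 0.5)
  expect_equal(length(s$s), 16)
  expect_error(compute_signature("AC", k = 2), class = "dbcbin_unsignable")
})

test_that("signatures are strand-invariant, non-negative and sum to 1", {
  set.seed(63)
  for (i in 1:8) {
    x <- random_acgt(sample(500:5000, 1))
    for (k in 2:4) {
      s <- compute_signature(x, k)
      expect_true(all(s$s >= 0))
      expect_lt(abs(sum(s$s) - 1), 1e-9)
      s_rc <- compute_signature(reverse_complement(x), k)
      expect_lt(max(abs(s$s - s_rc$s)), 1e-12)
    }
  }
})

test_that("signature_distance is a symmetric metric with analytic values", {
  set.seed(5)
  a <- compute_signature(random_acgt(900), 3)
  b <- compute_signature(random_acgt(900), 3)
  expect_equal(signature_distance(a, a), 0)
  expect_equal(signature_distance(a, b), signature_distance(b, a))
  expect_gt(signature_distance(a, b), 0)
  # unit masses on two different words are sqrt(2) apart
  ua <- c(1, rep(0, 15)); ub <- c(0, 1, rep(0, 14))
  expect_equal(signature_distance(ua, ub), sqrt(2))
  expect_equal(signature_distance(ua, ub, metric = "cosine"), 1)
  c4 <- compute_signature(random_acgt(900), 2)
  expect_error(signature_distance(a, c4), "order mismatch")
})

test_that("signatures separate generating models on seeded fragments", {
  # fragments of one compositional model cluster together: two disjoint
  # 50 kb fragments of one model are closer to each other than to any
  # fragment of the other model
  models <- make_models(2, separation = 0.6, seed = 301)
  frags <- lapply(1:2, function(mi) lapply(1:2, function(fi) {
    compute_signature(
      generate_genome(models[[mi]], 50000, seed = 301 + 10 * mi + fi)$sequence,
      k = 3)
  }))
  d_intra <- c(signature_distance(frags[[1]][[1]], frags[[1]][[2]]),
               signature_distance(frags[[2]][[1]], frags[[2]][[2]]))
  d_inter <- c(signature_distance(frags[[1]][[1]], frags[[2]][[1]]),
               signature_distance(frags[[1]][[1]], frags[[2]][[2]]),
               signature_distance(frags[[1]][[2]], frags[[2]][[1]]),
               signature_distance(frags[[1]][[2]], frags[[2]][[2]]))
  expect_lt(max(d_intra), min(d_inter))
})
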