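test_that("binomial tip conditionals match hand-computed masses", {
  sp <- enumerate_states(4)
  # monomorphic observation (4,0,0,0), S = 4
  v <- tip_conditionals(c(4, 0, 0, 0), sp)
  expect_equal(v[state_index_mono(sp, "A")], 1)
  expect_equal(v[state_index_mono(sp, "C")], 0)
  expect_equal(v[state_index_poly(sp, "AC", 2)], (2 / 4)^4)  # 0.0625
  expect_equal(v[state_index_poly(sp, "AT", 3)], (3 / 4)^4)
  expect_equal(v[state_index_poly(sp, "CG", 2)], 0)
  # biallelic observation (1,1,0,0), S = 2
  v2 <- tip_conditionals(c(1, 1, 0, 0), sp)
  expect_equal(v2[state_index_poly(sp, "AC", 1)], 2 * (1 / 4) * (3 / 4))
  expect_equal(v2[state_index_poly(sp, "AC", 2)], 2 * (2 / 4) * (2 / 4))
  expect_equal(sum(v2[1:4]), 0)
  expect_equal(v2[state_index_poly(sp, "AG", 1)], 0)
  # missing site: no information
  expect_equal(tip_conditionals(c(0, 0, 0, 0), sp), rep(1, 22))
  # three observed alleles are outside the biallelic state space
  expect_error(tip_conditionals(c(1, 1, 1, 0), sp), "two")
})

test_that("pattern compression merges duplicates and preserves likelihood", {
  set.seed(10)
  tree <- tiny_tree(3)
  pp <- random_params(4)
  ct <- simulate_counts(tree, pp, 15, sample_size = 4)
  # duplicate the table rows to force repeated patterns
  idx <- rep(seq_len(15), 3)
  ct2 <- counts_table(ct$counts[idx, , , drop = FALSE], ct$pops)
  pat <- compress_patterns(ct2)
  expect_lte(length(pat$weights), 15)
  expect_equal(sum(pat$weights), 45)
  # uncompressed = one-row-at-a-time sum
  f <- likelihood_engine(pat, tree, 4)
  ll_pat <- f(pp)
  ll_site <- 0
  for (i in seq_len(45)) {
    pi1 <- compress_patterns(counts_table(ct2$counts[i, , , drop = FALSE],
                                          ct2$pops))
    ll_site <- ll_site + likelihood_engine(pi1, tree, 4)(pp)
  }
  expect_equal(ll_pat, ll_site, tolerance = 1e-10)
})

test_that("pruning equals joint-state brute force on small trees (N=2)", {
  set.seed(11)
  for (r in 1:12) {
    nl <- sample(2:3, 1)
    tree <- tiny_tree(nl)
    pp <- random_params(2, B = 1)
    ct <- simulate_counts(tree, pp, 3, sample_size = 3)
    pat <- compress_patterns(ct)
    f <- likelihood_engine(pat, tree, 2)
    expect_equal(f(pp), brute_force_loglik(tree, pp, pat),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to child order and collapses on a star", {
  set.seed(12)
  pp <- random_params(4)
  t1 <- ape::read.tree(text = "((A:1.2,B:0.4):0.8,C:1.5);")
  t2 <- ape::read.tree(text = "(C:1.5,(B:0.4,A:1.2):0.8);")
  ct <- simulate_counts(t1, pp, 25, sample_size = 6, seed = 5)
  pat <- compress_patterns(ct)
  expect_equal(likelihood_engine(pat, t1, 4)(pp),
               likelihood_engine(pat, t2, 4)(pp), tolerance = 1e-10)
  # zero branch lengths: likelihood independent of internal topology
  t3 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  t4 <- ape::read.tree(text = "((A:0,C:0):0,B:0);")
  expect_equal(likelihood_engine(pat, t3, 4)(pp),
               likelihood_engine(pat, t4, 4)(pp), tolerance = 1e-10)
})

test_that("single-leaf likelihood is log(psi . tip conditional)", {
  sp <- enumerate_states(4)
  pp <- pomo_params(4, pi = rep(.25, 4), rho = rep(.1, 6))
  Q <- build_rate_matrix(sp, pp)
  psi <- stationary_distribution(Q)
  ct <- ct_from_list(list(rbind(c(2, 2, 0, 0))), "A")
  tree <- ape::read.tree(text = "(A:0);")
  f <- likelihood_engine(compress_patterns(ct), tree, 4)
  expected <- log(sum(psi * tip_conditionals(c(2, 2, 0, 0), sp)))
  expect_equal(f(pp), expected, tolerance = 1e-12)
})

test_that("divergence from a matched monomorphic tip lowers the site likelihood", {
  # with S = N monomorphic data at both tips of a cherry, mixing toward
  # stationarity can only dilute the match
  pp <- pomo_params(4, pi = rep(.25, 4), rho = rep(.1, 6))
  ct <- ct_from_list(list(rbind(c(4, 0, 0, 0), c(4, 0, 0, 0))), c("A", "B"))
  pat <- compress_patterns(ct)
  ll <- sapply(c(0, 0.5, 2, 10), function(b) {
    tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", b, b))
    likelihood_engine(pat, tree, 4)(pp)
  })
  expect_true(all(diff(ll) < 0))
})
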