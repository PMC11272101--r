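test_that("with mu = 0 a fixed monomorphic root is absorbing", {
  tree <- ape::read.tree(text = "((A:3,B:3):3,C:6);")
  pp <- pomo_params(4, mu = rep(0, 12))
  ct <- simulate_counts(tree, pp, 30, root_state = "A", seed = 2)
  expect_true(all(ct$counts[, , 1] == 4))
  expect_true(all(ct$counts[, , 2:4] == 0))
})

test_that("a long single branch reaches the stationary state distribution", {
  set.seed(21)
  pp <- pomo_params(4, pi = c(.4, .3, .2, .1), rho = rep(.08, 6),
                    sigma = .1, beta = 2, B = 2, mode = "balance")
  sp <- enumerate_states(4)
  Q <- build_rate_matrix(sp, pp)
  psi <- stationary_distribution(Q)
  tree <- ape::read.tree(text = "(A:1);")  # root drawn from psi already
  L <- 50000
  ct <- simulate_counts(tree, pp, L)
  # classify each site back to its state index
  emp <- numeric(sp$n_states)
  for (i in seq_len(L)) {
    v <- ct$counts[i, 1, ]
    nz <- which(v > 0)
    if (length(nz) == 1) {
      emp[nz] <- emp[nz] + 1
    } else {
      pair <- paste0(c("A", "C", "G", "T")[nz], collapse = "")
      emp[state_index_poly(sp, pair, v[nz[1]])] <- 1 +
        emp[state_index_poly(sp, pair, v[nz[1]])]
    }
  }
  phat <- emp / L
  se <- sqrt(psi * (1 - psi) / L)
  expect_true(all(abs(phat - psi) < 3 * se + 3 / L))
})

test_that("gillespie branch sampling agrees with the matrix exponential law", {
  set.seed(22)
  sp <- enumerate_states(3)
  pp <- pomo_params(3, pi = rep(.25, 4), rho = rep(.3, 6), sigma = .2,
                    beta = 2, B = 1, mode = "balance")
  Q <- build_rate_matrix(sp, pp)
  t <- 0.5
  start <- state_index_poly(sp, "AC", 1)
  nrep <- 20000
  ends <- replicate(nrep, gillespie_branch(start, Q, t))
  expected <- transition_probabilities(Q, t)[start, ]
  obs <- tabulate(ends, nbins = sp$n_states)
  keep <- expected > 5 / nrep
  chi <- suppressWarnings(
    chisq.test(obs[keep], p = expected[keep] / sum(expected[keep])))
  expect_gt(chi$p.value, 0.01)
  # trivial cases
  expect_equal(gillespie_branch(start, Q, 0), start)
  Q0 <- build_rate_matrix(sp, pomo_params(3, mu = rep(0, 12)))
  expect_equal(gillespie_branch(1, Q0, 100), 1)
})

test_that("binomial downsampling has the right mean and monomorphic tail", {
  set.seed(23)
  # Poly(AC, 2) at N = 4, S = 4: P(sample monomorphic) = 2 * (1/2)^4
  ct <- ct_from_list(rep(list(rbind(c(2, 2, 0, 0))), 10000), "A")
  ds <- binomial_downsample(ct, 4)
  tots <- ds$counts[, 1, ]
  expect_true(all(rowSums(tots) == 4))
  mono <- mean(tots[, 1] == 4 | tots[, 2] == 4)
  se <- sqrt(0.125 * 0.875 / 10000)
  expect_lt(abs(mono - 0.125), 4 * se)
  # mean first-allele count = S * n / N
  expect_lt(abs(mean(tots[, 1]) - 2), 4 * sqrt(4 * .5 * .5 / 10000))
  # monomorphic input stays monomorphic at any S
  ctm <- ct_from_list(list(rbind(c(0, 4, 0, 0))), "A")
  expect_equal(binomial_downsample(ctm, 7)$counts[1, 1, ], c(A = 0, C = 7, G = 0, T = 0))
})

test_that("zero-length tree copies the root state to every leaf", {
  tree <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  pp <- random_params(4)
  ct <- simulate_counts(tree, pp, 50, seed = 3)
  for (i in 1:50) {
    expect_equal(ct$counts[i, 1, ], ct$counts[i, 2, ])
    expect_equal(ct$counts[i, 1, ], ct$counts[i, 3, ])
  }
})

test_that("simulated SFS shows an interior peak only under balancing selection", {
  set.seed(24)
  tree <- ape::read.tree(text = "(A:1);")
  base <- list(pi = rep(.25, 4), rho = rep(.05, 6))
  pp_neutral <- pomo_params(6, pi = base$pi, rho = base$rho,
                            beta = 1, B = 2, mode = "balance")
  pp_bs <- pomo_params(6, pi = base$pi, rho = base$rho,
                       beta = 5, B = 2, mode = "balance")
  L <- 40000
  sfs_n <- empirical_sfs(simulate_counts(tree, pp_neutral, L), 6)
  sfs_b <- empirical_sfs(simulate_counts(tree, pp_bs, L), 6)
  pool_n <- colSums(sfs_n$poly)
  pool_b <- colSums(sfs_b$poly)
  # neutral: U-shape, no interior peak at 2
  expect_false(pool_n[2] > pool_n[1] && pool_n[2] > pool_n[3])
  # strong BS with common B = 2: mass at 2 beats both neighbours
  expect_gt(pool_b[2], pool_b[1])
  expect_gt(pool_b[2], pool_b[3])
})
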