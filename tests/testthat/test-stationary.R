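test_that("transition probabilities are stochastic and satisfy Chapman-Kolmogorov", {
  set.seed(3)
  sp <- enumerate_states(4)
  Q <- build_rate_matrix(sp, random_params(4))
  P0 <- transition_probabilities(Q, 0)
  expect_equal(unname(P0), diag(sp$n_states))
  for (t in c(0.3, 2, 50)) {
    P <- transition_probabilities(Q, t)
    expect_true(all(P >= -1e-12))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  Ps <- transition_probabilities(Q, 0.7)
  Pt <- transition_probabilities(Q, 1.6)
  Pst <- transition_probabilities(Q, 2.3)
  expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-9)
  expect_error(transition_probabilities(Q, -1), "nonnegative")
})

test_that("stationary distribution solves psi Q = 0 and matches exp(1e6 Q)", {
  set.seed(4)
  for (r in 1:5) {
    N <- sample(c(2, 4, 6), 1)
    Q <- build_rate_matrix(enumerate_states(N), random_params(N))
    psi <- stationary_distribution(Q)
    expect_equal(sum(psi), 1, tolerance = 1e-12)
    expect_true(all(psi >= 0))
    expect_lt(max(abs(psi %*% unclass(Q))), 1e-10)
    P <- transition_probabilities(Q, 1e6)
    expect_lt(max(abs(sweep(P, 2, psi))), 1e-6)
  }
})

test_that("fully symmetric neutral model gives an allele-permutation-invariant psi", {
  sp <- enumerate_states(6)
  pp <- pomo_params(6, pi = rep(.25, 4), rho = rep(.1, 6), sigma = 0)
  psi <- stationary_distribution(build_rate_matrix(sp, pp))
  expect_equal(unname(psi[1]), unname(psi[2]), tolerance = 1e-10)
  expect_equal(unname(psi[1]), unname(psi[4]), tolerance = 1e-10)
  # all pairs carry identical interior profiles, symmetric about N/2
  prof <- matrix(psi[-(1:4)], 6, 5, byrow = TRUE)
  for (p in 2:6) expect_equal(prof[1, ], prof[p, ], tolerance = 1e-10)
  expect_equal(prof[1, ], rev(prof[1, ]), tolerance = 1e-10)
})

test_that("raising beta_AC increases the stationary mass at Poly(AC, B)", {
  sp <- enumerate_states(6)
  B <- 2
  mass_at_B <- function(beta_ac) {
    pp <- pomo_params(6, pi = rep(.25, 4), rho = rep(.05, 6),
                      beta = c(beta_ac, rep(1, 5)), B = B, mode = "balance")
    psi <- stationary_distribution(build_rate_matrix(sp, pp))
    psi[state_index_poly(sp, "AC", B)]
  }
  expect_gt(mass_at_B(5), mass_at_B(1))
  # and the increase is monotone along 1, 2, 5
  expect_gt(mass_at_B(2), mass_at_B(1))
  expect_gt(mass_at_B(5), mass_at_B(2))
})

test_that("disconnected alleles raise a degeneracy error naming them", {
  # rho = 0 for every pair containing T isolates the T boundary state
  rho <- c(AC = .1, AG = .1, AT = 0, CG = .1, CT = 0, GT = 0)
  pp <- pomo_params(4, pi = rep(.25, 4), rho = unname(rho))
  Q <- build_rate_matrix(enumerate_states(4), pp)
  expect_error(stationary_distribution(Q), "T")
})

test_that("detailed balance holds exactly when B = N/2 with symmetric rho", {
  sp <- enumerate_states(6)
  # balancing model, B = N/2 = 3: reversible even with GC bias
  ppr <- pomo_params(6, pi = c(.3, .25, .25, .2), rho = rep(.07, 6),
                     sigma = 0.2, beta = c(2, 1.5, 3, 2, 2, 2.5), B = 3,
                     mode = "balance")
  expect_lt(detailed_balance_residual(build_rate_matrix(sp, ppr)), 1e-10)
  # one B off the midpoint breaks reversibility
  ppn <- pomo_params(6, pi = c(.3, .25, .25, .2), rho = rep(.07, 6),
                     sigma = 0.2, beta = c(2, 1.5, 3, 2, 2, 2.5),
                     B = c(2, rep(3, 5)), mode = "balance")
  expect_gt(detailed_balance_residual(build_rate_matrix(sp, ppn)), 1e-6)
  # the selection-only model with symmetric rho is always reversible
  pps <- pomo_params(6, pi = c(.4, .2, .2, .2), rho = rep(.07, 6),
                     sigma = 0.3, mode = "select")
  expect_lt(detailed_balance_residual(build_rate_matrix(sp, pps)), 1e-10)
})
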