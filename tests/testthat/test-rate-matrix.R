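test_that("hand-derived N=4 entries match the drift/selection/balancing form", {
  sp <- enumerate_states(4)
  sigma <- 0.3
  beta_ac <- 1.7
  pp <- pomo_params(4, pi = rep(.25, 4), rho = rep(.1, 6),
                    phi = c(1, 1 + sigma, 1 + sigma, 1),
                    beta = c(beta_ac, rep(1, 5)), B = 2, mode = "balance")
  Q <- build_rate_matrix(sp, pp)
  i1 <- state_index_poly(sp, "AC", 1)
  i2 <- state_index_poly(sp, "AC", 2)
  i3 <- state_index_poly(sp, "AC", 3)
  # n=1 -> 2 moves toward B=2 and gains an A: (1*3/4) * phi_A * beta
  expect_equal(Q[i1, i2], (1 * 3 / 4) * 1 * beta_ac)
  # n=2 -> 3 moves away from B: (2*2/4) * phi_A * beta^0
  expect_equal(Q[i2, i3], (2 * 2 / 4) * 1 * 1)
  # n=2 -> 1 moves away from B but gains a C: drift * phi_C only
  expect_equal(Q[i2, i1], (2 * 2 / 4) * (1 + sigma))
  # n=3 -> 2 moves toward B and gains a C
  expect_equal(Q[i3, i2], (3 * 1 / 4) * (1 + sigma) * beta_ac)
})

test_that("monomorphic rows carry exactly the three boundary-mutation exits", {
  sp <- enumerate_states(5)
  pp <- random_params(5)
  Q <- build_rate_matrix(sp, pp)
  iA <- 1
  nz <- unname(which(Q[iA, ] > 0))
  expect_equal(sort(nz), sort(c(state_index_poly(sp, "AC", 4),
                                state_index_poly(sp, "AG", 4),
                                state_index_poly(sp, "AT", 4))))
  expect_equal(Q[iA, state_index_poly(sp, "AC", 4)], unname(pp$mu["AC"]))
  expect_equal(Q[iA, state_index_poly(sp, "AG", 4)], unname(pp$mu["AG"]))
  expect_equal(Q[iA, state_index_poly(sp, "AT", 4)], unname(pp$mu["AT"]))
  # and the T row exits into n = 1 states of pairs ending in T
  iT <- 4
  expect_equal(Q[iT, state_index_poly(sp, "AT", 1)], unname(pp$mu["TA"]))
})

test_that("rows sum to zero and long shifts are impossible", {
  set.seed(1)
  for (N in c(2, 4, 6, 9)) {
    sp <- enumerate_states(N)
    Q <- build_rate_matrix(sp, random_params(N))
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    # frequency shifts over 1 are strictly zero
    st <- sp$states
    for (i in seq_len(nrow(st))) for (j in seq_len(nrow(st))) {
      if (i == j) next
      ni <- if (st$type[i] == "mono") NA else st$n[i]
      nj <- if (st$type[j] == "mono") NA else st$n[j]
      same_pair <- !is.na(st$pair[i]) && !is.na(st$pair[j]) &&
        st$pair[i] == st$pair[j]
      if (same_pair && abs(ni - nj) > 1) expect_identical(Q[i, j], 0)
    }
  }
})

test_that("beta = 1 collapses the balancing model onto the selection model", {
  set.seed(7)
  for (r in 1:100) {
    N <- sample(2:8, 1)
    g <- rgamma(4, 1); pi <- g / sum(g)
    rho <- rexp(6, 5); sigma <- rexp(1, 5)
    sp <- enumerate_states(N)
    Qb <- build_rate_matrix(sp, pomo_params(N, pi = pi, rho = rho,
                                            sigma = sigma, beta = 1,
                                            B = sample(N - 1, 1),
                                            mode = "balance"))
    Qs <- build_rate_matrix(sp, pomo_params(N, pi = pi, rho = rho,
                                            sigma = sigma, mode = "select"))
    expect_identical(c(unclass(Qb)), c(unclass(Qs)))
  }
})

test_that("beta < 1 purges polymorphism: rates toward B fall below drift", {
  sp <- enumerate_states(6)
  pp <- pomo_params(6, pi = rep(.25, 4), rho = rep(.05, 6),
                    beta = 0.5, B = 3, mode = "balance")
  Q <- build_rate_matrix(sp, pp)
  for (p in c("AC", "GT")) {
    for (n in 1:5) {
      drift <- n * (6 - n) / 6
      i <- state_index_poly(sp, p, n)
      if (n < 3) {  # up-move toward B carries beta < 1
        j <- state_index_poly(sp, p, n + 1)
        expect_lt(Q[i, j], drift)
      }
      if (n > 3) {  # down-move toward B carries beta < 1
        j <- state_index_poly(sp, p, n - 1)
        expect_lt(Q[i, j], drift)
      }
    }
  }
})

test_that("the beta exponent of every assembled entry is 0 or 1", {
  # with beta prime and all other factors 1, entries must be drift or
  # drift * beta exactly - never a fractional power
  sp <- enumerate_states(7)
  beta0 <- 3
  pp <- pomo_params(7, pi = rep(.25, 4), rho = rep(0, 6),
                    beta = beta0, B = 2, mode = "balance")
  Q <- build_rate_matrix(sp, pp)
  st <- sp$states
  for (i in which(st$type == "poly")) {
    n <- st$n[i]
    for (m in c(n - 1, n + 1)) {
      j <- if (m == 0) state_index_mono(sp, st$second[i])
           else if (m == 7) state_index_mono(sp, st$first[i])
           else state_index_poly(sp, st$pair[i], m)
      drift <- n * (7 - n) / 7
      expect_true(isTRUE(all.equal(Q[i, j], drift)) ||
                  isTRUE(all.equal(Q[i, j], drift * beta0)))
    }
  }
})

test_that("normalized generator has unit stationary event flux", {
  sp <- enumerate_states(4)
  pp <- random_params(4)
  Qn <- build_rate_matrix(sp, pp, normalize = TRUE)
  psi <- stationary_distribution(Qn)
  expect_equal(-sum(psi * diag(Qn)), 1, tolerance = 1e-8)
})
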