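# tiny dataset + tree reused across sampler tests
mcmc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(55)
      tree <- ape::read.tree(text = "((p1:2,p2:2):2,p3:4);")
      pp <- pomo_params(4, pi = rep(.25, 4), rho = rep(.05, 6), sigma = .1,
                        beta = 2, B = 2, mode = "balance")
      ct <- simulate_counts(tree, pp, 300, sample_size = 4)
      cache <<- list(tree = tree, pat = compress_patterns(ct))
    }
    cache
  }
})

test_that("prior draws have the configured moments and B support", {
  set.seed(51)
  config <- prior_config(N = 4, mode = "balance")
  n <- 10000
  sig <- replicate(n, sample_prior(config)$state$sigma)
  expect_lt(abs(mean(sig) - 0.1), 3 * 0.1 / sqrt(n))
  bet <- replicate(n, sample_prior(config)$state$beta[1])
  expect_lt(abs(mean(bet) - 1), 3 * 1 / sqrt(n))
  Bs <- replicate(n, sample_prior(config)$params$B)
  expect_setequal(unique(as.vector(Bs)), c(1L, 2L, 3L))
  # rounded latent is uniform over the interior frequencies
  tab <- table(Bs)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  # pi draws live on the simplex
  p <- sample_prior(config)$state$pi
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("with the likelihood disabled the sampler recovers its priors", {
  fx <- mcmc_fixture()
  config <- prior_config(N = 4, mode = "balance")
  tr <- run_mcmc(fx$pat, fx$tree, config, n_iter = 6500, burnin = 0.2,
                 seed = 3, power = 0)
  post <- tr[tr$iter > 1300, ]
  expect_gte(nrow(post), 5000)
  ks_sig <- suppressWarnings(ks.test(post$sigma, pexp, 10))
  expect_lt(unname(ks_sig$statistic), 0.05)
  ks_beta <- suppressWarnings(ks.test(post$beta_AC, pexp, 1))
  expect_lt(unname(ks_beta$statistic), 0.05)
  ks_rho <- suppressWarnings(ks.test(post$rho_CG, pexp, 10))
  expect_lt(unname(ks_rho$statistic), 0.05)
  # Dirichlet(0.25) marginal mean is 1/4; tolerance scaled by the chain's
  # own effective sample size (the simplex prior mixes slowly)
  ess_pi <- effective_sample_size(post$pi_A)
  expect_lt(abs(mean(post$pi_A) - 0.25), 4 * 0.306 / sqrt(ess_pi))
  # rounded B stays strictly inside (0, N) and covers the interior
  expect_setequal(sort(unique(post$B_AC)), 1:3)
})

test_that("trace log-posterior is reproducible from the stored parameters", {
  fx <- mcmc_fixture()
  config <- prior_config(N = 4, mode = "balance")
  tr <- run_mcmc(fx$pat, fx$tree, config, n_iter = 40, burnin = 0.5, seed = 4)
  engine <- likelihood_engine(fx$pat, fx$tree, 4)
  i <- nrow(tr)
  pp <- pomo_params(4,
                    pi = as.numeric(tr[i, paste0("pi_", c("A", "C", "G", "T"))]),
                    rho = as.numeric(tr[i, paste0("rho_", c("AC", "AG", "AT",
                                                            "CG", "CT", "GT"))]),
                    sigma = tr$sigma[i],
                    beta = as.numeric(tr[i, paste0("beta_", c("AC", "AG", "AT",
                                                              "CG", "CT", "GT"))]),
                    B = as.numeric(tr[i, paste0("B_", c("AC", "AG", "AT",
                                                        "CG", "CT", "GT"))]),
                    mode = "balance")
  expect_equal(engine(pp), tr$lnlik[i], tolerance = 1e-8)
})

test_that("post-tuning acceptance of scalar scale moves is reasonable", {
  fx <- mcmc_fixture()
  config <- prior_config(N = 4, mode = "balance")
  tr <- run_mcmc(fx$pat, fx$tree, config, n_iter = 300, burnin = 0.5, seed = 5)
  ms <- attr(tr, "move_stats")[[1]]
  sc <- ms[ms$type == "scale", ]
  expect_true(all(sc$rate > 0.15 & sc$rate < 0.75))
})

test_that("effective sample size behaves on iid, AR(1) and constant series", {
  set.seed(52)
  x <- rnorm(1000)
  expect_true(effective_sample_size(x) > 800 &&
              effective_sample_size(x) < 1200)
  n <- 10000
  ar <- as.numeric(arima.sim(list(ar = 0.5), n))
  ess <- effective_sample_size(ar)
  expect_lt(abs(ess - n / 3) / (n / 3), 0.2)
  expect_warning(e0 <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(e0, 0)
  expect_error(effective_sample_size(1:5), "short")
})

test_that("trace summaries report central intervals, modes and ESS", {
  set.seed(53)
  tr <- data.frame(iter = 1:4000, sigma = rnorm(4000, 1, 0.1),
                   B_AC = sample(c(2, 2, 2, 3), 4000, replace = TRUE))
  s <- summarize_trace(tr, burn_in_fraction = 0)
  srow <- s[s$parameter == "sigma", ]
  expect_equal(srow$mean, srow$median, tolerance = 0.02)
  expect_equal(srow$lower, quantile(tr$sigma, 0.025, names = FALSE))
  expect_equal(srow$upper, quantile(tr$sigma, 0.975, names = FALSE))
  expect_equal(s[s$parameter == "B_AC", "mode"], 2)
  expect_error(summarize_trace(tr[0, ]), "empty")
})

test_that("the coupled-chain variant still targets the posterior", {
  fx <- mcmc_fixture()
  config <- prior_config(N = 4, mode = "balance")
  tr <- run_mcmc(fx$pat, fx$tree, config, n_iter = 2500, burnin = 0.2,
                 seed = 6, power = 0, mc3 = TRUE)
  post <- tr[tr$iter > 500, ]
  ess_s <- effective_sample_size(post$sigma)
  expect_lt(abs(mean(post$sigma) - 0.1), 4 * 0.1 / sqrt(ess_s))
  # swap moves happen and some are accepted
  ms <- attr(tr, "move_stats")[[1]]
  expect_gt(ms$proposed[ms$move == "mc3_swap"], 0)
})
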