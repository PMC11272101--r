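test_that("empirical SFS matches a brute-force tally on a hand-made table", {
  # 10 sites, one population, N = 4 with S = 4 (exact grid)
  sites <- list(
    rbind(c(4, 0, 0, 0)), rbind(c(4, 0, 0, 0)), rbind(c(0, 0, 0, 4)),
    rbind(c(2, 2, 0, 0)), rbind(c(2, 2, 0, 0)), rbind(c(1, 3, 0, 0)),
    rbind(c(0, 2, 0, 2)), rbind(c(3, 0, 1, 0)), rbind(c(0, 4, 0, 0)),
    rbind(c(0, 0, 0, 0))  # missing: contributes nothing
  )
  sfs <- empirical_sfs(ct_from_list(sites, "p1"), 4)
  expect_equal(unname(sfs$mono["A"]), 2 / 9)
  expect_equal(unname(sfs$mono["T"]), 1 / 9)
  expect_equal(unname(sfs$mono["C"]), 1 / 9)
  expect_equal(unname(sfs$poly["AC", 2]), 2 / 9)
  expect_equal(unname(sfs$poly["AC", 1]), 1 / 9)
  expect_equal(unname(sfs$poly["CT", 2]), 1 / 9)  # first allele C count 2
  expect_equal(unname(sfs$poly["AG", 3]), 1 / 9)
  expect_equal(sum(sfs$mono) + sum(sfs$poly), 1)
})

test_that("all-monomorphic and boundary-split tables hit the ends", {
  s1 <- empirical_sfs(ct_from_list(rep(list(rbind(c(5, 0, 0, 0))), 4), "p"), 5)
  expect_equal(unname(s1$mono["A"]), 1)
  s2 <- empirical_sfs(ct_from_list(list(rbind(c(5, 0, 0, 0)),
                                        rbind(c(0, 5, 0, 0))), "p"), 5)
  expect_equal(unname(s2$mono[c("A", "C")]), c(0.5, 0.5))
})

test_that("off-grid sample sizes are projected by binomial expectation", {
  # S = 8, c = 3 on pair AC with N = 4: lands at 1.5, split half/half
  sfs <- empirical_sfs(ct_from_list(list(rbind(c(3, 5, 0, 0))), "p"), 4)
  expect_equal(unname(sfs$poly["AC", 1]), 0.5)
  expect_equal(unname(sfs$poly["AC", 2]), 0.5)
})

test_that("expected SFS is the reshaped stationary distribution", {
  pp <- pomo_params(6, pi = rep(.25, 4), rho = rep(.05, 6))
  sfs <- expected_sfs(pp)
  expect_equal(sum(sfs$mono) + sum(sfs$poly), 1, tolerance = 1e-12)
  # neutral symmetric: interior symmetric about N/2 for each pair
  for (p in 1:6)
    expect_equal(unname(sfs$poly[p, ]), unname(rev(sfs$poly[p, ])),
                 tolerance = 1e-10)
  # large beta with common B: interior argmax at B for each pair
  ppb <- pomo_params(6, pi = rep(.25, 4), rho = rep(.05, 6),
                     beta = 6, B = 2, mode = "balance")
  sfsb <- expected_sfs(ppb)
  for (p in 1:6) expect_equal(unname(which.max(sfsb$poly[p, ])), 2)
})

test_that("empirical SFS converges to the expected SFS in total variation", {
  set.seed(31)
  pp <- pomo_params(6, pi = c(.3, .2, .2, .3), rho = rep(.04, 6),
                    sigma = .1, beta = 2, B = 2, mode = "balance")
  tree <- ape::read.tree(text = "(A:1);")
  L <- 100000
  emp <- empirical_sfs(simulate_counts(tree, pp, L), 6)
  expect_lt(sfs_distance(emp, expected_sfs(pp)), 0.01)
})

test_that("the matrix view duplicates the shared monomorphic ends", {
  pp <- pomo_params(4, pi = c(.4, .3, .2, .1), rho = rep(.1, 6))
  sfs <- expected_sfs(pp)
  m <- as.matrix(sfs)
  expect_equal(dim(m), c(6, 5))
  expect_equal(m["AC", "4"], unname(sfs$mono["A"]))
  expect_equal(m["AC", "0"], unname(sfs$mono["C"]))
  expect_equal(m["GT", "0"], unname(sfs$mono["T"]))
})
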