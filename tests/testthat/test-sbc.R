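test_that("RF distance matches hand-enumerated bipartition counts", {
  t1 <- read_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  t2 <- read_newick("((((A:1,C:1):1,B:1):1,D:1):1,E:1);")
  expect_equal(rf_distance(t1, t1), 0L)
  # swapping B and C destroys {A,B} and {A,B,C}... wait both caterpillars
  # share {A,B,C}; only the cherry partition differs on each side: distance 2
  expect_equal(rf_distance(t1, t2), 2L)
  # the maximum for binary 5-taxon trees is 2(n-3) = 4
  set.seed(61)
  for (i in 1:10) {
    a <- ape::rtopology(5, rooted = TRUE, tip.label = LETTERS[1:5])
    b <- ape::rtopology(5, rooted = TRUE, tip.label = LETTERS[1:5])
    expect_lte(rf_distance(a, b), 4L)
  }
  t3 <- read_newick("((A:1,B:1):1,Z:1);")
  expect_error(rf_distance(t1, t3), "leaf")
})

test_that("prior topology draws cover rooted shapes uniformly", {
  set.seed(62)
  config <- prior_config(N = 4, mode = "select")
  # 4 taxa: 15 rooted labeled binary topologies
  draws <- replicate(1500, {
    tr <- sample_prior(config, n_taxa = 4)$tree
    cl <- vapply(ape::prop.part(tr),
                 function(p) paste(sort(tr$tip.label[p]), collapse = ""), "")
    paste(sort(cl), collapse = "|")
  })
  tab <- table(draws)
  expect_equal(length(tab), 15)   # rooted labeled 4-taxon topologies
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-4)
})

test_that("the exact-posterior stub hits nominal coverage", {
  rep <- sbc_exact_stub(n_replicates = 400, n_posterior = 600,
                        levels = c(0.5, 0.9), seed = 63)
  for (i in seq_len(nrow(rep$coverage))) {
    row <- rep$coverage[i, ]
    expect_lt(abs(row$coverage - row$level), 3 * row$se + 0.01)
  }
  # coverage is monotone in the nominal level
  expect_lte(rep$coverage$coverage[rep$coverage$level == 0.5],
             rep$coverage$coverage[rep$coverage$level == 0.9])
  # rank statistic of the truth within exact posterior draws is uniform
  h <- hist(rep$ranks[, 1], breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_gt(suppressWarnings(chisq.test(h)$p.value), 0.01)
})

test_that("a small full-pipeline SBC runs end to end and reports coverage", {
  config <- prior_config(N = 4, mode = "select", sample_branch_lengths = TRUE)
  rep <- run_sbc(n_replicates = 4, n_sites = 60, config,
                 tree = read_newick("((a:.1,b:.1):.1,(c:.1,d:.1):.1);"),
                 n_iter = 120, burnin = 0.5, seed = 64)
  expect_s3_class(rep, "sbc_report")
  expect_true(all(rep$coverage$coverage >= 0 & rep$coverage$coverage <= 1))
  expect_true(all(c("sigma", "pi_A", "rho_AC") %in% rep$coverage$parameter))
  expect_true(any(grepl("^blen_", rep$coverage$parameter)))
  expect_equal(unique(rep$coverage$n), 4)
})
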