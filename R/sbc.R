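#' Robinson-Foulds distance between two topologies
#'
#' Symmetric difference of the nontrivial bipartitions of the unrooted
#' versions of the two trees (leaf sets must match).
#'
#' @param tree_a,tree_b \code{phylo} trees on the same leaves.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  stopifnot(inherits(tree_a, "phylo"), inherits(tree_b, "phylo"))
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
  ua <- ape::unroot(tree_a)
  ub <- ape::unroot(tree_b)
  as.integer(phangorn::RF.dist(ua, ub, normalize = FALSE))
}

#' Simulation-based calibration of the PoMo inference
#'
#' The prior-draw / simulate / infer loop: for each replicate, parameters
#' (and a tree, or branch lengths on a fixed topology) are drawn from the
#' priors, a count alignment is simulated under them, the posterior is
#' sampled, and each credible interval is checked against the generating
#' value. If the inference is calibrated, a nominal 90 percent interval
#' contains the truth in 90 percent of replicates (up to binomial noise).
#'
#' @param n_replicates Number of prior-predictive replicates.
#' @param n_sites Sites per simulated alignment.
#' @param config A \code{pomo_prior}.
#' @param tree Fixed tree topology (\code{phylo}); its branch lengths are
#'   redrawn from the prior per replicate when
#'   \code{config$sample_branch_lengths} is TRUE. When \code{NULL}, a
#'   5-taxon topology is drawn uniformly per replicate and held fixed in
#'   the inference (topology search is outside this routine; the RF score
#'   is 0 by construction then).
#' @param n_taxa Taxa count when \code{tree} is NULL.
#' @param sample_size Observed alleles per population (passed to the
#'   simulator; NULL keeps virtual-N counts).
#' @param n_iter,burnin MCMC length per replicate.
#' @param levels Nominal credible levels to score (default 0.9).
#' @param seed Integer seed.
#' @param progress Print replicate progress.
#' @return A \code{sbc_report}: data frame \code{coverage} (per parameter
#'   and level: empirical coverage, replicate count, binomial SE), the
#'   per-replicate hit matrix, ranks of the truth within the posterior
#'   samples (for histogram checks), mean RF distance, and the count of
#'   failed replicates.
#' @export
run_sbc <- function(n_replicates, n_sites, config, tree = NULL, n_taxa = 5,
                    sample_size = NULL, n_iter = 400, burnin = 0.4,
                    levels = 0.9, seed = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pomo_prior"), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  hits <- list(); ranks <- list(); rf <- numeric(0); failed <- 0
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      sbc_replicate(n_sites, config, tree, n_taxa, sample_size,
                    n_iter, burnin, levels),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1
      if (progress) message(sprintf("  replicate %d failed: %s", r,
                                    conditionMessage(res)))
      next
    }
    hits[[length(hits) + 1]] <- res$hits
    ranks[[length(ranks) + 1]] <- res$ranks
    rf <- c(rf, res$rf)
    if (progress && r %% 10 == 0)
      message(sprintf("  SBC replicate %d / %d", r, n_replicates))
  }
  if (!length(hits)) stop("all SBC replicates failed", call. = FALSE)
  H <- do.call(rbind, hits)
  cov <- do.call(rbind, lapply(levels, function(lv) {
    cols <- grep(paste0("@", lv, "$"), colnames(H), value = TRUE)
    data.frame(parameter = sub("@.*$", "", cols),
               level = lv,
               coverage = colMeans(H[, cols, drop = FALSE]),
               n = nrow(H),
               se = sqrt(lv * (1 - lv) / nrow(H)))
  }))
  rownames(cov) <- NULL
  structure(list(coverage = cov, hits = H,
                 ranks = do.call(rbind, ranks),
                 mean_rf = if (length(rf)) mean(rf) else NA_real_,
                 n_failed = failed),
            class = "sbc_report")
}

#' @export
print.sbc_report <- function(x, ...) {
  cat(sprintf("SBC report: %d replicates (%d failed), mean RF %.2f\n",
              max(x$coverage$n), x$n_failed, x$mean_rf))
  print(x$coverage, digits = 3)
  invisible(x)
}

sbc_replicate <- function(n_sites, config, tree, n_taxa, sample_size,
                          n_iter, burnin, levels) {
  if (is.null(tree)) {
    draw <- sample_prior(config, n_taxa = n_taxa)
    sim_tree <- draw$tree
  } else {
    draw <- sample_prior(config)
    sim_tree <- tree
    if (config$sample_branch_lengths) {
      sim_tree$edge.length <- stats::rexp(nrow(sim_tree$edge),
                                          config$rate_blen)
      draw$state$blen <- NULL   # re-ordered below against the engine
    }
  }
  truth <- c(state_to_row(draw$state, config))
  ct <- simulate_counts(sim_tree, draw$params, n_sites,
                        sample_size = sample_size)
  trace <- run_mcmc(ct, sim_tree, config, n_iter = n_iter, burnin = burnin)
  tr <- trace[trace$iter > attr(trace, "burnin_iter"), ]
  if (config$sample_branch_lengths) {
    # truth for branch lengths in the engine's postorder edge order
    engine_elen <- attr(likelihood_engine(compress_patterns(ct), sim_tree,
                                          config$N), "elen")
    truth <- c(truth, stats::setNames(engine_elen,
                                      paste0("blen_", seq_along(engine_elen))))
  }
  pnames <- intersect(names(truth), names(tr))
  hits <- c(); ranks <- c()
  for (p in pnames) {
    x <- tr[[p]]
    for (lv in levels) {
      a <- (1 - lv) / 2
      qs <- stats::quantile(x, c(a, 1 - a), names = FALSE)
      hits[paste0(p, "@", lv)] <- as.numeric(truth[p] >= qs[1] &
                                             truth[p] <= qs[2])
    }
    ranks[p] <- mean(x < truth[p]) + 0.5 * mean(x == truth[p])
  }
  list(hits = hits, ranks = ranks, rf = 0L)
}

#' Coverage calibration of the interval machinery on an exact posterior
#'
#' A conjugate normal-normal check of the coverage bookkeeping used by
#' [run_sbc()], with the MCMC replaced by exact posterior sampling: truth
#' drawn from a N(0, 1) prior, one observation y ~ N(truth, sd_obs^2),
#' posterior available in closed form. Empirical coverage of the central
#' credible intervals must then hit the nominal level up to binomial
#' error - a pure test of the interval and aggregation code.
#'
#' @param n_replicates Replicates.
#' @param n_posterior Posterior draws per replicate.
#' @param levels Nominal levels.
#' @param sd_obs Observation noise standard deviation.
#' @param seed Integer seed.
#' @return An \code{sbc_report} for the single parameter \code{theta}.
#' @export
sbc_exact_stub <- function(n_replicates = 200, n_posterior = 500,
                           levels = 0.9, sd_obs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(NA_real_, n_replicates, length(levels),
                 dimnames = list(NULL, paste0("theta@", levels)))
  ranks <- matrix(NA_real_, n_replicates, 1, dimnames = list(NULL, "theta"))
  for (r in seq_len(n_replicates)) {
    theta <- stats::rnorm(1)
    y <- stats::rnorm(1, theta, sd_obs)
    post_var <- 1 / (1 + 1 / sd_obs^2)
    post_mean <- post_var * y / sd_obs^2
    x <- stats::rnorm(n_posterior, post_mean, sqrt(post_var))
    for (li in seq_along(levels)) {
      a <- (1 - levels[li]) / 2
      qs <- stats::quantile(x, c(a, 1 - a), names = FALSE)
      hits[r, li] <- as.numeric(theta >= qs[1] & theta <= qs[2])
    }
    ranks[r, 1] <- mean(x < theta)
  }
  cov <- data.frame(parameter = "theta", level = levels,
                    coverage = colMeans(hits), n = n_replicates,
                    se = sqrt(levels * (1 - levels) / n_replicates))
  structure(list(coverage = cov, hits = hits, ranks = ranks,
                 mean_rf = NA_real_, n_failed = 0L),
            class = "sbc_report")
}
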