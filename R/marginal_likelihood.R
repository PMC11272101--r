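#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood by the stepping-stone method:
#' power posteriors prior x likelihood^b are sampled at K powers spaced
#' as quantiles of a Beta(0.3, 1) distribution (concentrating stones near
#' the prior, where the integrand changes fastest), and each ratio is
#' estimated by importance sampling from the colder neighbouring stone,
#' \deqn{\log Z = \sum_k \log \frac{1}{n}\sum_i e^{(b_{k+1}-b_k)\,\ell_i}}
#' with \eqn{\ell_i} the log-likelihood samples drawn at power
#' \eqn{b_k}. Chains are warm-started from the previous stone.
#'
#' @param patterns A \code{pomo_patterns} or \code{counts_table}.
#' @param tree Rooted \code{phylo}.
#' @param config A \code{pomo_prior} (its \code{mode} selects the model).
#' @param n_stones Number of power-posterior stones (default 32).
#' @param n_iter Iterations per stone (default 200).
#' @param burnin Burn-in fraction per stone.
#' @param seed Integer seed.
#' @param progress Print per-stone progress.
#' @return Scalar log marginal likelihood with attribute
#'   \code{"per_stone"} (data frame of per-stone contributions and
#'   importance-weight diagnostics). A warning is raised when adjacent
#'   power posteriors barely overlap (effective importance sample < 10
#'   percent).
#' @seealso [bayes_factor()]
#' @export
marginal_log_likelihood <- function(patterns, tree, config, n_stones = 32,
                                    n_iter = 200, burnin = 0.4, seed = NULL,
                                    progress = FALSE) {
  stopifnot(inherits(config, "pomo_prior"))
  if (inherits(patterns, "counts_table")) patterns <- compress_patterns(patterns)
  if (!is.null(seed)) set.seed(seed)
  powers <- (seq(0, n_stones) / n_stones)^(1 / 0.3)   # Beta(0.3, 1) quantiles
  engine <- likelihood_engine(patterns, tree, config$N,
                              root_freq = config$root_freq)
  n_blen <- length(attr(engine, "elen"))
  burnin_iter <- floor(burnin * n_iter)
  init <- NULL
  logZ <- 0
  per_stone <- vector("list", n_stones)
  for (k in seq_len(n_stones)) {
    b0 <- powers[k]; b1 <- powers[k + 1]
    res <- run_chain(engine, config, n_iter, burnin_iter, power = b0,
                     init = init, n_blen = n_blen)
    tr <- res$trace[res$trace$iter > burnin_iter, ]
    lnl <- tr$lnlik
    w <- (b1 - b0) * lnl
    mx <- max(w)
    contrib <- mx + log(mean(exp(w - mx)))
    # effective sample size of the importance weights
    ew <- exp(w - mx)
    ess_w <- sum(ew)^2 / sum(ew^2)
    per_stone[[k]] <- data.frame(stone = k, power = b0, contrib = contrib,
                                 ess_weights = ess_w, n = length(w))
    if (ess_w < 0.1 * length(w))
      warning(sprintf(
        "stone %d (power %.4f): adjacent power posteriors barely overlap (weight ESS %.1f of %d)",
        k, b0, ess_w, length(w)))
    logZ <- logZ + contrib
    # warm start next stone from the last state of this one
    last <- tr[nrow(tr), ]
    init <- row_to_state(last, config)
    if (progress) message(sprintf("  stone %d/%d power %.4f contrib %.3f",
                                  k, n_stones, b0, contrib))
  }
  structure(logZ, per_stone = do.call(rbind, per_stone))
}

row_to_state <- function(row, config) {
  st <- list()
  if (config$reversible) {
    if (is.null(config$fixed$pi))
      st$pi <- as.numeric(row[paste0("pi_", NUC)])
    else st$pi <- config$fixed$pi
    if (is.null(config$fixed$rho))
      st$rho <- as.numeric(row[paste0("rho_", PAIRS)])
    else st$rho <- config$fixed$rho
  } else {
    if (is.null(config$fixed$mu))
      st$mu <- as.numeric(row[paste0("mu_", MU_NAMES)])
    else st$mu <- config$fixed$mu
  }
  st$sigma <- if (is.null(config$fixed$sigma)) as.numeric(row["sigma"])
              else config$fixed$sigma
  if (config$mode == "balance") {
    st$beta <- if (is.null(config$fixed$beta))
                 as.numeric(row[paste0("beta_", PAIRS)])
               else config$fixed$beta
    st$Blat <- if (is.null(config$fixed$B))
                 as.numeric(row[paste0("B_", PAIRS)])
               else as.numeric(config$fixed$B)
  }
  if (config$sample_branch_lengths) {
    bl <- grep("^blen_", names(row), value = TRUE)
    st$blen <- as.numeric(row[bl])
  }
  st
}

#' Bayes factor between balancing-selection and selection-only models
#'
#' Runs the stepping-stone estimator under the balancing-selection model
#' and under the directional-selection-only model on the same data and
#' returns the log Bayes factor (balance minus select). Positive values
#' favor balancing selection.
#'
#' @param patterns A \code{pomo_patterns} or \code{counts_table}.
#' @param tree Rooted \code{phylo}.
#' @param config_balance,config_select \code{pomo_prior} configurations
#'   for the two models (modes "balance" and "select").
#' @param ... Passed to [marginal_log_likelihood()].
#' @return Scalar log BF with attributes \code{"logZ_balance"} and
#'   \code{"logZ_select"}.
#' @export
bayes_factor <- function(patterns, tree, config_balance, config_select, ...) {
  stopifnot(config_balance$mode == "balance", config_select$mode == "select")
  z1 <- marginal_log_likelihood(patterns, tree, config_balance, ...)
  z0 <- marginal_log_likelihood(patterns, tree, config_select, ...)
  structure(as.numeric(z1) - as.numeric(z0),
            logZ_balance = as.numeric(z1), logZ_select = as.numeric(z0))
}
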