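# ---- priors ---------------------------------------------------------------

#' Prior and sampling configuration for PoMo inference
#'
#' Captures the hierarchical priors: Dirichlet (concentration 0.25 per
#' allele) on base frequencies; Exponential priors on exchangeabilities
#' (rate 10), mutation rates (rate 10, nonreversible mode), the GC-bias
#' rate (rate 10) and balancing-selection strengths (rate 1); Uniform on
#' (0, N) for each preferred frequency B, carried as a continuous latent
#' that is rounded to an integer whenever the likelihood or a summary is
#' evaluated; Exponential (rate 10 by default) on branch lengths when they
#' are sampled.
#'
#' @param N Virtual population size.
#' @param mode \code{"balance"} or \code{"select"}.
#' @param reversible Use the \code{(pi, rho)} mutation parameterization
#'   (TRUE) or 12 free mutation rates (FALSE).
#' @param conc_pi Dirichlet concentration, length 4.
#' @param rate_rho,rate_mu,rate_sigma,rate_beta,rate_blen Exponential
#'   prior rates.
#' @param sample_branch_lengths Sample branch lengths (TRUE) or keep the
#'   tree's lengths fixed (FALSE).
#' @param fixed Named list of parameter blocks to hold fixed at the given
#'   values instead of sampling (e.g. \code{list(sigma = 0.1)}; allowed
#'   names: pi, rho, mu, sigma, beta, B).
#' @param root_freq Root state frequencies for the likelihood,
#'   \code{"stationary"} or \code{"uniform"}.
#' @return A \code{pomo_prior} configuration list.
#' @export
prior_config <- function(N, mode = c("balance", "select"),
                         reversible = TRUE,
                         conc_pi = rep(0.25, 4),
                         rate_rho = 10, rate_mu = 10, rate_sigma = 10,
                         rate_beta = 1, rate_blen = 10,
                         sample_branch_lengths = FALSE,
                         fixed = list(),
                         root_freq = c("stationary", "uniform")) {
  mode <- match.arg(mode)
  root_freq <- match.arg(root_freq)
  stopifnot(N >= 2, N == round(N), length(conc_pi) == 4, all(conc_pi > 0),
            rate_rho > 0, rate_mu > 0, rate_sigma > 0, rate_beta > 0,
            rate_blen > 0)
  bad <- setdiff(names(fixed), c("pi", "rho", "mu", "sigma", "beta", "B"))
  if (length(bad)) stop("unknown fixed block(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(N = as.integer(N), mode = mode, reversible = reversible,
                 conc_pi = conc_pi, rate_rho = rate_rho, rate_mu = rate_mu,
                 rate_sigma = rate_sigma, rate_beta = rate_beta,
                 rate_blen = rate_blen,
                 sample_branch_lengths = sample_branch_lengths,
                 fixed = fixed, root_freq = root_freq),
            class = "pomo_prior")
}

ldirichlet <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# latent B lives in (0.5, N - 0.5) so rounding stays strictly inside (0, N)
b_bounds <- function(N) c(0.5, N - 0.5)

#' Draw model parameters (and optionally a tree) from the priors
#'
#' @param config A \code{pomo_prior}.
#' @param n_taxa If not \code{NULL}, also draw a rooted tree: topology
#'   uniform over labeled topologies, branch lengths Exponential with the
#'   configured rate.
#' @param tip_labels Optional tip names (default \code{"t1"...}).
#' @return List with \code{params} (a \code{pomo_params}), \code{state}
#'   (the internal sampler state, including the continuous latent for B)
#'   and \code{tree} (or NULL).
#' @export
sample_prior <- function(config, n_taxa = NULL, tip_labels = NULL) {
  stopifnot(inherits(config, "pomo_prior"))
  N <- config$N
  fx <- config$fixed
  st <- list()
  if (config$reversible) {
    st$pi <- if (!is.null(fx$pi)) fx$pi else {
      g <- stats::rgamma(4, shape = config$conc_pi); g / sum(g)
    }
    st$rho <- if (!is.null(fx$rho)) fx$rho
              else stats::rexp(6, config$rate_rho)
  } else {
    st$mu <- if (!is.null(fx$mu)) fx$mu
             else stats::rexp(12, config$rate_mu)
  }
  st$sigma <- if (!is.null(fx$sigma)) fx$sigma
              else stats::rexp(1, config$rate_sigma)
  if (config$mode == "balance") {
    st$beta <- if (!is.null(fx$beta)) fx$beta
               else stats::rexp(6, config$rate_beta)
    st$Blat <- if (!is.null(fx$B)) as.numeric(fx$B)
               else stats::runif(6, b_bounds(N)[1], b_bounds(N)[2])
  }
  tree <- NULL
  if (!is.null(n_taxa)) {
    if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_taxa))
    tree <- ape::rtopology(n_taxa, rooted = TRUE, tip.label = tip_labels)
    tree$edge.length <- stats::rexp(nrow(tree$edge), config$rate_blen)
    st$blen <- tree$edge.length
  }
  list(params = state_to_params(st, config), state = st, tree = tree)
}

state_to_params <- function(st, config) {
  if (config$mode == "balance") {
    B <- as.integer(round(st$Blat))
    if (config$reversible)
      pomo_params(config$N, pi = st$pi, rho = st$rho, sigma = st$sigma,
                  beta = st$beta, B = B, mode = "balance")
    else
      pomo_params(config$N, mu = st$mu, sigma = st$sigma,
                  beta = st$beta, B = B, mode = "balance")
  } else {
    if (config$reversible)
      pomo_params(config$N, pi = st$pi, rho = st$rho, sigma = st$sigma,
                  mode = "select")
    else
      pomo_params(config$N, mu = st$mu, sigma = st$sigma, mode = "select")
  }
}

log_prior <- function(st, config) {
  fx <- config$fixed
  lp <- 0
  if (config$reversible) {
    if (is.null(fx$pi)) lp <- lp + ldirichlet(st$pi, config$conc_pi)
    if (is.null(fx$rho))
      lp <- lp + sum(stats::dexp(st$rho, config$rate_rho, log = TRUE))
  } else if (is.null(fx$mu)) {
    lp <- lp + sum(stats::dexp(st$mu, config$rate_mu, log = TRUE))
  }
  if (is.null(fx$sigma))
    lp <- lp + stats::dexp(st$sigma, config$rate_sigma, log = TRUE)
  if (config$mode == "balance") {
    if (is.null(fx$beta))
      lp <- lp + sum(stats::dexp(st$beta, config$rate_beta, log = TRUE))
    if (is.null(fx$B)) lp <- lp + 6 * log(1 / config$N)  # Uniform(0, N)
  }
  if (config$sample_branch_lengths && !is.null(st$blen))
    lp <- lp + sum(stats::dexp(st$blen, config$rate_blen, log = TRUE))
  lp
}

# ---- moves ----------------------------------------------------------------

# Every move targets one component: scale moves for positive scalars
# (Hastings term log(multiplier)), a Dirichlet-centered proposal for pi,
# and reflective-free slide / scale / independent-uniform proposals for
# the latent B (out-of-range proposals fall outside the prior support and
# are rejected).
make_moves <- function(config, n_blen = 0) {
  fx <- config$fixed
  mv <- list()
  add <- function(name, type, block, index = NA_integer_, tune = 0.5) {
    mv[[length(mv) + 1]] <<- list(name = name, type = type, block = block,
                                  index = index, tune = tune)
  }
  if (config$reversible) {
    if (is.null(fx$pi)) {
      add("pi_simplex", "dirichlet", "pi", tune = 100)
      add("pi_prior_redraw", "redraw_pi", "pi")
      for (i in 1:4) add(paste0("pi_", NUC[i], "_beta"), "beta_simplex",
                         "pi", i, tune = 50)
    }
    if (is.null(fx$rho))
      for (i in 1:6) add(paste0("rho_", PAIRS[i]), "scale", "rho", i)
  } else if (is.null(fx$mu)) {
    for (i in 1:12) add(paste0("mu_", MU_NAMES[i]), "scale", "mu", i)
  }
  if (is.null(fx$sigma)) add("sigma", "scale", "sigma", 1)
  if (config$mode == "balance") {
    if (is.null(fx$beta))
      for (i in 1:6) add(paste0("beta_", PAIRS[i]), "scale", "beta", i)
    if (is.null(fx$B)) {
      for (i in 1:6) add(paste0("B_", PAIRS[i], "_slide"), "slide_B", "Blat", i,
                         tune = 1)
      for (i in 1:6) add(paste0("B_", PAIRS[i], "_scale"), "scale_B", "Blat", i,
                         tune = 0.4)
      for (i in 1:6) add(paste0("B_", PAIRS[i], "_redraw"), "redraw_B", "Blat", i)
      if (is.null(fx$beta))
        # joint jump: new B plus a beta rescale, to cross the valley
        # between (B, beta) modes that single-coordinate moves cannot
        for (i in 1:6) add(paste0("B_", PAIRS[i], "_jump"), "jump_B_beta",
                           "Blat", i, tune = 1.5)
    }
  }
  if (config$sample_branch_lengths)
    for (i in seq_len(n_blen)) add(paste0("blen_", i), "scale", "blen", i)
  # adaptive multivariate-normal moves over all transformed continuous
  # parameters: they learn the posterior covariance during burn-in and
  # propose along it, which is what crosses the sigma/pi/rho ridges -
  # applied several times per sweep because they dominate the mixing of
  # the slow directions
  for (i in 1:5) add(paste0("avmvn_", i), "avmvn", "all", tune = 0.3)
  mv
}

# transform the continuous blocks to an unconstrained vector (log scales,
# log-ratio simplex); used by the adaptive multivariate move
z_encode <- function(st, config) {
  fx <- config$fixed
  z <- c()
  if (config$reversible) {
    if (is.null(fx$pi)) z <- c(z, log(st$pi[2:4] / st$pi[1]))
    if (is.null(fx$rho)) z <- c(z, log(st$rho))
  } else if (is.null(fx$mu)) z <- c(z, log(st$mu))
  if (is.null(fx$sigma)) z <- c(z, log(max(st$sigma, 1e-12)))
  if (config$mode == "balance" && is.null(fx$beta)) z <- c(z, log(st$beta))
  if (config$sample_branch_lengths && !is.null(st$blen))
    z <- c(z, log(pmax(st$blen, 1e-12)))
  z
}

z_decode <- function(z, st, config) {
  fx <- config$fixed
  i <- 0
  take <- function(n) { out <- z[(i + 1):(i + n)]; i <<- i + n; out }
  if (config$reversible) {
    if (is.null(fx$pi)) {
      w <- c(0, take(3)); e <- exp(w - max(w)); st$pi <- e / sum(e)
    }
    if (is.null(fx$rho)) st$rho <- exp(take(6))
  } else if (is.null(fx$mu)) st$mu <- exp(take(12))
  if (is.null(fx$sigma)) st$sigma <- exp(take(1))
  if (config$mode == "balance" && is.null(fx$beta)) st$beta <- exp(take(6))
  if (config$sample_branch_lengths && !is.null(st$blen))
    st$blen <- exp(take(n <- length(st$blen)))
  st
}

# log |Jacobian| of the z -> x map (sum of logs of the positive scalars,
# plus the multinomial-logit simplex Jacobian for pi)
z_log_jacobian <- function(st, config) {
  fx <- config$fixed
  lj <- 0
  if (config$reversible) {
    if (is.null(fx$pi)) lj <- lj + sum(log(st$pi))
    if (is.null(fx$rho)) lj <- lj + sum(log(st$rho))
  } else if (is.null(fx$mu)) lj <- lj + sum(log(st$mu))
  if (is.null(fx$sigma)) lj <- lj + log(st$sigma)
  if (config$mode == "balance" && is.null(fx$beta)) lj <- lj + sum(log(st$beta))
  if (config$sample_branch_lengths && !is.null(st$blen))
    lj <- lj + sum(log(st$blen))
  lj
}

propose <- function(st, move, config) {
  lh <- 0
  bb <- b_bounds(config$N)
  switch(move$type,
    scale = {
      m <- exp(move$tune * (stats::runif(1) - 0.5))
      st[[move$block]][move$index] <- st[[move$block]][move$index] * m
      lh <- log(m)
    },
    dirichlet = {
      x <- st$pi
      conc <- move$tune
      xp <- stats::rgamma(4, shape = conc * x + 1e-4)
      xp <- xp / sum(xp)
      lh <- ldirichlet(x, conc * xp + 1e-4) - ldirichlet(xp, conc * x + 1e-4)
      st$pi <- xp
    },
    beta_simplex = {
      # redraw one simplex component from a Beta centered at its value,
      # rescaling the rest; Hastings includes the (1-u)^(K-2) Jacobian
      x <- st$pi
      i <- move$index
      a <- move$tune
      xi <- x[i]
      u <- stats::rbeta(1, a * xi + 1, a * (1 - xi) + 1)
      u <- min(max(u, 1e-12), 1 - 1e-12)
      xnew <- x * (1 - u) / (1 - xi)
      xnew[i] <- u
      lh <- stats::dbeta(xi, a * u + 1, a * (1 - u) + 1, log = TRUE) -
            2 * log(1 - xi) -
            stats::dbeta(u, a * xi + 1, a * (1 - xi) + 1, log = TRUE) +
            2 * log(1 - u)
      st$pi <- xnew / sum(xnew)
    },
    slide_B = {
      st$Blat[move$index] <- st$Blat[move$index] +
        move$tune * (stats::runif(1) - 0.5)
    },
    scale_B = {
      m <- exp(move$tune * (stats::runif(1) - 0.5))
      st$Blat[move$index] <- st$Blat[move$index] * m
      lh <- log(m)
    },
    redraw_pi = {
      # independent draw from the Dirichlet prior: near-certain acceptance
      # when the data are weak, where random-walk simplex moves crawl
      xp <- stats::rgamma(4, shape = config$conc_pi)
      xp <- pmax(xp, 1e-12); xp <- xp / sum(xp)
      lh <- ldirichlet(st$pi, config$conc_pi) - ldirichlet(xp, config$conc_pi)
      st$pi <- xp
    },
    redraw_B = {
      st$Blat[move$index] <- stats::runif(1, bb[1], bb[2])
    },
    jump_B_beta = {
      st$Blat[move$index] <- stats::runif(1, bb[1], bb[2])
      m <- exp(move$tune * (stats::runif(1) - 0.5))
      st$beta[move$index] <- st$beta[move$index] * m
      lh <- log(m)
    },
    stop("unknown move type"))
  list(state = st, log_hastings = lh)
}

state_in_support <- function(st, config) {
  bb <- b_bounds(config$N)
  ok <- TRUE
  if (config$reversible) ok <- ok && all(st$rho >= 0) && all(st$pi > 0)
  else ok <- ok && all(st$mu >= 0)
  ok <- ok && st$sigma >= 0
  if (config$mode == "balance")
    ok <- ok && all(st$beta > 0) &&
      all(st$Blat > bb[1]) && all(st$Blat < bb[2])
  if (!is.null(st$blen)) ok <- ok && all(st$blen >= 0)
  ok
}


# prior change for a single-move update; constants (uniform B latent)
# cancel in the MH ratio
move_prior_delta <- function(st, stp, mv, config) {
  switch(mv$type,
    scale = {
      i <- mv$index
      r <- switch(mv$block,
                  rho = config$rate_rho, mu = config$rate_mu,
                  sigma = config$rate_sigma, beta = config$rate_beta,
                  blen = config$rate_blen)
      stats::dexp(stp[[mv$block]][i], r, log = TRUE) -
        stats::dexp(st[[mv$block]][i], r, log = TRUE)
    },
    dirichlet = ldirichlet(stp$pi, config$conc_pi) -
      ldirichlet(st$pi, config$conc_pi),
    beta_simplex = ldirichlet(stp$pi, config$conc_pi) -
      ldirichlet(st$pi, config$conc_pi),
    redraw_pi = ldirichlet(stp$pi, config$conc_pi) -
      ldirichlet(st$pi, config$conc_pi),
    slide_B = 0,
    scale_B = 0,
    redraw_B = 0,
    jump_B_beta = stats::dexp(stp$beta[mv$index], config$rate_beta,
                              log = TRUE) -
      stats::dexp(st$beta[mv$index], config$rate_beta, log = TRUE),
    stop("unknown move type"))
}

# cheap in-support check for the single component a move touched
move_in_support <- function(stp, mv, config) {
  bb <- b_bounds(config$N)
  if (mv$block == "Blat") {
    x <- stp$Blat[mv$index]
    if (x <= bb[1] || x >= bb[2]) return(FALSE)
  }
  if (mv$type == "jump_B_beta") {
    x <- stp$Blat[mv$index]
    if (x <= bb[1] || x >= bb[2]) return(FALSE)
    if (!is.finite(stp$beta[mv$index]) || stp$beta[mv$index] <= 0)
      return(FALSE)
  }
  if (mv$type == "scale") {
    x <- stp[[mv$block]][mv$index]
    if (!is.finite(x) || x <= 0) return(FALSE)
  }
  if (mv$block == "pi" && any(stp$pi <= 0)) return(FALSE)
  TRUE
}

# ---- the sampler ----------------------------------------------------------

#' Metropolis-Hastings MCMC over PoMo parameters
#'
#' Random-scan Metropolis-Hastings targeting prior x likelihood^power.
#' One iteration applies every active move once. Proposal step sizes are
#' autotuned toward 44 percent acceptance during the burn-in phase and
#' frozen afterwards. Each chain starts from an independent prior draw
#' (over-dispersed starts), re-drawn a bounded number of times if the
#' initial likelihood is degenerate.
#'
#' @param patterns A \code{pomo_patterns} (from [compress_patterns()]), or
#'   a \code{counts_table} which is compressed on the fly.
#' @param tree Rooted \code{phylo}; when
#'   \code{config$sample_branch_lengths} is TRUE its branch lengths only
#'   seed the move set and are replaced by sampled values.
#' @param config A \code{pomo_prior}.
#' @param n_iter Total iterations (sweeps) per chain, including burn-in.
#' @param burnin Fraction of \code{n_iter} used for autotuning (default
#'   0.3); these iterations are kept in the trace and flagged.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed; per-chain streams are derived from it.
#' @param power Likelihood tempering power (1 = posterior; 0 = prior);
#'   used by the stepping-stone marginal likelihood.
#' @param init Optional initial sampler state (as from
#'   \code{sample_prior()$state}), or \code{"empirical"} for a
#'   moment-matched start (base frequencies from the pooled counts, a
#'   shared exchangeability calibrated to the observed polymorphic
#'   fraction, neutral selection), or \code{"map"} for a posterior-mode
#'   warm start (quasi-Newton ascent plus conditional sweeps over the
#'   discrete preferred frequencies), jittered per chain. The default
#'   (\code{NULL}) draws over-dispersed starts from the priors.
#' @param mc3 If TRUE, run each chain as a Metropolis-coupled quartet
#'   (ladder \code{1/(1 + 0.1 (i-1))}, swap proposals every 10
#'   iterations) and record the cold chain.
#' @param thin Record every \code{thin}-th iteration.
#' @param progress Print progress messages.
#' @return A \code{pomo_trace} data frame (one row per recorded iteration
#'   and chain) with log-prior, log-likelihood, log-posterior, all sampled
#'   parameters (B at its rounded value), and attributes
#'   \code{"move_stats"}, \code{"config"}, \code{"burnin_iter"}.
#' @export
run_mcmc <- function(patterns, tree, config, n_iter = 1000, burnin = 0.3,
                     n_chains = 1, seed = NULL, power = 1, init = NULL,
                     mc3 = FALSE, thin = 1, progress = FALSE) {
  stopifnot(inherits(config, "pomo_prior"))
  if (inherits(patterns, "counts_table")) patterns <- compress_patterns(patterns)
  engine <- likelihood_engine(patterns, tree, config$N,
                              root_freq = config$root_freq)
  n_blen <- length(attr(engine, "elen"))
  burnin_iter <- floor(burnin * n_iter)
  traces <- vector("list", n_chains)
  stats_all <- vector("list", n_chains)
  map_base <- NULL
  zchol0 <- NULL
  if (identical(init, "map")) {
    if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
    map_base <- map_init(engine, config, patterns, n_blen)
    zchol0 <- laplace_zchol(engine, config, map_base, n_blen)
  }
  for (ch in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed((seed * 97L + ch) %% .Machine$integer.max)
    init_ch <- if (identical(init, "empirical"))
                 empirical_init(patterns, config)
               else if (identical(init, "map")) jitter_state(map_base, config)
               else init
    if (config$sample_branch_lengths && is.list(init_ch) &&
        is.null(init_ch$blen))
      init_ch$blen <- stats::rexp(n_blen, config$rate_blen)
    if (mc3) {
      res <- run_chain_mc3(engine, config, n_iter, burnin_iter, power,
                           init_ch, n_blen, thin, progress)
    } else {
      res <- run_chain(engine, config, n_iter, burnin_iter, power, init_ch,
                       n_blen, thin, progress, zchol0 = zchol0)
    }
    res$trace$chain <- ch
    traces[[ch]] <- res$trace
    stats_all[[ch]] <- res$move_stats
  }
  out <- do.call(rbind, traces)
  class(out) <- c("pomo_trace", "data.frame")
  attr(out, "move_stats") <- stats_all
  attr(out, "config") <- config
  attr(out, "burnin_iter") <- burnin_iter
  out
}

# Moment-matched starting state: base frequencies from the pooled allele
# counts, one common exchangeability calibrated by bisection so the
# model's stationary polymorphic mass matches the observed polymorphic
# site fraction, neutral selection, and mid-range preferred frequencies.
# Cuts burn-in substantially on informative data sets; chains are jittered
# so multi-chain starts remain distinct.
empirical_init <- function(patterns, config, jitter = 0.1) {
  N <- config$N
  w <- patterns$weights
  tot <- c(0, 0, 0, 0)
  npoly <- 0; nobs <- 0
  for (i in seq_along(w)) {
    for (j in seq_along(patterns$pops)) {
      v <- patterns$counts[i, j, ]
      if (sum(v) == 0) next
      tot <- tot + v * w[i]
      nobs <- nobs + w[i]
      if (sum(v > 0) == 2) npoly <- npoly + w[i]
    }
  }
  pi_hat <- (tot + 1) / sum(tot + 1)
  f_poly <- max(npoly / max(nobs, 1), 1e-4)
  # bisection on a shared exchangeability against stationary poly mass
  poly_mass <- function(r) {
    pp <- pomo_params(N, pi = pi_hat, rho = rep(r, 6))
    1 - sum(stationary_distribution(
      build_rate_matrix(enumerate_states(N), pp))[1:4])
  }
  lo <- 1e-5; hi <- 1
  for (k in 1:25) {
    mid <- sqrt(lo * hi)
    if (poly_mass(mid) < f_poly) lo <- mid else hi <- mid
  }
  r0 <- sqrt(lo * hi)
  st <- list()
  if (config$reversible) {
    st$pi <- if (!is.null(config$fixed$pi)) config$fixed$pi
             else pi_hat * exp(stats::rnorm(4, 0, jitter))
    st$pi <- st$pi / sum(st$pi)
    st$rho <- if (!is.null(config$fixed$rho)) config$fixed$rho
              else r0 * exp(stats::rnorm(6, 0, jitter))
  } else {
    mu0 <- mutation_rates(pi_hat, rep(r0, 6))
    st$mu <- if (!is.null(config$fixed$mu)) config$fixed$mu
             else as.numeric(mu0) * exp(stats::rnorm(12, 0, jitter))
  }
  st$sigma <- if (!is.null(config$fixed$sigma)) config$fixed$sigma
              else 0.05 * exp(stats::rnorm(1, 0, jitter))
  if (config$mode == "balance") {
    st$beta <- if (!is.null(config$fixed$beta)) config$fixed$beta
               else 1.5 * exp(stats::rnorm(6, 0, jitter))
    if (!is.null(config$fixed$B)) {
      st$Blat <- as.numeric(config$fixed$B)
    } else {
      # start each preferred frequency at the empirical interior peak of
      # its pair (balancing selection shows up exactly there); pairs with
      # no interior mass start mid-range
      prof <- matrix(0, 6, N - 1)
      for (i in seq_along(w)) {
        for (j in seq_along(patterns$pops)) {
          v <- patterns$counts[i, j, ]
          nz <- which(v > 0)
          if (length(nz) != 2) next
          p <- match(paste0(NUC[nz[1]], NUC[nz[2]]), PAIRS)
          n <- min(max(round(N * v[nz[1]] / sum(v)), 1), N - 1)
          prof[p, n] <- prof[p, n] + w[i]
        }
      }
      st$Blat <- vapply(1:6, function(p) {
        if (sum(prof[p, ]) == 0) return(N / 2)
        which.max(prof[p, ]) + stats::runif(1, -0.3, 0.3)
      }, 0)
    }
  }
  st
}

# Posterior-mode warm start: quasi-Newton ascent on the log posterior over
# the continuous parameters (log / softmax transformed), alternating with
# per-pair conditional sweeps over the discrete preferred frequencies.
# Starting chains at the mode leaves the sampler the job it is good at -
# local exploration - instead of a long ridge crawl through burn-in.
map_init <- function(engine, config, patterns, n_blen, cycles = 2,
                     maxit = 30) {
  seval <- attr(engine, "state_eval")
  st <- empirical_init(patterns, config, jitter = 0)
  if (config$sample_branch_lengths)
    st$blen <- rep(1 / config$rate_blen, n_blen)
  st_emp <- st   # uncompensated moment start; candidate restarts use it
  fx <- config$fixed
  # pooled composition of monomorphic observations, for base-frequency
  # inversion: the observed composition is the model's stationary
  # monomorphic mass, not pi itself
  mono_obs <- c(0, 0, 0, 0)
  for (i in seq_along(patterns$weights)) for (j in seq_along(patterns$pops)) {
    v <- patterns$counts[i, j, ]
    nz <- which(v > 0)
    if (length(nz) == 1) mono_obs[nz] <- mono_obs[nz] + patterns$weights[i]
  }
  mono_obs <- (mono_obs + 1) / sum(mono_obs + 1)
  space <- enumerate_states(config$N)
  # fixed point on pi so the stationary monomorphic masses match mono_obs
  match_pi <- function(s, iters = 20) {
    pi <- mono_obs
    for (it in seq_len(iters)) {
      pp <- tryCatch(state_to_params(utils::modifyList(s, list(pi = pi)), config),
                     error = function(e) NULL)
      if (is.null(pp)) return(s$pi)
      psi <- tryCatch(stationary_distribution(build_rate_matrix(space, pp)),
                      error = function(e) NULL)
      if (is.null(psi)) return(s$pi)
      m <- psi[1:4] / sum(psi[1:4])
      pi <- pi * (mono_obs / pmax(m, 1e-12))^0.7
      pi <- pmax(pi, 1e-8)
      pi <- pi / sum(pi)
    }
    as.numeric(pi)
  }
  # encode the continuous free parameters
  enc <- function(st) {
    v <- c()
    if (config$reversible) {
      if (is.null(fx$pi)) v <- c(v, log(st$pi[2:4] / st$pi[1]))
      if (is.null(fx$rho)) v <- c(v, log(st$rho))
    } else if (is.null(fx$mu)) v <- c(v, log(st$mu))
    if (is.null(fx$sigma)) v <- c(v, log(max(st$sigma, 1e-8)))
    if (config$mode == "balance" && is.null(fx$beta)) v <- c(v, log(st$beta))
    if (config$sample_branch_lengths) v <- c(v, log(pmax(st$blen, 1e-8)))
    v
  }
  dec <- function(v, st) {
    i <- 0
    take <- function(n) { out <- v[(i + 1):(i + n)]; i <<- i + n; out }
    if (config$reversible) {
      if (is.null(fx$pi)) {
        z <- c(0, take(3)); st$pi <- exp(z) / sum(exp(z))
      }
      if (is.null(fx$rho)) st$rho <- exp(take(6))
    } else if (is.null(fx$mu)) st$mu <- exp(take(12))
    if (is.null(fx$sigma)) st$sigma <- exp(take(1))
    if (config$mode == "balance" && is.null(fx$beta)) st$beta <- exp(take(6))
    if (config$sample_branch_lengths) st$blen <- exp(take(n_blen))
    st
  }
  # objective factory: the template fixes the non-encoded fields (notably
  # the discrete preferred frequencies) for this optimization
  mkobj <- function(tmpl) {
    function(v) {
      s <- dec(v, tmpl)
      lp <- log_prior(s, config)
      if (!is.finite(lp)) return(1e10)
      el <- if (config$sample_branch_lengths) s$blen else NULL
      ll <- tryCatch(seval(s, config, el), error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -(ll + lp)
    }
  }
  beta_grid0 <- c(0.5, 0.8, 1, 1.5, 2, 3, 5)
  for (cy in seq_len(cycles)) {
    opt <- stats::optim(enc(st), mkobj(st), method = "BFGS",
                        control = list(maxit = maxit))
    st <- dec(opt$par, st)
    if (cy == 1 && config$mode == "balance" && is.null(fx$B)) {
      # multi-start over shared preferred frequencies: the per-pair
      # landscape is warped by base-frequency compensation, so each
      # candidate (all pairs at B = b, best shared beta) gets its own
      # short continuous re-optimization before the comparison
      cands <- list(st)
      for (b in seq_len(config$N - 1)) {
        # restart from the uncompensated moment state: optimizing the
        # incumbent's continuous parameters has already absorbed a wrong
        # B into pi and sigma, which poisons the candidate basin
        s <- st_emp
        s$Blat[] <- b
        if (is.null(fx$sigma)) s$sigma <- 1 / config$rate_sigma
        if (is.null(fx$beta)) {
          raw <- vapply(beta_grid0, function(be) {
            s2 <- s; s2$beta[] <- be
            if (config$reversible && is.null(fx$pi)) s2$pi <- match_pi(s2)
            el <- if (config$sample_branch_lengths) s2$blen else NULL
            tryCatch(seval(s2, config, el) +
                       log_prior(s2, config), error = function(e) -Inf)
          }, 0)
          s$beta[] <- beta_grid0[which.max(raw)]
        }
        if (config$reversible && is.null(fx$pi)) s$pi <- match_pi(s)
        o <- stats::optim(enc(s), mkobj(s), method = "BFGS",
                          control = list(maxit = 25))
        cands[[length(cands) + 1]] <- dec(o$par, s)
      }
      scores <- vapply(cands, function(s) -mkobj(s)(enc(s)), 0)
      st <- cands[[which.max(scores)]]
      opt <- stats::optim(enc(st), mkobj(st), method = "BFGS",
                          control = list(maxit = maxit))
      st <- dec(opt$par, st)
    }
    if (config$mode == "balance" && is.null(fx$B)) {
      # conditional sweep jointly over (B, beta) per pair: a wrong B is
      # locally shielded by a compensating beta, so B alone never moves
      beta_grid <- beta_grid0
      for (p in 1:6) {
        grid <- rbind(expand.grid(b = seq_len(config$N - 1), be = beta_grid),
                      data.frame(b = st$Blat[p], be = st$beta[p]))
        vals <- vapply(seq_len(nrow(grid)), function(g) {
          s <- st
          s$Blat[p] <- grid$b[g]
          if (is.null(fx$beta)) s$beta[p] <- grid$be[g]
          el <- if (config$sample_branch_lengths) s$blen else NULL
          tryCatch(seval(s, config, el) + log_prior(s, config),
                   error = function(e) -Inf)
        }, 0)
        best <- which.max(vals)
        st$Blat[p] <- grid$b[best]
        if (is.null(fx$beta)) st$beta[p] <- grid$be[best]
      }
    }
  }
  st
}

# small multiplicative jitter so chains started from a shared mode differ
jitter_state <- function(st, config, eps = 0.05) {
  fx <- config$fixed
  j <- function(x) x * exp(stats::rnorm(length(x), 0, eps))
  if (config$reversible) {
    if (is.null(fx$pi)) { st$pi <- j(st$pi); st$pi <- st$pi / sum(st$pi) }
    if (is.null(fx$rho)) st$rho <- j(st$rho)
  } else if (is.null(fx$mu)) st$mu <- j(st$mu)
  if (is.null(fx$sigma)) st$sigma <- j(st$sigma)
  if (config$mode == "balance") {
    if (is.null(fx$beta)) st$beta <- j(st$beta)
    if (is.null(fx$B))
      st$Blat <- pmin(pmax(st$Blat + stats::runif(6, -0.2, 0.2), 0.6),
                      config$N - 0.6)
  }
  if (!is.null(st$blen)) st$blen <- j(st$blen)
  st
}

# Laplace proposal shape at the posterior mode: numerical Hessian of the
# log posterior in the transformed (z) space. The inverse Hessian knows
# the nearly-flat ridges (e.g. the GC-bias direction) that burn-in
# samples cannot discover on their own, so the adaptive multivariate
# proposal is shaped correctly from the first iteration.
laplace_zchol <- function(engine, config, st, n_blen, h = 2e-3) {
  seval <- attr(engine, "state_eval")
  z0 <- z_encode(st, config)
  d <- length(z0)
  if (d == 0) return(NULL)
  g <- function(z) {
    s <- z_decode(z, st, config)
    lp <- log_prior(s, config)
    if (!is.finite(lp)) return(-1e10)
    el <- if (config$sample_branch_lengths) s$blen else NULL
    ll <- tryCatch(seval(s, config, el), error = function(e) -Inf)
    if (!is.finite(ll)) return(-1e10)
    ll + lp + z_log_jacobian(s, config)
  }
  H <- matrix(0, d, d)
  g0 <- g(z0)
  gp <- numeric(d); gm <- numeric(d)
  for (i in seq_len(d)) {
    zp <- z0; zp[i] <- zp[i] + h
    zm <- z0; zm[i] <- zm[i] - h
    gp[i] <- g(zp); gm[i] <- g(zm)
    H[i, i] <- (gp[i] - 2 * g0 + gm[i]) / h^2
  }
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    zpp <- z0; zpp[c(i, j)] <- zpp[c(i, j)] + h
    gpp <- g(zpp)
    H[i, j] <- H[j, i] <- (gpp - gp[i] - gp[j] + g0) / h^2
  }
  ei <- eigen(-H, symmetric = TRUE)
  lam <- pmin(pmax(ei$values, 0.05), 1e8)   # curvature floor: z-variance <= 20
  cov <- ei$vectors %*% (t(ei$vectors) / lam)
  ch <- tryCatch(chol(2.38^2 / d * (cov + diag(1e-10, d))),
                 error = function(e) NULL)
  if (is.null(ch)) NULL else t(ch)
}

init_state <- function(engine, config, n_blen, init, power, max_retry = 25) {
  for (try in seq_len(max_retry)) {
    if (!is.null(init)) {
      st <- init
    } else {
      st <- sample_prior(config)$state
      if (config$sample_branch_lengths)
        st$blen <- stats::rexp(n_blen, config$rate_blen)
    }
    el <- if (config$sample_branch_lengths) st$blen else NULL
    seval <- attr(engine, "state_eval")
    ll <- tryCatch(seval(st, config, el), error = function(e) -Inf)
    if (is.finite(ll) || power == 0) return(list(state = st, lnL = ll))
    init <- NULL
  }
  stop("could not find a starting state with finite likelihood", call. = FALSE)
}

run_chain <- function(engine, config, n_iter, burnin_iter, power, init,
                      n_blen, thin = 1, progress = FALSE, zchol0 = NULL) {
  seval <- attr(engine, "state_eval")
  moves <- make_moves(config, n_blen)
  s0 <- init_state(engine, config, n_blen, init, power)
  st <- s0$state; lnL <- s0$lnL
  lnP <- log_prior(st, config)
  acc <- integer(length(moves)); tot <- integer(length(moves))
  acc_tune <- integer(length(moves)); tot_tune <- integer(length(moves))
  rec <- vector("list", ceiling(n_iter / thin))
  nrec <- 0
  # adaptive-MVN bookkeeping: history of transformed states (burn-in only)
  zdim <- length(z_encode(st, config))
  zhist <- matrix(NA_real_, min(burnin_iter, 2000), zdim)
  zn <- 0
  zchol <- zchol0   # Laplace-shaped when a mode warm start provided it
  for (it in seq_len(n_iter)) {
    for (m in seq_along(moves)) {
      mv <- moves[[m]]
      if (mv$type == "avmvn") {
        if (is.null(zchol) || zdim == 0) next
        z <- z_encode(st, config)
        zp <- z + mv$tune * as.numeric(zchol %*% stats::rnorm(zdim))
        stp <- z_decode(zp, st, config)
        lnPp <- log_prior(stp, config)
        if (!is.finite(lnPp)) { tot[m] <- tot[m] + 1L
          tot_tune[m] <- tot_tune[m] + 1L; next }
        lnLp <- if (power == 0) 0
                else {
                  el <- if (config$sample_branch_lengths) stp$blen else NULL
                  tryCatch(seval(stp, config, el), error = function(e) -Inf)
                }
        lnalpha <- power * (lnLp - lnL) + lnPp - lnP +
          z_log_jacobian(stp, config) - z_log_jacobian(st, config)
        tot[m] <- tot[m] + 1L; tot_tune[m] <- tot_tune[m] + 1L
        if (is.finite(lnalpha) && log(stats::runif(1)) < lnalpha) {
          st <- stp; lnL <- lnLp; lnP <- lnPp
          acc[m] <- acc[m] + 1L; acc_tune[m] <- acc_tune[m] + 1L
        }
        next
      }
      prop <- propose(st, mv, config)
      stp <- prop$state
      if (!move_in_support(stp, mv, config)) { tot[m] <- tot[m] + 1L;
        tot_tune[m] <- tot_tune[m] + 1L; next }
      dP <- move_prior_delta(st, stp, mv, config)
      lnPp <- lnP + dP
      if (!is.finite(lnPp)) { tot[m] <- tot[m] + 1L;
        tot_tune[m] <- tot_tune[m] + 1L; next }
      # B moves that do not change the rounded value leave the likelihood
      # untouched
      same_lik <- mv$type %in% c("slide_B", "scale_B", "redraw_B") &&
        round(stp$Blat[mv$index]) == round(st$Blat[mv$index])
      lnLp <- if (same_lik) lnL
              else if (power == 0) 0
              else {
                el <- if (config$sample_branch_lengths) stp$blen else NULL
                tryCatch(seval(stp, config, el), error = function(e) -Inf)
              }
      lnalpha <- power * (lnLp - lnL) + lnPp - lnP + prop$log_hastings
      tot[m] <- tot[m] + 1L; tot_tune[m] <- tot_tune[m] + 1L
      if (is.finite(lnalpha) && log(stats::runif(1)) < lnalpha) {
        st <- stp; lnL <- lnLp; lnP <- lnPp
        acc[m] <- acc[m] + 1L; acc_tune[m] <- acc_tune[m] + 1L
      }
    }
    if (it <= burnin_iter && zdim > 0 && is.null(zchol0)) {
      zn <- zn + 1
      if (zn <= nrow(zhist)) zhist[zn, ] <- z_encode(st, config)
      if (it %% 25 == 0 && zn >= 50) {
        zc <- stats::cov(zhist[max(1, zn - 500):zn, , drop = FALSE])
        ch <- tryCatch(chol(2.38^2 / zdim * zc + diag(1e-9, zdim)),
                       error = function(e) NULL)
        if (!is.null(ch)) zchol <- t(ch)
      }
    }
    # autotune toward 0.44 acceptance during burn-in
    if (it <= burnin_iter && it %% 25 == 0) {
      for (m in seq_along(moves)) {
        if (tot_tune[m] == 0 ||
            moves[[m]]$type %in% c("redraw_B", "jump_B_beta",
                                   "redraw_pi")) next
        rate <- acc_tune[m] / tot_tune[m]
        f <- exp(rate - if (moves[[m]]$type == "avmvn") 0.25 else 0.44)
        if (moves[[m]]$type %in% c("dirichlet", "beta_simplex")) {
          # higher concentration = smaller steps, so invert; adapt fast -
          # posterior concentrations can sit orders of magnitude above the
          # prior scale
          moves[[m]]$tune <- min(max(moves[[m]]$tune / f^4, 1), 1e7)
        } else {
          moves[[m]]$tune <- min(max(moves[[m]]$tune * f, 1e-3), 20)
        }
      }
      acc_tune[] <- 0L; tot_tune[] <- 0L
    }
    if (it %% thin == 0) {
      nrec <- nrec + 1
      rec[[nrec]] <- c(iter = it, lnprior = lnP, lnlik = lnL,
                       lnpost = lnP + power * lnL,
                       state_to_row(st, config))
    }
    if (progress && it %% 200 == 0)
      message(sprintf("  iter %d / %d  lnL = %.2f", it, n_iter, lnL))
  }
  trace <- as.data.frame(do.call(rbind, rec[seq_len(nrec)]))
  list(trace = trace,
       move_stats = data.frame(
         move = vapply(moves, `[[`, "", "name"),
         type = vapply(moves, `[[`, "", "type"),
         tune = vapply(moves, `[[`, 0, "tune"),
         accepted = acc, proposed = tot,
         rate = ifelse(tot > 0, acc / tot, NA)))
}

state_to_row <- function(st, config) {
  out <- c()
  if (config$reversible) {
    out <- c(out, stats::setNames(st$pi, paste0("pi_", NUC)),
             stats::setNames(st$rho, paste0("rho_", PAIRS)))
  } else {
    out <- c(out, stats::setNames(st$mu, paste0("mu_", MU_NAMES)))
  }
  out <- c(out, sigma = st$sigma)
  if (config$mode == "balance") {
    out <- c(out, stats::setNames(st$beta, paste0("beta_", PAIRS)),
             stats::setNames(round(st$Blat), paste0("B_", PAIRS)))
  }
  if (config$sample_branch_lengths && !is.null(st$blen))
    out <- c(out, stats::setNames(st$blen,
                                  paste0("blen_", seq_along(st$blen))))
  out
}

# Metropolis-coupled variant: a ladder of heated chains advanced in
# lockstep, with a swap proposal between a random adjacent pair every 10
# iterations; only the cold chain is recorded.
run_chain_mc3 <- function(engine, config, n_iter, burnin_iter, power,
                          init, n_blen, thin = 1, progress = FALSE,
                          n_heat = 4, dheat = 0.1) {
  heats <- 1 / (1 + dheat * (seq_len(n_heat) - 1))
  chains <- lapply(heats, function(h) {
    s0 <- init_state(engine, config, n_blen, init, power * h)
    list(st = s0$state, lnL = s0$lnL,
         lnP = log_prior(s0$state, config),
         moves = make_moves(config, n_blen))
  })
  acc <- NULL
  rec <- vector("list", ceiling(n_iter / thin)); nrec <- 0
  swap_acc <- 0L; swap_tot <- 0L
  for (it in seq_len(n_iter)) {
    for (ci in seq_along(chains)) {
      chl <- chains[[ci]]
      res <- mc3_sweep(engine, config, chl, power * heats[ci],
                       tune = it <= burnin_iter)
      chains[[ci]] <- res
    }
    if (it %% 10 == 0 && n_heat > 1) {
      i <- sample.int(n_heat - 1, 1)
      c1 <- chains[[i]]; c2 <- chains[[i + 1]]
      lnalpha <- (power * heats[i] * c2$lnL + power * heats[i + 1] * c1$lnL) -
                 (power * heats[i] * c1$lnL + power * heats[i + 1] * c2$lnL)
      swap_tot <- swap_tot + 1L
      if (log(stats::runif(1)) < lnalpha) {
        tmp <- chains[[i]]
        chains[[i]] <- chains[[i + 1]]
        chains[[i + 1]] <- tmp
        swap_acc <- swap_acc + 1L
      }
    }
    if (it %% thin == 0) {
      nrec <- nrec + 1
      cold <- chains[[1]]
      rec[[nrec]] <- c(iter = it, lnprior = cold$lnP, lnlik = cold$lnL,
                       lnpost = cold$lnP + power * cold$lnL,
                       state_to_row(cold$st, config))
    }
  }
  trace <- as.data.frame(do.call(rbind, rec[seq_len(nrec)]))
  list(trace = trace,
       move_stats = data.frame(move = "mc3_swap", type = "swap", tune = NA,
                               accepted = swap_acc, proposed = swap_tot,
                               rate = ifelse(swap_tot > 0,
                                             swap_acc / swap_tot, NA)))
}

mc3_sweep <- function(engine, config, chl, power, tune) {
  seval <- attr(engine, "state_eval")
  st <- chl$st; lnL <- chl$lnL; lnP <- chl$lnP; moves <- chl$moves
  for (m in seq_along(moves)) {
    mv <- moves[[m]]
    if (mv$type == "avmvn") next   # plain component moves only under MC3
    prop <- propose(st, mv, config)
    stp <- prop$state
    if (!move_in_support(stp, mv, config)) next
    dP <- move_prior_delta(st, stp, mv, config)
    lnPp <- lnP + dP
    if (!is.finite(lnPp)) next
    same_lik <- mv$type %in% c("slide_B", "scale_B", "redraw_B") &&
      round(stp$Blat[mv$index]) == round(st$Blat[mv$index])
    lnLp <- if (same_lik) lnL
            else if (power == 0) 0
            else {
              el <- if (config$sample_branch_lengths) stp$blen else NULL
              tryCatch(seval(stp, config, el), error = function(e) -Inf)
            }
    lnalpha <- power * (lnLp - lnL) + lnPp - lnP + prop$log_hastings
    if (is.finite(lnalpha) && log(stats::runif(1)) < lnalpha) {
      st <- stp; lnL <- lnLp; lnP <- lnPp
    }
  }
  list(st = st, lnL = lnL, lnP = lnP, moves = moves)
}

# ---- diagnostics and summaries --------------------------------------------

#' Effective sample size of an MCMC series
#'
#' Autocorrelation-time estimate using Geyer's initial positive sequence:
#' consecutive autocorrelation pairs are summed while the pair sums stay
#' positive.
#'
#' @param x Numeric series (length >= 10).
#' @return Scalar ESS; 0 (with a warning) for a constant series.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("series too short for an ESS estimate", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("constant series: ESS reported as 0")
    return(0)
  }
  lag_max <- min(n - 1, 2000)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  # rho[1] is lag 0; form pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  tau <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 2; i2 <- 2 * m + 3      # lags 2m+1, 2m+2 (1-based offset)
    if (i1 > length(rho)) break
    g <- rho[i1] + (if (i2 <= length(rho)) rho[i2] else 0)
    if (g <= 0) break
    tau <- tau + g
    m <- m + 1
  }
  ess <- n / (1 + 2 * tau)
  min(ess, n)
}

#' Summarize an MCMC trace
#'
#' Per-parameter posterior mean, median, central 95 percent credible
#' interval and ESS after discarding burn-in; preferred-frequency
#' parameters (columns \code{B_*}) additionally get their posterior mode,
#' which is also reported as the point estimate for them.
#'
#' @param trace A \code{pomo_trace} (or data frame of samples).
#' @param burn_in_fraction Fraction of each chain discarded (default:
#'   the tuning phase recorded in the trace).
#' @param prob Credible level for the central interval (default 0.95).
#' @return Data frame with one row per parameter: mean, median, lower,
#'   upper, mode (B only), ess.
#' @export
summarize_trace <- function(trace, burn_in_fraction = NULL, prob = 0.95) {
  stopifnot(is.data.frame(trace))
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  drop_cols <- c("iter", "chain", "lnprior", "lnlik", "lnpost")
  if (is.null(burn_in_fraction)) {
    bi <- attr(trace, "burnin_iter")
    burn_in_fraction <- if (is.null(bi)) 0 else bi / max(trace$iter)
  }
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  cut <- burn_in_fraction * max(trace$iter)
  keep <- trace$iter > cut
  if (!any(keep)) stop("no post-burn-in samples", call. = FALSE)
  tr <- trace[keep, setdiff(names(trace), drop_cols), drop = FALSE]
  a <- (1 - prob) / 2
  out <- do.call(rbind, lapply(names(tr), function(p) {
    x <- tr[[p]]
    is_B <- grepl("^B_", p)
    data.frame(
      parameter = p,
      mean = mean(x),
      median = stats::median(x),
      lower = stats::quantile(x, a, names = FALSE),
      upper = stats::quantile(x, 1 - a, names = FALSE),
      mode = if (is_B) as.numeric(names(which.max(table(x)))) else NA_real_,
      ess = if (length(x) >= 10 && stats::var(x) > 0)
              effective_sample_size(x) else NA_real_
    )
  }))
  rownames(out) <- NULL
  attr(out, "prob") <- prob
  out
}

#' Write / read a trace as tab-separated text
#'
#' One column per parameter with a header row, in the style of
#' phylogenetic MCMC log files.
#'
#' @param trace A \code{pomo_trace}.
#' @param path File path.
#' @return \code{path} (write) or a \code{pomo_trace} (read).
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("pomo_trace", "data.frame")
  out
}
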