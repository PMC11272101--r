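#' Build the PoMo rate matrix
#'
#' Assembles the generator Q of the continuous-time Markov chain over the
#' PoMo state space. Monomorphic (boundary) states exit only by mutation:
#' the state fixed for allele \code{ai} moves to the polymorphic state with
#' \code{N-1} copies of \code{ai} at rate \code{mu[ai->aj]}. Polymorphic
#' states take unit frequency shifts at rate
#' \deqn{\frac{n(N-n)}{N}\,\phi\,\beta^{\frac{1}{2}(|n-B|-|n\pm1-B|+1)}}
#' i.e. Moran drift times the fitness of the allele gaining a copy, times
#' the balancing-selection strength \code{beta} when (and only when) the
#' shift moves the frequency toward the preferred frequency \code{B}; the
#' exponent is always 0 or 1. Shifts of more than one copy have rate zero,
#' and the diagonal is set to minus the row sum.
#'
#' With all \code{beta = 1} (or \code{mode = "select"}) the balancing term
#' vanishes and the matrix is the directional-selection (PoMoSelect)
#' generator.
#'
#' @param space A \code{pomo_states} object (see [enumerate_states()]).
#' @param params A \code{pomo_params} object with matching \code{N}.
#' @param normalize If \code{TRUE}, divide Q by the stationary event flux
#'   \code{-sum(psi * diag(Q))} so that branch lengths are in expected
#'   events per site; default leaves Q in raw Moran time.
#' @return A \code{pomo_rate_matrix}: the matrix \code{Q} with state labels,
#'   plus the state space and parameters as attributes.
#' @examples
#' sp <- enumerate_states(4)
#' pp <- pomo_params(N = 4, pi = rep(.25, 4), rho = rep(.1, 6),
#'                   beta = 2, B = 2, mode = "balance")
#' Q <- build_rate_matrix(sp, pp)
#' max(abs(rowSums(Q)))  # 0 within 1e-10
#' @export
build_rate_matrix <- function(space, params, normalize = FALSE) {
  stopifnot(inherits(space, "pomo_states"), inherits(params, "pomo_params"))
  if (space$N != params$N)
    stop("state space and parameters disagree on N", call. = FALSE)
  N <- space$N
  k <- space$n_states
  mu <- params$mu
  phi <- params$phi
  balance <- params$mode == "balance"
  if (balance && any(is.na(params$B)))
    stop("balance mode requires integer B strictly inside (0, N)", call. = FALSE)

  Q <- matrix(0, k, k, dimnames = list(space$states$label, space$states$label))
  for (p in seq_along(PAIRS)) {
    pair <- PAIRS[p]
    ai <- substr(pair, 1, 1); aj <- substr(pair, 2, 2)
    i_mono_ai <- state_index_mono(space, ai)
    i_mono_aj <- state_index_mono(space, aj)
    idx <- function(n) {          # state {n ai, (N-n) aj}; n in 0..N
      if (n == 0) i_mono_aj
      else if (n == N) i_mono_ai
      else state_index_poly(space, pair, n)
    }
    beta_p <- if (balance) params$beta[pair] else 1
    B_p <- if (balance) params$B[pair] else NA_integer_
    bs_exp <- function(n, m) {    # exponent of beta for the shift n -> m
      if (!balance) return(0)
      (abs(n - B_p) - abs(m - B_p) + 1) / 2
    }
    # boundary mutations
    Q[i_mono_ai, idx(N - 1)] <- Q[i_mono_ai, idx(N - 1)] + mu[pair]
    Q[i_mono_aj, idx(1)] <- Q[i_mono_aj, idx(1)] +
      mu[paste0(aj, ai)]
    # polymorphic drift / selection / balancing shifts
    for (n in seq_len(N - 1)) {
      drift <- n * (N - n) / N
      Q[idx(n), idx(n + 1)] <- drift * phi[ai] * beta_p^bs_exp(n, n + 1)
      Q[idx(n), idx(n - 1)] <- drift * phi[aj] * beta_p^bs_exp(n, n - 1)
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)

  out <- structure(Q, class = c("pomo_rate_matrix", "matrix", "array"),
                   space = space, params = params, time_scale = "moran")
  if (normalize) {
    psi <- stationary_distribution(out)
    flux <- -sum(psi * diag(Q))
    out[] <- Q / flux
    attr(out, "time_scale") <- "events_per_site"
  }
  out
}

#' Transition probabilities of a PoMo chain
#'
#' Computes \code{P(t) = exp(tQ)} by dense scaling-and-squaring.
#'
#' @param Q Rate matrix (a \code{pomo_rate_matrix} or plain square matrix).
#' @param t Nonnegative time.
#' @return Stochastic matrix of the same dimension.
#' @export
transition_probabilities <- function(Q, t) {
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("`t` must be a single nonnegative time", call. = FALSE)
  P <- expm_cpp(unclass(Q) * t)
  dimnames(P) <- dimnames(Q)
  P
}

# adjacency check: alleles are connected through nonzero mutation rates
reachable_alleles <- function(mu) {
  adj <- matrix(FALSE, 4, 4, dimnames = list(NUC, NUC))
  for (p in PAIRS) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    if (mu[p] > 0) adj[a, b] <- TRUE
    if (mu[paste0(b, a)] > 0) adj[b, a] <- TRUE
  }
  # connectivity of the undirected support
  und <- adj | t(adj)
  seen <- c(TRUE, FALSE, FALSE, FALSE)
  repeat {
    new <- seen | apply(und[seen, , drop = FALSE], 2, any)
    if (all(new == seen)) break
    seen <- new
  }
  seen
}

#' Stationary distribution of a PoMo rate matrix
#'
#' Solves \code{psi Q = 0, sum(psi) = 1} by a least-squares null-space
#' solve. For an ergodic chain this is the long-run state distribution,
#' whose polymorphic part is the model's expected site frequency spectrum.
#'
#' @param Q A \code{pomo_rate_matrix}.
#' @return Named probability vector over the states.
#' @export
stationary_distribution <- function(Q) {
  params <- attr(Q, "params")
  if (!is.null(params)) {
    seen <- reachable_alleles(params$mu)
    if (!all(seen))
      stop(sprintf(
        "rate matrix is reducible: allele(s) %s unreachable through nonzero mutation rates",
        paste(NUC[!seen], collapse = ", ")), call. = FALSE)
  }
  k <- nrow(Q)
  A <- rbind(t(unclass(Q)), rep(1, k))
  b <- c(rep(0, k), 1)
  psi <- tryCatch(qr.solve(A, b), error = function(e) {
    # ill-conditioned at extreme parameter values: least-squares via SVD
    sv <- svd(A)
    dinv <- ifelse(sv$d > sv$d[1] * 1e-14, 1 / sv$d, 0)
    as.numeric(sv$v %*% (dinv * crossprod(sv$u, b)))
  })
  psi[psi < 0 & psi > -1e-12] <- 0
  if (any(psi < 0))
    stop("stationary solve produced negative probabilities", call. = FALSE)
  psi <- psi / sum(psi)
  stats::setNames(psi, rownames(Q))
}

#' Detailed-balance residual
#'
#' Maximum over state pairs of \code{|psi_i q_ij - psi_j q_ji|} at the
#' stationary distribution. The residual is zero (to numerical tolerance)
#' exactly when the chain is reversible: for the balancing-selection model
#' this requires symmetric exchangeabilities and every preferred frequency
#' at the mid-point \code{B = N/2}; the directional-selection model with
#' symmetric exchangeabilities is always reversible.
#'
#' @param Q A \code{pomo_rate_matrix}.
#' @return Nonnegative scalar.
#' @export
detailed_balance_residual <- function(Q) {
  psi <- stationary_distribution(Q)
  M <- psi * unclass(Q)        # rows scaled: M_ij = psi_i q_ij
  max(abs(M - t(M)))
}
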