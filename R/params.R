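# 12 ordered mutation-rate names: forward pair order then reverse
MU_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT",
              "CA", "GA", "TA", "GC", "TC", "TG")

#' Model parameters for PoMoSelect / PoMoBalance
#'
#' Collects the parameters of the polymorphism-aware substitution models.
#' In reversible mode the 12 mutation rates are derived as
#' \code{mu[ij] = rho[ij] * pi[j]} from 6 exchangeabilities and 4 base
#' frequencies; in nonreversible mode the 12 rates are free. Allele
#' fitnesses are \code{phi = (1, 1+sigma, 1+sigma, 1)} under GC-biased gene
#' conversion (the default), or a free 4-vector anchored at
#' \code{phi[A] = 1}. Balancing selection adds, per nucleotide pair, a
#' strength \code{beta > 0} and an integer preferred frequency
#' \code{0 < B < N}.
#'
#' @param N Virtual population size (integer >= 2).
#' @param pi Base frequencies (4-simplex), reversible mode.
#' @param rho 6 nonnegative exchangeabilities (order AC, AG, AT, CG, CT,
#'   GT), reversible mode.
#' @param mu 12 nonnegative mutation rates (order AC, AG, AT, CG, CT, GT,
#'   CA, GA, TA, GC, TC, TG), nonreversible mode. Supply either
#'   \code{pi}+\code{rho} or \code{mu}, not both.
#' @param sigma GC-bias rate; sets \code{phi = (1, 1+sigma, 1+sigma, 1)}.
#' @param phi Free fitness 4-vector with \code{phi[1] == 1}; overrides
#'   \code{sigma}.
#' @param beta 6 positive balancing-selection strengths (scalar recycled).
#' @param B 6 integer preferred frequencies in \code{(0, N)} (scalar
#'   recycled).
#' @param mode \code{"select"} (no balancing-selection term) or
#'   \code{"balance"}.
#' @return An object of class \code{pomo_params}.
#' @examples
#' p <- pomo_params(N = 6, pi = rep(0.25, 4), rho = rep(0.01, 6),
#'                  sigma = 0.1, beta = 2, B = 2, mode = "balance")
#' @export
pomo_params <- function(N, pi = NULL, rho = NULL, mu = NULL,
                        sigma = 0, phi = NULL, beta = 1, B = NULL,
                        mode = c("select", "balance")) {
  mode <- match.arg(mode)
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 2)
    stop("`N` must be a single integer >= 2", call. = FALSE)
  N <- as.integer(N)

  reversible <- is.null(mu)
  if (reversible) {
    if (is.null(pi) || is.null(rho))
      stop("supply either `pi` and `rho` (reversible) or `mu` (nonreversible)",
           call. = FALSE)
    if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
      stop("`pi` must be 4 nonnegative frequencies summing to 1", call. = FALSE)
    if (length(rho) != 6 || any(rho < 0))
      stop("`rho` must be 6 nonnegative exchangeabilities", call. = FALSE)
    pi <- stats::setNames(as.numeric(pi), NUC)
    rho <- stats::setNames(as.numeric(rho), PAIRS)
    mu <- mutation_rates(pi, rho)
  } else {
    if (!is.null(pi) || !is.null(rho))
      stop("supply either `pi`+`rho` or `mu`, not both", call. = FALSE)
    if (length(mu) != 12 || any(mu < 0))
      stop("`mu` must be 12 nonnegative mutation rates", call. = FALSE)
    mu <- stats::setNames(as.numeric(mu), MU_NAMES)
    pi <- NULL; rho <- NULL
  }

  if (is.null(phi)) {
    if (length(sigma) != 1 || sigma < -1)
      stop("`sigma` must be a single value > -1", call. = FALSE)
    phi <- c(1, 1 + sigma, 1 + sigma, 1)
  } else {
    if (length(phi) != 4 || any(phi <= 0) || phi[1] != 1)
      stop("`phi` must be 4 positive fitnesses with phi[1] (A) fixed at 1",
           call. = FALSE)
    sigma <- NA_real_
  }
  phi <- stats::setNames(as.numeric(phi), NUC)

  if (length(beta) == 1) beta <- rep(beta, 6)
  if (length(beta) != 6 || any(beta <= 0))
    stop("`beta` must be 6 positive balancing-selection strengths",
         call. = FALSE)
  beta <- stats::setNames(as.numeric(beta), PAIRS)

  if (mode == "balance") {
    if (is.null(B)) stop("`B` is required in balance mode", call. = FALSE)
    if (length(B) == 1) B <- rep(B, 6)
    if (length(B) != 6 || any(B != round(B)) || any(B <= 0) || any(B >= N))
      stop("`B` must be 6 integers strictly inside (0, N)", call. = FALSE)
    B <- stats::setNames(as.integer(B), PAIRS)
  } else {
    beta <- stats::setNames(rep(1, 6), PAIRS)
    B <- stats::setNames(rep(NA_integer_, 6), PAIRS)
  }

  structure(
    list(N = N, pi = pi, rho = rho, mu = mu, sigma = sigma, phi = phi,
         beta = beta, B = B, mode = mode, reversible = reversible),
    class = "pomo_params"
  )
}

#' Mutation rates from base frequencies and exchangeabilities
#'
#' Reversible parameterization \code{mu[ij] = rho[ij] * pi[j]}: the
#' symmetric exchangeability of a pair multiplies the frequency of the
#' target allele, for all 12 ordered nucleotide pairs.
#'
#' @param pi Base frequencies (4-simplex, order A, C, G, T).
#' @param rho 6 nonnegative exchangeabilities (order AC, AG, AT, CG, CT, GT).
#' @return Named 12-vector of mutation rates (order AC, AG, AT, CG, CT,
#'   GT, CA, GA, TA, GC, TC, TG).
#' @examples
#' mutation_rates(rep(0.25, 4), c(0.1, 0, 0, 0, 0, 0))[c("AC", "CA")]
#' @export
mutation_rates <- function(pi, rho) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("`pi` must be 4 nonnegative frequencies summing to 1", call. = FALSE)
  if (length(rho) != 6 || any(rho < 0))
    stop("`rho` must be 6 nonnegative exchangeabilities", call. = FALSE)
  pi <- stats::setNames(as.numeric(pi), NUC)
  rho <- stats::setNames(as.numeric(rho), PAIRS)
  first <- substr(PAIRS, 1, 1)
  second <- substr(PAIRS, 2, 2)
  fwd <- rho * pi[second]   # e.g. mu_AC = rho_AC * pi_C
  rev <- rho * pi[first]    # e.g. mu_CA = rho_AC * pi_A
  stats::setNames(c(fwd, rev), MU_NAMES)
}

#' @export
print.pomo_params <- function(x, ...) {
  cat(sprintf("PoMo parameters (%s mode, %s mutations), N = %d\n",
              x$mode, if (x$reversible) "reversible" else "nonreversible",
              x$N))
  if (x$reversible) {
    cat("  pi :", paste(sprintf("%s=%.4g", NUC, x$pi), collapse = " "), "\n")
    cat("  rho:", paste(sprintf("%s=%.4g", PAIRS, x$rho), collapse = " "), "\n")
  } else {
    cat("  mu :", paste(sprintf("%s=%.4g", MU_NAMES, x$mu), collapse = " "), "\n")
  }
  cat("  phi:", paste(sprintf("%.4g", x$phi), collapse = " "), "\n")
  if (x$mode == "balance") {
    cat("  beta:", paste(sprintf("%s=%.4g", PAIRS, x$beta), collapse = " "), "\n")
    cat("  B   :", paste(sprintf("%s=%d", PAIRS, x$B), collapse = " "), "\n")
  }
  invisible(x)
}
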