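#' Binomial tip conditionals for one site and population
#'
#' Probability of the observed allele counts given each true PoMo state,
#' using with-replacement (binomial) sampling of \code{S} alleles from the
#' virtual population: a monomorphic state yields the observed monomorphic
#' sample with probability 1 (and probability \code{(n/N)^S} or
#' \code{((N-n)/N)^S} from polymorphic states of pairs containing the
#' observed allele); a polymorphic observation of the pair \code{aiaj}
#' with \code{c} copies of \code{ai} has probability
#' \code{dbinom(c, S, n/N)} from the state with \code{n} copies of
#' \code{ai}. A fully missing site (\code{S = 0}) is uninformative and
#' returns all ones.
#'
#' @param counts Nonnegative integer 4-vector of observed A, C, G, T
#'   counts (at most two nonzero entries).
#' @param space A \code{pomo_states} state space.
#' @return Numeric vector over the states with entries in \code{[0, 1]}.
#' @examples
#' sp <- enumerate_states(4)
#' tip_conditionals(c(4, 0, 0, 0), sp)[1:6]
#' @export
tip_conditionals <- function(counts, space) {
  stopifnot(inherits(space, "pomo_states"))
  if (length(counts) != 4 || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be 4 nonnegative integers", call. = FALSE)
  N <- space$N
  k <- space$n_states
  S <- sum(counts)
  if (S == 0) return(rep(1, k))
  nz <- which(counts > 0)
  if (length(nz) > 2)
    stop("unsupported site: more than two observed alleles", call. = FALSE)
  out <- numeric(k)
  st <- space$states
  if (length(nz) == 1) {
    a <- NUC[nz]
    out[state_index_mono(space, a)] <- 1
    ip <- which(st$type == "poly" & (st$first == a | st$second == a))
    nn <- ifelse(st$first[ip] == a, st$n[ip], N - st$n[ip])
    out[ip] <- (nn / N)^S
  } else {
    a <- NUC[nz[1]]; b <- NUC[nz[2]]   # nz ascending => "ab" is a valid pair
    pair <- paste0(a, b)
    ip <- which(st$type == "poly" & st$pair == pair)
    out[ip] <- stats::dbinom(counts[nz[1]], S, st$n[ip] / N)
  }
  out
}

#' Compress sites into unique joint count patterns
#'
#' Identical joint tip-count patterns are merged with multiplicities, so
#' the tree likelihood is computed once per pattern. Sites where any
#' population shows three or more alleles are outside the biallelic PoMo
#' state space and are dropped with a logged count.
#'
#' @param table A \code{counts_table}.
#' @return An object of class \code{pomo_patterns}: array \code{counts}
#'   of dimension \code{c(n_patterns, n_pops, 4)}, integer \code{weights}
#'   summing to the number of retained sites, \code{pops}, and
#'   \code{n_dropped}.
#' @export
compress_patterns <- function(table) {
  stopifnot(inherits(table, "counts_table"))
  nall <- apply(table$counts > 0, c(1, 2), sum)
  bad <- apply(nall >= 3, 1, any)
  if (any(bad))
    message(sprintf("compress_patterns: dropped %d site(s) with 3+ observed alleles",
                    sum(bad)))
  cnt <- table$counts[!bad, , , drop = FALSE]
  n <- dim(cnt)[1]
  key <- vapply(seq_len(n),
                function(i) paste(cnt[i, , ], collapse = ","), "")
  first <- !duplicated(key)
  idx <- which(first)
  weights <- as.integer(table(factor(key, levels = key[first])))
  structure(list(counts = cnt[idx, , , drop = FALSE],
                 weights = weights,
                 pops = table$pops,
                 n_sites = n,
                 n_dropped = sum(bad)),
            class = "pomo_patterns")
}

#' @export
print.pomo_patterns <- function(x, ...) {
  cat(sprintf("pomo_patterns: %d unique patterns over %d sites, %d populations\n",
              length(x$weights), x$n_sites, length(x$pops)))
  invisible(x)
}

# Validate an ape tree against a pattern table and return postorder pieces.
# Tip labels must match population names exactly (any order).
prepare_tree <- function(tree, pops) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  if (!setequal(tree$tip.label, pops) ||
      length(tree$tip.label) != length(pops))
    stop("tree leaves must match populations 1:1 by name", call. = FALSE)
  tr <- if (length(tree$tip.label) > 1) ape::reorder.phylo(tree, "postorder")
        else tree
  list(edge = tr$edge, elen = tr$edge.length,
       tip_pop = match(tr$tip.label, pops),   # tip i observes pops[tip_pop[i]]
       n_node = max(tr$edge), ntip = length(tr$tip.label))
}

# Build the per-tip conditional matrices (states x patterns), in tip order.
pattern_tipcond <- function(patterns, space, tip_pop) {
  npat <- length(patterns$weights)
  lapply(tip_pop, function(j) {
    vapply(seq_len(npat),
           function(i) tip_conditionals(patterns$counts[i, j, ], space),
           numeric(space$n_states))
  })
}

#' Prepare a reusable likelihood engine
#'
#' Precomputes pattern tip conditionals and tree bookkeeping once, so MCMC
#' can re-evaluate the log-likelihood cheaply as parameters change.
#'
#' @param patterns A \code{pomo_patterns} object.
#' @param tree A rooted \code{phylo} tree whose tip labels are the
#'   population names.
#' @param N Virtual population size.
#' @param root_freq \code{"stationary"} (default) uses the stationary
#'   distribution of the current rate matrix as root state frequencies;
#'   \code{"uniform"} uses equal frequencies.
#' @return A function \code{f(params, edge_lengths = NULL)} returning the
#'   log-likelihood; \code{edge_lengths}, when given, override the tree's
#'   branch lengths (in postorder edge order, available as attribute
#'   \code{"elen"} of the function).
#' @export
likelihood_engine <- function(patterns, tree, N,
                              root_freq = c("stationary", "uniform")) {
  root_freq <- match.arg(root_freq)
  stopifnot(inherits(patterns, "pomo_patterns"))
  space <- enumerate_states(N)
  tp <- prepare_tree(tree, patterns$pops)
  tipcond <- pattern_tipcond(patterns, space, tp$tip_pop)
  weights <- as.numeric(patterns$weights)
  f <- function(params, edge_lengths = NULL) {
    Q <- build_rate_matrix(space, params)
    rf <- if (root_freq == "stationary") stationary_distribution(Q)
          else rep(1 / space$n_states, space$n_states)
    el <- if (is.null(edge_lengths)) tp$elen else edge_lengths
    if (tp$ntip == 1) {
      P <- expm_cpp(unclass(Q) * el[1])
      site <- as.numeric(rf %*% P %*% tipcond[[1]])
      if (any(site <= 0)) return(-Inf)
      return(sum(weights * log(site)))
    }
    pruning_loglik_cpp(unclass(Q), tp$edge, el, tipcond, rf, weights,
                       tp$n_node)
  }
  attr(f, "elen") <- tp$elen
  attr(f, "space") <- space
  # fast path for the sampler: evaluate directly from a raw state list
  # (pi/rho or mu, sigma, beta, latent B) without constructor overhead;
  # equals f(state_to_params(st, config)) and is cross-checked in the
  # tests
  first <- match(substr(PAIRS, 1, 1), NUC)
  second <- match(substr(PAIRS, 2, 2), NUC)
  rmode <- if (root_freq == "stationary") 0L else 1L
  attr(f, "state_eval") <- function(st, config, edge_lengths = NULL) {
    mu <- if (config$reversible) c(st$rho * st$pi[second],
                                   st$rho * st$pi[first])
          else st$mu
    balance <- config$mode == "balance"
    beta <- if (balance) st$beta else rep(1, 6)
    B <- if (balance) as.integer(round(st$Blat)) else integer(6)
    el <- if (is.null(edge_lengths)) tp$elen else edge_lengths
    if (tp$ntip == 1)
      return(f(state_to_params(st, config), edge_lengths))
    pomo_state_loglik_cpp(space$N, mu, c(1, 1 + st$sigma, 1 + st$sigma, 1),
                          beta, B, balance, tp$edge, el, tipcond, weights,
                          tp$n_node, rmode)
  }
  f
}

#' Tree log-likelihood of count patterns under a PoMo model
#'
#' Felsenstein pruning over the PoMo state space, with per-node scaling
#' against underflow. Root state frequencies default to the stationary
#' distribution of the model's rate matrix.
#'
#' @inheritParams likelihood_engine
#' @param params A \code{pomo_params} object.
#' @param ... Passed to [likelihood_engine()].
#' @return Log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, params, patterns, ...) {
  f <- likelihood_engine(patterns, tree, params$N, ...)
  f(params)
}
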