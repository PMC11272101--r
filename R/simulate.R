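#' Simulate allele-count alignments along a species tree
#'
#' Sites evolve independently under the PoMo Moran dynamics: the root
#' state of each site is drawn from the stationary distribution of the
#' rate matrix (or fixed), and each branch transmits the state by
#' sampling the child state from the corresponding row of
#' \code{exp(t Q)} - exact in law, without discretizing individual Moran
#' events. Leaf states are rendered as virtual-N allele counts and,
#' optionally, binomially downsampled to per-population sample sizes.
#'
#' @param tree Rooted \code{phylo} tree; tip labels name the populations,
#'   branch lengths are in the rate matrix's time units.
#' @param params A \code{pomo_params} object.
#' @param n_sites Number of independent sites to simulate.
#' @param sample_size Per-population number of sampled alleles
#'   (scalar recycled, or a vector named by population). \code{NULL}
#'   keeps the virtual-N counts.
#' @param root_state \code{NULL} to draw roots from the stationary
#'   distribution, or a fixed state index / label.
#' @param seed Optional integer seed.
#' @return A \code{counts_table}; the generating parameters are attached
#'   as attribute \code{"params"}.
#' @examples
#' tr <- ape::read.tree(text = "((p1:5,p2:5):5,p3:10);")
#' pp <- pomo_params(N = 4, pi = rep(.25, 4), rho = rep(.05, 6))
#' ct <- simulate_counts(tr, pp, n_sites = 10, seed = 1)
#' @export
simulate_counts <- function(tree, params, n_sites, sample_size = NULL,
                            root_state = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "pomo_params"),
            n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  space <- enumerate_states(params$N)
  Q <- build_rate_matrix(space, params)
  k <- space$n_states
  ntip <- length(tree$tip.label)
  tr <- if (ntip > 1) ape::reorder.phylo(tree, "postorder") else tree
  # preorder over edges = reversed postorder
  edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]

  root <- ntip + 1L
  state <- matrix(0L, max(tr$edge), n_sites)
  if (is.null(root_state)) {
    psi <- stationary_distribution(Q)
    state[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = psi)
  } else {
    if (is.character(root_state))
      root_state <- match(root_state, space$states$label)
    stopifnot(!is.na(root_state), root_state >= 1, root_state <= k)
    state[root, ] <- as.integer(root_state)
  }
  # group sites by parent state per branch so each P(t) row is sampled once
  for (e in seq_len(nrow(edge))) {
    P <- transition_probabilities(Q, elen[e])
    par <- state[edge[e, 1], ]
    child <- integer(n_sites)
    for (s in unique(par)) {
      w <- which(par == s)
      child[w] <- sample.int(k, length(w), replace = TRUE, prob = P[s, ])
    }
    state[edge[e, 2], ] <- child
  }

  counts <- array(0L, c(n_sites, ntip, 4))
  st <- space$states
  for (tip in seq_len(ntip)) {
    sidx <- state[tip, ]
    for (a in seq_along(NUC)) {
      n_of_a <- ifelse(st$type[sidx] == "mono",
                       ifelse(st$first[sidx] == NUC[a], space$N, 0L),
                       ifelse(st$first[sidx] == NUC[a], st$n[sidx],
                              ifelse(st$second[sidx] == NUC[a],
                                     space$N - st$n[sidx], 0L)))
      counts[, tip, a] <- as.integer(n_of_a)
    }
  }
  out <- counts_table(counts, tr$tip.label)
  if (!is.null(sample_size)) out <- binomial_downsample(out, sample_size,
                                                        N = params$N)
  attr(out, "params") <- params
  out
}

#' Exact event-by-event simulation of one branch
#'
#' Gillespie realization of the same generator used by
#' [simulate_counts()]: exponential waiting times with rate
#' \code{-q[ii]} and jump probabilities \code{q[ij]/-q[ii]}. Used as an
#' independent oracle for the matrix-exponential branch sampling.
#'
#' @param start_state State index at the top of the branch.
#' @param Q Rate matrix.
#' @param t Branch length (nonnegative).
#' @return State index at time \code{t}.
#' @export
gillespie_branch <- function(start_state, Q, t) {
  stopifnot(t >= 0)
  s <- as.integer(start_state)
  time <- 0
  Qm <- unclass(Q)
  repeat {
    rate <- -Qm[s, s]
    if (rate <= 0) return(s)
    time <- time + stats::rexp(1, rate)
    if (time > t) return(s)
    p <- Qm[s, ]
    p[s] <- 0
    s <- sample.int(length(p), 1, prob = p)
  }
}

#' Binomially downsample virtual-N counts to observed sample sizes
#'
#' Draws \code{S} alleles with replacement per site and population:
#' the number of first-pair alleles observed is binomial with success
#' probability \code{n/N}. Monomorphic states stay monomorphic;
#' polymorphic sites in small samples may come out monomorphic, which is
#' exactly the sampling bias the binomial tip correction of the
#' likelihood undoes.
#'
#' @param table A \code{counts_table} holding virtual-N counts.
#' @param sample_size Scalar or per-population vector of sample sizes
#'   \code{S >= 0}.
#' @param N Virtual population size of the source counts (defaults to the
#'   per-row totals).
#' @return A \code{counts_table} at the sample sizes.
#' @export
binomial_downsample <- function(table, sample_size, N = NULL) {
  stopifnot(inherits(table, "counts_table"))
  npop <- length(table$pops)
  if (length(sample_size) == 1) sample_size <- rep(sample_size, npop)
  stopifnot(length(sample_size) == npop, all(sample_size >= 0))
  counts <- table$counts
  out <- array(0L, dim(counts))
  for (j in seq_len(npop)) {
    S <- sample_size[j]
    if (S == 0) next
    tot <- apply(counts[, j, , drop = FALSE], 1, sum)
    for (i in seq_len(table$n_sites)) {
      if (tot[i] == 0) next                       # missing stays missing
      v <- counts[i, j, ]
      nz <- which(v > 0)
      if (length(nz) == 1) {
        out[i, j, nz] <- S
      } else {
        c1 <- stats::rbinom(1, S, v[nz[1]] / tot[i])
        out[i, j, nz[1]] <- c1
        out[i, j, nz[2]] <- S - c1
      }
    }
  }
  counts_table(out, table$pops, table$chrom, table$pos)
}
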