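# Shared fixtures: random parameter draws and small trees, built in code.

random_params <- function(N, mode = "balance", B = NULL) {
  g <- rgamma(4, 1)
  pomo_params(N,
              pi = g / sum(g),
              rho = rexp(6, 5) + 1e-3,
              sigma = rexp(1, 5),
              beta = if (mode == "balance") rexp(6, 1) + 0.05 else 1,
              B = if (mode == "balance") {
                if (is.null(B)) sample(seq_len(N - 1), 6, replace = TRUE) else B
              } else NULL,
              mode = mode)
}

tiny_tree <- function(n = 3, scale = 2) {
  txt <- switch(as.character(n),
    "2" = sprintf("(A:%f,B:%f);", runif(1, 0, scale), runif(1, 0, scale)),
    "3" = sprintf("((A:%f,B:%f):%f,C:%f);",
                  runif(1, 0, scale), runif(1, 0, scale),
                  runif(1, 0, scale), runif(1, 0, scale)))
  ape::read.tree(text = txt)
}

# joint-state enumeration oracle for the tree likelihood (naive, exact)
brute_force_loglik <- function(tree, params, patterns) {
  sp <- enumerate_states(params$N)
  k <- sp$n_states
  Q <- build_rate_matrix(sp, params)
  psi <- stationary_distribution(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  P <- lapply(seq_len(nrow(E)),
              function(e) transition_probabilities(Q, tr$edge.length[e]))
  ntip <- length(tr$tip.label)
  nnode <- max(E)
  tipc <- lapply(seq_len(ntip), function(i) {
    j <- match(tr$tip.label[i], patterns$pops)
    sapply(seq_along(patterns$weights),
           function(s) tip_conditionals(patterns$counts[s, j, ], sp))
  })
  ll <- 0
  grid <- as.matrix(expand.grid(rep(list(1:k), nnode)))
  for (s in seq_along(patterns$weights)) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      a <- grid[g, ]
      term <- psi[a[ntip + 1]]
      for (e in seq_len(nrow(E)))
        term <- term * P[[e]][a[E[e, 1]], a[E[e, 2]]]
      for (i in seq_len(ntip))
        term <- term * tipc[[i]][a[i], s]
      tot <- tot + term
    }
    ll <- ll + patterns$weights[s] * log(tot)
  }
  as.numeric(ll)
}

# counts table from a plain site x (pop, allele) specification
ct_from_list <- function(site_list, pops) {
  n <- length(site_list)
  counts <- array(0L, c(n, length(pops), 4))
  for (i in seq_len(n))
    counts[i, , ] <- site_list[[i]]
  counts_table(counts, pops)
}
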