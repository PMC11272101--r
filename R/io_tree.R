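#' Read and write Newick trees
#'
#' Thin wrappers around the ape Newick parser with the package's dialect:
#' rooted trees are accepted and preserved, duplicate leaf names are an
#' error, and edges without a branch length default to 0 with a warning.
#'
#' @param path File path (or, for \code{read_newick}, a literal Newick
#'   string containing a semicolon).
#' @return A \code{phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in Newick tree", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' @rdname read_newick
#' @param tree A \code{phylo} tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Write / read model parameters as a YAML manifest
#'
#' Round-trippable record of the generating parameters of a simulation.
#'
#' @param params A \code{pomo_params}.
#' @param path File path.
#' @return \code{path} (write) or a \code{pomo_params} (read).
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pomo_params"))
  x <- list(N = params$N, mode = params$mode,
            reversible = params$reversible, sigma = params$sigma)
  if (params$reversible) {
    x$pi <- as.numeric(params$pi); x$rho <- as.numeric(params$rho)
  } else {
    x$mu <- as.numeric(params$mu)
  }
  if (params$mode == "balance") {
    x$beta <- as.numeric(params$beta); x$B <- as.integer(params$B)
  }
  if (is.na(x$sigma)) { x$sigma <- NULL; x$phi <- as.numeric(params$phi) }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  # a bare `N:` key is YAML 1.1 boolean FALSE; accept it anyway
  if (is.null(x$N) && !is.null(x[["FALSE"]])) x$N <- x[["FALSE"]]
  pomo_params(N = x$N, pi = x$pi, rho = x$rho, mu = x$mu,
              sigma = if (is.null(x$sigma)) 0 else x$sigma,
              phi = x$phi,
              beta = if (is.null(x$beta)) 1 else x$beta,
              B = x$B,
              mode = if (is.null(x$mode)) "select" else x$mode)
}

#' Serialize a rate matrix as TSV (debugging aid)
#'
#' @param Q A \code{pomo_rate_matrix}.
#' @param path Output path.
#' @export
write_rate_matrix <- function(Q, path) {
  df <- data.frame(state = rownames(Q), unclass(Q), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
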