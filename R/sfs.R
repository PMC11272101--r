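#' Site frequency spectra on the PoMo state grid
#'
#' An SFS vector holds, for each of the six nucleotide pairs, the mass at
#' each of the N+1 ordered frequencies of the pair's first allele,
#' including the two monomorphic ends; monomorphic mass is shared between
#' the pairs containing the allele, and the whole object is normalized so
#' that the 4 monomorphic plus 6(N-1) polymorphic masses sum to 1.
#'
#' @param mono Named 4-vector of monomorphic masses (A, C, G, T).
#' @param poly 6 x (N-1) matrix of polymorphic masses (rows = pairs).
#' @param N Virtual population size.
#' @return An object of class \code{pomo_sfs}.
#' @export
pomo_sfs <- function(mono, poly, N) {
  stopifnot(length(mono) == 4, nrow(poly) == 6, ncol(poly) == N - 1,
            all(mono >= 0), all(poly >= 0))
  tot <- sum(mono) + sum(poly)
  if (tot <= 0) stop("empty spectrum", call. = FALSE)
  structure(list(mono = stats::setNames(as.numeric(mono) / tot, NUC),
                 poly = matrix(poly / tot, 6, N - 1,
                               dimnames = list(PAIRS, seq_len(N - 1))),
                 N = as.integer(N)),
            class = "pomo_sfs")
}

#' @export
print.pomo_sfs <- function(x, ...) {
  cat(sprintf("pomo_sfs (N = %d): monomorphic mass %.3f, polymorphic %.3f\n",
              x$N, sum(x$mono), sum(x$poly)))
  invisible(x)
}

#' Full per-pair matrix view of an SFS
#'
#' @param x A \code{pomo_sfs}.
#' @param ... Unused.
#' @return 6 x (N+1) matrix: per pair, the mass at first-allele frequency
#'   0..N; the boundary columns repeat the shared monomorphic masses.
#' @export
as.matrix.pomo_sfs <- function(x, ...) {
  m <- matrix(0, 6, x$N + 1, dimnames = list(PAIRS, 0:x$N))
  for (p in seq_along(PAIRS)) {
    a <- substr(PAIRS[p], 1, 1); b <- substr(PAIRS[p], 2, 2)
    m[p, 1] <- x$mono[b]
    m[p, x$N + 1] <- x$mono[a]
    m[p, 2:x$N] <- x$poly[p, ]
  }
  m
}

#' Empirical site frequency spectrum of a counts table
#'
#' Pools sites and populations. Monoallelic observations add their mass
#' to the monomorphic end states; biallelic observations are projected
#' onto the N-grid of the pair by binomial expectation: an observed split
#' of c out of S lands at fractional frequency N c/S, shared linearly
#' between the two neighbouring integer frequencies (splitting boundary
#' spill into the adjacent monomorphic state). Sites with three or more
#' alleles in a population are skipped with a logged count; missing
#' entries contribute nothing.
#'
#' @param table A \code{counts_table}.
#' @param N Virtual population size of the target grid.
#' @return A \code{pomo_sfs}.
#' @export
empirical_sfs <- function(table, N) {
  stopifnot(inherits(table, "counts_table"), N >= 2)
  mono <- stats::setNames(numeric(4), NUC)
  poly <- matrix(0, 6, N - 1, dimnames = list(PAIRS, NULL))
  skipped <- 0
  for (i in seq_len(table$n_sites)) {
    for (j in seq_along(table$pops)) {
      v <- table$counts[i, j, ]
      S <- sum(v)
      if (S == 0) next
      nz <- which(v > 0)
      if (length(nz) > 2) { skipped <- skipped + 1; next }
      if (length(nz) == 1) {
        mono[nz] <- mono[nz] + 1
        next
      }
      pair <- paste0(NUC[nz[1]], NUC[nz[2]])
      p <- match(pair, PAIRS)
      x <- N * v[nz[1]] / S              # fractional grid position in (0, N)
      lo <- floor(x); hi <- lo + 1
      w_hi <- x - lo
      put <- function(n, w) {
        if (w <= 0) return()
        if (n <= 0) mono[nz[2]] <<- mono[nz[2]] + w
        else if (n >= N) mono[nz[1]] <<- mono[nz[1]] + w
        else poly[p, n] <<- poly[p, n] + w
      }
      put(lo, 1 - w_hi)
      put(hi, w_hi)
    }
  }
  if (skipped > 0)
    message(sprintf("empirical_sfs: skipped %d entries with 3+ alleles",
                    skipped))
  pomo_sfs(mono, poly, N)
}

#' Expected site frequency spectrum of a PoMo model
#'
#' The stationary distribution of the rate matrix, reshaped onto the SFS
#' grid: under the model, the long-run distribution of PoMo states across
#' independent sites is exactly the stationary distribution, so its
#' polymorphic part is the expected SFS (with a balancing-selection peak
#' at the preferred frequency when beta is large).
#'
#' @param params A \code{pomo_params}.
#' @return A \code{pomo_sfs}.
#' @export
expected_sfs <- function(params) {
  space <- enumerate_states(params$N)
  Q <- build_rate_matrix(space, params)
  psi <- stationary_distribution(Q)
  mono <- psi[1:4]
  poly <- matrix(psi[-(1:4)], 6, params$N - 1, byrow = TRUE)
  pomo_sfs(mono, poly, params$N)
}

#' Total variation distance between two SFS objects
#'
#' @param a,b \code{pomo_sfs} objects on the same N.
#' @return Scalar in [0, 1].
#' @export
sfs_distance <- function(a, b) {
  stopifnot(inherits(a, "pomo_sfs"), inherits(b, "pomo_sfs"), a$N == b$N)
  (sum(abs(a$mono - b$mono)) + sum(abs(a$poly - b$poly))) / 2
}

#' Write an SFS as TSV
#'
#' @param sfs A \code{pomo_sfs}.
#' @param path Output path.
#' @export
write_sfs <- function(sfs, path) {
  m <- as.matrix(sfs)
  df <- data.frame(pair = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an empirical SFS against a model SFS
#'
#' Stars show the empirical spectrum, diamonds the model expectation, one
#' panel column per nucleotide pair.
#'
#' @param empirical,expected \code{pomo_sfs} objects on the same grid.
#' @param log_scale Plot mass on a log axis (default TRUE).
#' @export
plot_sfs <- function(empirical, expected = NULL, log_scale = TRUE) {
  me <- as.matrix(empirical)
  xs <- 0:empirical$N
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in seq_along(PAIRS)) {
    ylim <- range(c(me[p, ][me[p, ] > 0],
                    if (!is.null(expected)) as.matrix(expected)[p, ]), na.rm = TRUE)
    graphics::plot(xs, me[p, ], pch = 8, col = "steelblue",
                   log = if (log_scale) "y" else "",
                   ylim = ylim, xlab = "first-allele frequency",
                   ylab = "mass", main = PAIRS[p])
    if (!is.null(expected))
      graphics::points(xs, as.matrix(expected)[p, ], pch = 5, col = "firebrick")
  }
  invisible(NULL)
}
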