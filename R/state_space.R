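#' @useDynLib pomobalance, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

NUC <- c("A", "C", "G", "T")

# unordered nucleotide pairs, fixed ordering used throughout the package
PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Enumerate the PoMo state space
#'
#' A polymorphism-aware model over a virtual haploid population of size
#' \code{N} has 4 monomorphic (boundary) states, one per nucleotide, and
#' \code{6(N-1)} biallelic polymorphic states: for each unordered pair of
#' nucleotides, one state per frequency \code{n = 1..N-1} of the pair's
#' first allele. States are ordered monomorphic A, C, G, T, then pairs
#' AC, AG, AT, CG, CT, GT with \code{n} ascending.
#'
#' @param N Virtual haploid population size, integer \code{>= 2}.
#' @return An object of class \code{pomo_states} with fields \code{N},
#'   \code{K} (fixed at 4), \code{n_states}, and a data frame \code{states}
#'   with columns \code{type} ("mono"/"poly"), \code{pair}, \code{n},
#'   \code{first}, \code{second} and a human-readable \code{label}.
#' @examples
#' sp <- enumerate_states(4)
#' sp$n_states  # 22
#' @export
enumerate_states <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 2)
    stop("`N` must be a single integer >= 2", call. = FALSE)
  N <- as.integer(N)
  mono <- data.frame(
    type = "mono", pair = NA_character_, n = NA_integer_,
    first = NUC, second = NA_character_,
    label = NUC, stringsAsFactors = FALSE
  )
  poly <- do.call(rbind, lapply(PAIRS, function(p) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    data.frame(
      type = "poly", pair = p, n = seq_len(N - 1L),
      first = a, second = b,
      label = sprintf("%d%s%d%s", seq_len(N - 1L), a, N - seq_len(N - 1L), b),
      stringsAsFactors = FALSE
    )
  }))
  states <- rbind(mono, poly)
  rownames(states) <- NULL
  structure(
    list(N = N, K = 4L, n_states = nrow(states), states = states),
    class = "pomo_states"
  )
}

#' @export
print.pomo_states <- function(x, ...) {
  cat(sprintf("PoMo state space: N = %d, %d states (4 monomorphic + 6(N-1) polymorphic)\n",
              x$N, x$n_states))
  invisible(x)
}

#' State indices in the fixed PoMo ordering
#'
#' \code{state_index_mono} returns the index of the boundary state fixed
#' for \code{allele}; \code{state_index_poly} the index of the
#' polymorphic state of \code{pair} with \code{n} copies of the pair's
#' first allele.
#'
#' @param space A \code{pomo_states}.
#' @param allele One of "A", "C", "G", "T".
#' @return Integer state index.
#' @export
state_index_mono <- function(space, allele) {
  match(allele, NUC)
}

#' @rdname state_index_mono
#' @param pair One of "AC", "AG", "AT", "CG", "CT", "GT".
#' @param n Frequency of the pair's first allele, 1..N-1.
#' @export
state_index_poly <- function(space, pair, n) {
  p <- match(pair, PAIRS)
  stopifnot(!is.na(p), n >= 1, n <= space$N - 1)
  4L + (p - 1L) * (space$N - 1L) + as.integer(n)
}
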