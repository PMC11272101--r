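#' Per-site, per-population allele-count table
#'
#' The in-memory form of the cflib "counts" format: for every genomic site
#' and every population, a 4-vector of A, C, G, T allele counts. Missing
#' data are encoded as an all-zero count vector.
#'
#' @param counts Integer array of dimension \code{c(n_sites, n_pops, 4)}
#'   (last dimension ordered A, C, G, T).
#' @param pops Character vector of population names.
#' @param chrom Chromosome labels per site (default \code{"NA"}).
#' @param pos 1-based positions per site (default \code{1:n_sites}).
#' @return An object of class \code{counts_table}.
#' @export
counts_table <- function(counts, pops, chrom = NULL, pos = NULL) {
  if (length(dim(counts)) != 3 || dim(counts)[3] != 4)
    stop("`counts` must be an n_sites x n_pops x 4 array", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  n_sites <- dim(counts)[1]; n_pops <- dim(counts)[2]
  if (length(pops) != n_pops) stop("`pops` length must match dim(counts)[2]",
                                   call. = FALSE)
  if (is.null(chrom)) chrom <- rep("NA", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, pops, NUC)
  structure(list(counts = counts, pops = as.character(pops),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 n_sites = n_sites),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table: %d sites x %d populations (%s)\n",
              x$n_sites, length(x$pops), paste(x$pops, collapse = ", ")))
  invisible(x)
}

#' Read a counts file
#'
#' Parses the cflib counts format: a header line
#' \code{COUNTSFILE NPOP <n> NSITES <m>}, a column line
#' \code{CHROM POS <pop...>}, then one row per site with comma-separated
#' A,C,G,T counts per population. An entry of dashes (e.g. \code{-,-,-,-}
#' or \code{-}) is read as missing and stored as \code{0,0,0,0}.
#'
#' @param path Path to the counts file.
#' @return A \code{counts_table}.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("counts file too short", call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 5 || hdr[1] != "COUNTSFILE" || hdr[2] != "NPOP" ||
      hdr[4] != "NSITES" || anyNA(suppressWarnings(as.integer(hdr[c(3, 5)]))))
    stop("line 1: malformed header, expected 'COUNTSFILE NPOP <n> NSITES <m>'",
         call. = FALSE)
  npop <- as.integer(hdr[3]); nsites <- as.integer(hdr[5])
  cols <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(cols) != npop + 2 || cols[1] != "CHROM" || cols[2] != "POS")
    stop("line 2: malformed column line, expected 'CHROM POS <pop ...>'",
         call. = FALSE)
  pops <- cols[-(1:2)]
  body <- lines[-(1:2)]
  if (length(body) != nsites)
    stop(sprintf("declared NSITES %d but found %d site rows", nsites,
                 length(body)), call. = FALSE)
  counts <- array(0L, c(nsites, npop, 4))
  chrom <- character(nsites); pos <- integer(nsites)
  for (i in seq_len(nsites)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != npop + 2)
      stop(sprintf("line %d: expected %d fields, found %d", i + 2,
                   npop + 2, length(f)), call. = FALSE)
    chrom[i] <- f[1]
    pos[i] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[i]))
      stop(sprintf("line %d: non-integer position '%s'", i + 2, f[2]),
           call. = FALSE)
    for (j in seq_len(npop)) {
      entry <- f[j + 2]
      if (grepl("^-(,-)*$", entry)) next  # missing
      parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
      if (length(parts) != 4)
        stop(sprintf("line %d: population %s has %d comma-separated counts, expected 4",
                     i + 2, pops[j], length(parts)), call. = FALSE)
      v <- suppressWarnings(as.integer(parts))
      if (anyNA(v) || any(v < 0))
        stop(sprintf("line %d: non-integer allele count in '%s'", i + 2,
                     entry), call. = FALSE)
      counts[i, j, ] <- v
    }
  }
  counts_table(counts, pops, chrom, pos)
}

#' Write a counts file
#'
#' @param table A \code{counts_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "counts_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("COUNTSFILE NPOP %d NSITES %d", length(table$pops),
                     table$n_sites), con)
  writeLines(paste(c("CHROM", "POS", table$pops), collapse = " "), con)
  for (i in seq_len(table$n_sites)) {
    cells <- apply(table$counts[i, , , drop = FALSE], 2,
                   function(v) paste(v, collapse = ","))
    writeLines(paste(c(table$chrom[i], table$pos[i], cells), collapse = " "),
               con)
  }
  invisible(path)
}

#' Drop sites with too much missing data
#'
#' A site/population is missing when its count vector is all zero. Sites
#' where the missing fraction exceeds \code{max_missing_fraction} are
#' removed; the default threshold of 0.5 drops sites with more than 50
#' percent missing populations.
#'
#' @param table A \code{counts_table}.
#' @param max_missing_fraction Retain a site when its fraction of missing
#'   populations is less than or equal to this value.
#' @return Filtered \code{counts_table}; the number of dropped sites is
#'   reported with a message and stored in attribute \code{"n_dropped"}.
#' @export
filter_missing <- function(table, max_missing_fraction = 0.5) {
  stopifnot(inherits(table, "counts_table"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  tot <- apply(table$counts, c(1, 2), sum)      # site x pop totals
  frac <- rowMeans(tot == 0)
  keep <- frac <= max_missing_fraction
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("filter_missing: dropped %d of %d sites (> %.0f%% missing)",
                    dropped, table$n_sites, 100 * max_missing_fraction))
  out <- counts_table(table$counts[keep, , , drop = FALSE], table$pops,
                      table$chrom[keep], table$pos[keep])
  attr(out, "n_dropped") <- dropped
  out
}

#' Tally aligned FASTA sequences into a counts table
#'
#' Each population is given as a multi-sequence FASTA of equal-length
#' aligned sequences (or an already-parsed character matrix); per
#' alignment column the A/C/G/T characters are tallied per population.
#' Gaps, N and any other character count as missing.
#'
#' @param fastas Named list mapping population name to a FASTA file path.
#' @return A \code{counts_table} with one site per alignment column.
#' @export
fasta_to_counts <- function(fastas) {
  if (is.null(names(fastas)) || any(!nzchar(names(fastas))))
    stop("`fastas` must be a named list (population name -> FASTA path)",
         call. = FALSE)
  mats <- lapply(fastas, function(f) {
    seqs <- as.character(ape::read.FASTA(f))
    if (length(unique(lengths(seqs))) != 1)
      stop("ragged alignment within a population", call. = FALSE)
    toupper(do.call(rbind, seqs))
  })
  lens <- unlist(lapply(mats, ncol))
  if (length(unique(lens)) != 1)
    stop("ragged alignment: populations have different sequence lengths",
         call. = FALSE)
  L <- lens[1]
  npop <- length(mats)
  counts <- array(0L, c(L, npop, 4))
  for (j in seq_len(npop)) {
    m <- mats[[j]]
    for (a in seq_along(NUC))
      counts[, j, a] <- colSums(m == NUC[a])
  }
  counts_table(counts, names(fastas))
}
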