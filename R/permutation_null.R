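# Permutation-null abundance control: shuffled variants of a core should be
# absent from the reads, and the probability of that absence under a
# uniform-random base model is computable in closed form.

# log of the number of distinct orderings of the multiset of bases of x
.log_n_distinct_perms <- function(x) {
  counts <- table(strsplit(x, "", fixed = TRUE)[[1L]])
  lfactorial(nchar(x)) - sum(lfactorial(counts))
}

#' Generate distinct random permutations of a sequence
#'
#' Draws \code{K} distinct shuffles of the bases of \code{core}, none equal
#' to \code{core} itself, by shuffle-with-rejection against a seen-set.
#' Reproducible given \code{rng_seed}.
#'
#' @param core nucleotide string.
#' @param K number of distinct permutations requested.
#' @param rng_seed integer seed.
#' @return character vector of \code{K} distinct permutations of
#'   \code{core}'s bases.
#' @export
generate_distinct_permutations <- function(core, K, rng_seed = 1L) {
  core <- normalize_rna(core)
  n_avail <- exp(.log_n_distinct_perms(core)) - 1  # identity excluded
  if (K > n_avail + 1e-9) {
    stop("K = ", K, " exceeds the ", format(round(n_avail), scientific = FALSE),
         " distinct non-identity permutations available for '", core, "'")
  }
  bases <- strsplit(core, "", fixed = TRUE)[[1L]]
  set.seed(rng_seed)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(core, TRUE, envir = seen)
  out <- character(K)
  got <- 0L
  while (got < K) {
    p <- paste(sample(bases), collapse = "")
    if (!exists(p, envir = seen, inherits = FALSE)) {
      assign(p, TRUE, envir = seen)
      got <- got + 1L
      out[got] <- p
    }
  }
  out
}

#' Count reads containing each pattern
#'
#' @param patterns character vector of patterns.
#' @param reads character vector of read sequences (or a data.frame with a
#'   \code{sequence} column).
#' @return named integer vector: for each pattern, the number of reads that
#'   contain it as an exact substring.
#' @export
search_patterns_in_reads <- function(patterns, reads) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- normalize_rna(reads)
  patterns <- normalize_rna(patterns)
  vapply(patterns, function(p) sum(grepl(p, reads, fixed = TRUE)),
         integer(1L), USE.NAMES = TRUE)
}

#' Closed-form probability that no pattern is seen
#'
#' Probability, under a uniform-random base model with independence across
#' positions and patterns, that none of \code{K} random k-mers occurs at any
#' of the \code{L - k + 1} positions of any of \code{M} random L-mers:
#' \deqn{(1 - 4^{-k})^{K \cdot M \cdot (L-k+1)}.}
#' Overlap dependence between nearby positions is deliberately ignored;
#' the Monte-Carlo companion \code{\link{p_none_monte_carlo}} validates the
#' approximation.
#'
#' @param K number of patterns.
#' @param M number of random sequences searched.
#' @param L length of each searched sequence (nt).
#' @param k pattern length (nt).
#' @return probability in [0, 1].
#' @examples
#' p_none(1000, 1e6, 30, 16)  # ~0.0304
#' @export
p_none <- function(K, M, L, k) {
  if (k > L) stop("pattern length k exceeds sequence length L")
  if (K < 0 || M < 0) stop("K and M must be non-negative")
  if (K == 0 || M == 0) return(1)
  exp(K * M * (L - k + 1) * log1p(-4^(-k)))
}

#' Monte-Carlo check of the closed-form no-occurrence probability
#'
#' Simulates \code{n_trials} independent experiments: draw \code{K} random
#' k-mers and \code{M} random L-mers (uniform base composition) and record
#' whether no k-mer occurs in any L-mer.
#'
#' @inheritParams p_none
#' @param n_trials number of simulated experiments.
#' @param rng_seed integer seed.
#' @return list with \code{estimate} (fraction of no-occurrence trials),
#'   \code{se} (binomial standard error), \code{n_trials}.
#' @export
p_none_monte_carlo <- function(K, M, L, k, n_trials = 2000L, rng_seed = 1L) {
  if (k > L) stop("pattern length k exceeds sequence length L")
  if (K == 0 || M == 0) {
    return(list(estimate = 1, se = 0, n_trials = as.integer(n_trials)))
  }
  set.seed(rng_seed)
  bases <- c("A", "C", "G", "U")
  none <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    pats <- unique(vapply(seq_len(K), function(i)
      paste(sample(bases, k, replace = TRUE), collapse = ""),
      character(1L)))
    # one big string with '.' separators so matches cannot span reads
    m <- matrix(sample(bases, M * L, replace = TRUE), nrow = L)
    hay <- paste(rbind(m, "."), collapse = "")
    found <- FALSE
    for (p in pats) {
      if (grepl(p, hay, fixed = TRUE)) { found <- TRUE; break }
    }
    none[t] <- !found
  }
  est <- mean(none)
  list(estimate = est,
       se = sqrt(est * (1 - est) / n_trials),
       n_trials = as.integer(n_trials))
}

#' Run the permutation-null control for a core against a read set
#'
#' Generates \code{K} distinct permutations of \code{core}, counts how many
#' occur in the reads, and reports the closed-form probability that none
#' would occur under the uniform-random model.
#'
#' @param core nucleotide string (the core sequence).
#' @param reads character vector of read sequences or a data.frame with a
#'   \code{sequence} column.
#' @param K number of distinct permutations (default 1000).
#' @param rng_seed integer seed.
#' @return one-row data.frame: \code{core}, \code{K}, \code{M},
#'   \code{L} (read length, the maximum over reads), \code{k},
#'   \code{n_found} (permutations observed in at least one read),
#'   \code{p_none_analytic}.
#' @export
permutation_null_test <- function(core, reads, K = 1000L, rng_seed = 1L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  core <- normalize_rna(core)
  reads <- normalize_rna(reads)
  perms <- generate_distinct_permutations(core, K, rng_seed)
  hits <- search_patterns_in_reads(perms, reads)
  L <- if (length(reads)) max(nchar(reads)) else 0L
  k <- nchar(core)
  data.frame(core = core, K = as.integer(K), M = length(reads),
             L = L, k = k,
             n_found = sum(hits > 0L),
             p_none_analytic = if (L >= k) p_none(K, length(reads), L, k)
                               else 1,
             stringsAsFactors = FALSE)
}
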