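# miRNA-style target scanning: maximal exact reverse-complement blocks
# between a core sequence and 3'UTRs, plus a seed-redundancy check against
# mature miRNAs.

#' Reverse complement of an RNA string
#'
#' @param seq character vector of normalized RNA strings (N allowed, maps
#'   to N).
#' @return character vector of reverse complements (A-U, C-G pairing).
#'   An involution: applying it twice returns the input.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_rna(seq)
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAStringSet(seq)))
  unname(out)
}

#' All k-mer windows of a core
#'
#' @param core nucleotide string.
#' @param k window length (default 7, the miRNA seed length).
#' @return data.frame with columns \code{start} (1-based), \code{kmer}, in
#'   5' to 3' order; empty (with a warning) when \code{k > nchar(core)}.
#' @export
kmer_windows <- function(core, k = 7L) {
  core <- normalize_rna(core)
  n <- nchar(core)
  if (k > n) {
    warning("k = ", k, " exceeds core length ", n, "; no windows")
    return(data.frame(start = integer(), kmer = character(),
                      stringsAsFactors = FALSE))
  }
  st <- seq_len(n - k + 1L)
  data.frame(start = st, kmer = substring(core, st, st + k - 1L),
             stringsAsFactors = FALSE)
}

# maximal common-substring runs between two strings, as diagonal runs of
# the character match matrix; returns a/b start positions and lengths
.maximal_runs <- function(a, b, min_len) {
  va <- .explode(a); vb <- .explode(b)
  na <- length(va); nb <- length(vb)
  if (na == 0L || nb == 0L) {
    return(data.frame(a_start = integer(), b_start = integer(),
                      len = integer()))
  }
  eq <- outer(va, vb, "==")
  res <- list()
  for (d in seq(-(na - 1L), nb - 1L)) {
    i0 <- max(1L, 1L - d); j0 <- i0 + d
    len_d <- min(na - i0, nb - j0) + 1L
    diag_vals <- eq[cbind(i0 + seq_len(len_d) - 1L, j0 + seq_len(len_d) - 1L)]
    r <- rle(diag_vals)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      st <- ends[h] - r$lengths[h] + 1L
      res[[length(res) + 1L]] <- c(i0 + st - 1L, j0 + st - 1L,
                                   r$lengths[h])
    }
  }
  if (length(res) == 0L) {
    return(data.frame(a_start = integer(), b_start = integer(),
                      len = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(a_start = m[, 1L], b_start = m[, 2L], len = m[, 3L])
}

#' Find maximal reverse-complement target sites of a core in a UTR
#'
#' Reports every maximal block where a segment of the core is the exact
#' reverse complement of a UTR segment, of length at least
#' \code{min_site_len}.  Maximality means the block cannot be extended in
#' either direction; no G:U wobble is allowed.
#'
#' @param core a core sequence string, or a one-row data.frame with
#'   \code{core_id}/\code{sequence} columns (as from
#'   \code{\link{extract_cores}}).
#' @param utr a UTR sequence string, or a one-row data.frame with
#'   \code{id}/\code{sequence} columns (as from \code{\link{read_fasta}}).
#' @param min_site_len minimum block length (default 7, the seed length;
#'   biologically meaningful sites are outputs, not thresholds).
#' @param core_id,utr_id ids used when plain strings are supplied.
#' @return data.frame with columns \code{core_id}, \code{utr_id},
#'   \code{utr_start}, \code{utr_end}, \code{core_start}, \code{core_end}
#'   (all 1-based inclusive), \code{match_len}, \code{matched_block} (the
#'   UTR-side sequence), sorted by \code{utr_start}.  Every row satisfies
#'   \code{reverse_complement(core[core_start..core_end]) ==
#'   utr[utr_start..utr_end]}.
#' @export
find_target_sites <- function(core, utr, min_site_len = 7L,
                              core_id = "core", utr_id = "utr") {
  if (is.data.frame(core)) {
    core_id <- if ("core_id" %in% names(core)) core$core_id[1L] else core$id[1L]
    core <- core$sequence[1L]
  }
  if (is.data.frame(utr)) {
    utr_id <- utr$id[1L]
    utr <- utr$sequence[1L]
  }
  core <- normalize_rna(core)
  utr <- normalize_rna(utr)
  rc <- reverse_complement(core)
  runs <- .maximal_runs(rc, utr, min_site_len)
  nc <- nchar(core)
  if (nrow(runs) == 0L) {
    return(data.frame(core_id = character(), utr_id = character(),
                      utr_start = integer(), utr_end = integer(),
                      core_start = integer(), core_end = integer(),
                      match_len = integer(), matched_block = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    core_id = rep(core_id, nrow(runs)),
    utr_id = rep(utr_id, nrow(runs)),
    utr_start = runs$b_start,
    utr_end = runs$b_start + runs$len - 1L,
    core_start = nc - (runs$a_start + runs$len - 1L) + 1L,
    core_end = nc - runs$a_start + 1L,
    match_len = runs$len,
    matched_block = substring(utr, runs$b_start,
                              runs$b_start + runs$len - 1L),
    stringsAsFactors = FALSE)
  out <- out[order(out$utr_start, out$utr_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many cores against many UTRs
#'
#' @param cores data.frame from \code{\link{extract_cores}}.
#' @param utrs data.frame from \code{\link{read_fasta}}.
#' @inheritParams find_target_sites
#' @return row-bound data.frame of \code{\link{find_target_sites}} results.
#' @export
find_all_target_sites <- function(cores, utrs, min_site_len = 7L) {
  res <- list()
  for (i in seq_len(nrow(cores))) for (j in seq_len(nrow(utrs))) {
    res[[length(res) + 1L]] <- find_target_sites(
      cores$sequence[i], utrs$sequence[j], min_site_len,
      core_id = cores$core_id[i], utr_id = utrs$id[j])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) find_target_sites("A", "A", 1L)[0L, ] else out
}

#' Read a mature-miRNA table and derive seeds
#'
#' Seeds are nucleotides 2-8 (1-based inclusive) of each mature sequence.
#' Records with mature length below 8 are skipped with a warning.
#'
#' @param path TSV with columns \code{mirna_id}, \code{mature_sequence};
#'   or a data.frame with those columns.
#' @return data.frame with columns \code{mirna_id},
#'   \code{mature_sequence}, \code{seed}.
#' @export
read_seed_table <- function(path) {
  df <- if (is.data.frame(path)) path else read.delim(path)
  if (!all(c("mirna_id", "mature_sequence") %in% names(df))) {
    stop("seed table must have columns mirna_id, mature_sequence")
  }
  df$mature_sequence <- normalize_rna(df$mature_sequence)
  short <- nchar(df$mature_sequence) < 8L
  if (any(short)) {
    warning("skipped ", sum(short),
            " seed record(s) with mature length < 8")
    df <- df[!short, , drop = FALSE]
  }
  df$seed <- substring(df$mature_sequence, 2L, 8L)
  rownames(df) <- NULL
  df
}

#' Check a core's 7-mers against miRNA seeds
#'
#' Reports every exact equality between a 7-nt window of the core and a
#' miRNA seed.  An empty result means targeting by the core would not be
#' redundant with the supplied miRNA set.
#'
#' @param core nucleotide string.
#' @param seeds data.frame from \code{\link{read_seed_table}}.
#' @return data.frame with columns \code{window_start}, \code{kmer},
#'   \code{mirna_id}.
#' @export
seed_overlap <- function(core, seeds) {
  win <- kmer_windows(core, 7L)
  if (nrow(win) == 0L || nrow(seeds) == 0L) {
    return(data.frame(window_start = integer(), kmer = character(),
                      mirna_id = character(), stringsAsFactors = FALSE))
  }
  grid <- merge(win, seeds[, c("mirna_id", "seed")], by = NULL)
  hit <- grid[grid$kmer == grid$seed, , drop = FALSE]
  hit <- hit[order(hit$start, hit$mirna_id), , drop = FALSE]
  data.frame(window_start = hit$start, kmer = hit$kmer,
             mirna_id = hit$mirna_id, stringsAsFactors = FALSE,
             row.names = NULL)
}
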