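# Stem-loop enumeration and stability scoring.
#
# The model is deliberately restricted to perfect stem-loops (no bulges,
# internal loops or multiloops): contiguous Watson-Crick / G:U-wobble pair
# stacks closed by a single-stranded loop.  Free energies are a
# nearest-neighbour sum of stacking terms plus a hairpin-loop initiation
# term (with tetraloop replacement energies), which is enough to rank
# hairpins by stability; exact agreement with full folding engines is not a
# goal, and externally computed energies can be substituted via
# load_external_energies().

.explode <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Enumerate maximal perfect stem-loops
#'
#' Considers every loop placement of length \code{min_loop} to
#' \code{max_loop} and extends complementary pairs (Watson-Crick plus G:U
#' wobble) outward until a mismatch or the sequence end.  A placement is
#' reported only when its loop cannot be shrunk by pairing its end bases
#' (so each physical hairpin appears once) and its stem has at least
#' \code{min_stem_pairs} pairs.  Reported hairpins are maximal: none is
#' outward-extendable.
#'
#' @param seq nucleotide string (normalized internally).
#' @param min_stem_pairs minimum number of stem pairs.
#' @param min_loop minimum loop length (>= 3; smaller loops are sterically
#'   impossible).
#' @param max_loop maximum loop length.
#' @return data.frame, one row per hairpin: \code{start}, \code{end}
#'   (1-based inclusive span), \code{loop_start}, \code{loop_len},
#'   \code{n_stem_pairs}, \code{gc_pair_count} (stem pairs that are C-G or
#'   G-C), \code{L} (span length), \code{sequence}, \code{structure}
#'   (dot-bracket).
#' @export
enumerate_hairpins <- function(seq, min_stem_pairs = 2L, min_loop = 3L,
                               max_loop = 30L) {
  if (min_loop < 3L) stop("min_loop must be >= 3 (sterically impossible loops)")
  seq <- normalize_rna(seq)
  v <- .explode(seq)
  n <- length(v)
  empty <- data.frame(start = integer(), end = integer(),
                      loop_start = integer(), loop_len = integer(),
                      n_stem_pairs = integer(), gc_pair_count = integer(),
                      L = integer(), sequence = character(),
                      structure = character(), stringsAsFactors = FALSE)
  if (n < min_loop + 2L) return(empty)
  cand <- expand.grid(a = 2L:(n - 1L), len = min_loop:max_loop)
  cand$b <- cand$a + cand$len - 1L
  cand <- cand[cand$b <= n - 1L, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # first outward pair must exist
  keep <- .can_pair(v[cand$a - 1L], v[cand$b + 1L])
  # loop must not be shrinkable into a smaller legal loop
  shrinkable <- .can_pair(v[cand$a], v[cand$b]) &
    (cand$len - 2L >= min_loop)
  cand <- cand[keep & !shrinkable, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  np <- integer(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]
    k <- 1L
    while (a - 1L - k >= 1L && b + 1L + k <= n &&
           .can_pair(v[a - 1L - k], v[b + 1L + k])) {
      k <- k + 1L
    }
    np[r] <- k
  }
  sel <- np >= min_stem_pairs
  cand <- cand[sel, , drop = FALSE]
  np <- np[sel]
  if (nrow(cand) == 0L) return(empty)
  start <- cand$a - np
  end <- cand$b + np
  gc <- vapply(seq_len(nrow(cand)), function(r) {
    i <- seq_len(np[r])
    sum(paste0(v[start[r] + i - 1L], v[end[r] - i + 1L]) %in% c("GC", "CG"))
  }, integer(1L))
  out <- data.frame(
    start = start, end = end,
    loop_start = cand$a, loop_len = cand$len,
    n_stem_pairs = np, gc_pair_count = gc,
    L = end - start + 1L,
    sequence = substring(seq, start, end),
    structure = paste0(strrep("(", np), strrep(".", cand$len),
                       strrep(")", np)),
    stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Nearest-neighbour free energy of perfect stem-loops
#'
#' dG = sum of stacking terms over adjacent stem pairs + hairpin-loop
#' initiation for the loop size (replaced by the tabulated tetraloop energy
#' when the closing pair + 4-nt loop context is listed).  Loops larger than
#' the table are extrapolated with the standard logarithmic
#' (Jacobson-Stockmayer) correction.
#'
#' @param hairpins data.frame from \code{\link{enumerate_hairpins}}.
#' @param seq the parent sequence the coordinates refer to.
#' @param params an \code{\link{energy_parameters}} object.
#' @return numeric vector of dG values (kcal/mol), one per hairpin.
#' @export
hairpin_energy <- function(hairpins, seq, params = energy_parameters()) {
  seq <- normalize_rna(seq)
  v <- .explode(seq)
  n_tab <- length(params$loop)
  rt37 <- 1.9872e-3 * 310.15
  vapply(seq_len(nrow(hairpins)), function(r) {
    h <- hairpins[r, ]
    i <- seq_len(h$n_stem_pairs)
    pair_types <- paste0(v[h$start + i - 1L], v[h$end - i + 1L])
    bad <- setdiff(pair_types, .pair_types)
    if (length(bad)) {
      stop("non-canonical stem pair '", bad[1L], "' in hairpin at ",
           h$start, "-", h$end)
    }
    stacks <- 0
    if (h$n_stem_pairs >= 2L) {
      keys <- paste0(pair_types[-h$n_stem_pairs], ":", pair_types[-1L])
      miss <- setdiff(keys, names(params$stack))
      if (length(miss)) {
        stop("stacking parameter missing for pair combination ", miss[1L])
      }
      stacks <- sum(params$stack[keys])
    }
    loop_term <- if (h$loop_len <= n_tab) {
      params$loop[h$loop_len]
    } else {
      params$loop[n_tab] + 1.75 * rt37 * log(h$loop_len / n_tab)
    }
    if (h$loop_len == 4L) {
      ctx <- substring(seq, h$loop_start - 1L, h$loop_start + 4L)
      if (ctx %in% names(params$tetraloop)) {
        loop_term <- unname(params$tetraloop[ctx])
      }
    }
    stacks + loop_term
  }, numeric(1L))
}

#' Stability scores of energy-annotated hairpins
#'
#' Adds the stability ratio -dG/L (kcal/mol per nt) and the minimal folding
#' free energy index MFEI = -dG / (number of G and C nucleotides in the
#' hairpin span).  The two satisfy
#' \code{stability_ratio * L == mfei * gc_nt_count} (both equal -dG).
#' MFEI is NA when the span contains no G or C.
#'
#' @param hairpins data.frame with columns from
#'   \code{\link{enumerate_hairpins}} plus \code{dG}.
#' @return the data.frame with added columns \code{gc_nt_count},
#'   \code{stability_ratio}, \code{mfei}.
#' @export
score_hairpin <- function(hairpins) {
  stopifnot("dG" %in% names(hairpins))
  gc_nt <- nchar(gsub("[^GC]", "", hairpins$sequence))
  hairpins$gc_nt_count <- gc_nt
  hairpins$stability_ratio <- -hairpins$dG / hairpins$L
  hairpins$mfei <- ifelse(gc_nt > 0L, -hairpins$dG / gc_nt, NA_real_)
  hairpins
}

#' Load externally computed hairpin energies
#'
#' Lets a full folding engine's energies replace the internal
#' nearest-neighbour values: a TSV with columns \code{parent_id},
#' \code{start}, \code{end} (1-based inclusive span) and \code{dG}.
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
load_external_energies <- function(path) {
  df <- read.delim(path)
  need <- c("parent_id", "start", "end", "dG")
  if (!all(need %in% names(df))) {
    stop("external energy table must have columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$dG) | df$end <= df$start)
  if (length(bad)) {
    stop("malformed external energy row ", bad[1L],
         " (need finite dG and end > start)")
  }
  df[, need]
}

#' Scan an ncRNA for stable hairpins with sliding windows
#'
#' Enumerates perfect stem-loops within overlapping windows, pools and
#' deduplicates them, drops window-truncated stems (hairpins still
#' extendable in the full sequence), computes energies and scores, and
#' retains hairpins spanning at least \code{min_span} nt with stability
#' ratio at least \code{min_ratio}.
#'
#' @param seq either a nucleotide string or a one-row data.frame with
#'   \code{id} and \code{sequence} (as from \code{\link{read_fasta}}).
#' @param id parent id used when \code{seq} is a plain string.
#' @param window window size in nt (default 50); sequences shorter than the
#'   window are scanned as a single window.
#' @param step window step in nt (default 5).
#' @param min_span minimum hairpin span L in nt (default 25).
#' @param min_ratio minimum stability ratio -dG/L (default 0.30).
#' @param min_loop,max_loop loop length bounds passed to
#'   \code{\link{enumerate_hairpins}}.
#' @param params an \code{\link{energy_parameters}} object.
#' @param external_energies optional data.frame from
#'   \code{\link{load_external_energies}}; matching spans get the external
#'   dG and \code{energy_source = "external-table"}.
#' @return scored data.frame (columns of \code{\link{enumerate_hairpins}}
#'   plus \code{parent_id}, \code{dG}, \code{energy_source},
#'   \code{gc_nt_count}, \code{stability_ratio}, \code{mfei}), sorted by
#'   stability ratio descending.
#' @export
scan_ncrna <- function(seq, id = "seq", window = 50L, step = 5L,
                       min_span = 25L, min_ratio = 0.30,
                       min_loop = 3L, max_loop = 30L,
                       params = energy_parameters(),
                       external_energies = NULL) {
  if (is.data.frame(seq)) {
    id <- seq$id[1L]
    seq <- seq$sequence[1L]
  }
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  starts <- if (n <= window) 1L else unique(c(seq(1L, n - window + 1L, by = step),
                                              n - window + 1L))
  found <- do.call(rbind, lapply(starts, function(s) {
    w <- substring(seq, s, min(n, s + window - 1L))
    h <- enumerate_hairpins(w, min_stem_pairs = 2L,
                            min_loop = min_loop, max_loop = max_loop)
    if (nrow(h) == 0L) return(h)
    h$start <- h$start + s - 1L
    h$end <- h$end + s - 1L
    h$loop_start <- h$loop_start + s - 1L
    h
  }))
  out_cols <- c("parent_id", "start", "end", "loop_start", "loop_len",
                "n_stem_pairs", "gc_pair_count", "L", "sequence",
                "structure", "dG", "energy_source", "gc_nt_count",
                "stability_ratio", "mfei")
  if (is.null(found) || nrow(found) == 0L) {
    found <- enumerate_hairpins(seq, 2L, min_loop, max_loop)[0L, ]
  }
  found <- found[!duplicated(found[, c("start", "end", "loop_start")]), ,
                 drop = FALSE]
  if (nrow(found)) {
    # drop window-truncated stems: still extendable in the parent
    v <- .explode(seq)
    ext <- found$start > 1L & found$end < n &
      .can_pair(v[pmax(found$start - 1L, 1L)], v[pmin(found$end + 1L, n)])
    found <- found[!ext, , drop = FALSE]
  }
  if (nrow(found) == 0L) {
    empty <- enumerate_hairpins("AAAA", 2L)
    empty$parent_id <- character()
    empty$dG <- numeric()
    empty$energy_source <- character()
    return(score_hairpin(empty)[, out_cols])
  }
  found$dG <- hairpin_energy(found, seq, params)
  found$energy_source <- "internal-model"
  found$parent_id <- id
  if (!is.null(external_energies) && nrow(external_energies)) {
    key <- paste(found$parent_id, found$start, found$end)
    ekey <- paste(external_energies$parent_id, external_energies$start,
                  external_energies$end)
    hit <- match(key, ekey)
    found$dG[!is.na(hit)] <- external_energies$dG[hit[!is.na(hit)]]
    found$energy_source[!is.na(hit)] <- "external-table"
  }
  found <- score_hairpin(found)
  found <- found[found$L >= min_span & found$stability_ratio >= min_ratio, ,
                 drop = FALSE]
  found <- found[order(-found$stability_ratio, found$start), , drop = FALSE]
  rownames(found) <- NULL
  found[, out_cols]
}

#' Reconstruct a stem-loop from a core sequence
#'
#' Treats the first \code{loop_len} bases of the core as the loop and the
#' remaining bases as the 3' side of the stem, and prepends the strict
#' Watson-Crick reverse complement of the 3' side as the 5' side, yielding
#' a perfect hairpin that contains the core as its loop + 3' side.
#'
#' @param core nucleotide string, longer than \code{loop_len}.
#' @param loop_len loop length (default 4).
#' @param params an \code{\link{energy_parameters}} object used to assign
#'   dG; the result is scored like any enumerated hairpin.
#' @param id parent id recorded for the built sequence.
#' @return one-row data.frame in the schema of \code{\link{scan_ncrna}};
#'   \code{sequence} is the full built hairpin, whose length is
#'   \code{2 * (nchar(core) - loop_len) + loop_len}.
#' @examples
#' h <- reconstruct_hairpin("UUCGCGCUUUCCCCUG", 4)
#' h$L               # 28
#' h$n_stem_pairs    # 12
#' h$gc_pair_count   # 8
#' @export
reconstruct_hairpin <- function(core, loop_len = 4L,
                                params = energy_parameters(),
                                id = "reconstructed") {
  core <- normalize_rna(core)
  if (nchar(core) <= loop_len) stop("core must be longer than loop_len")
  loop <- substring(core, 1L, loop_len)
  side3 <- substring(core, loop_len + 1L, nchar(core))
  # strict Watson-Crick complement for the built 5' side (no wobble)
  side5 <- paste(rev(.explode(chartr("ACGU", "UGCA", side3))), collapse = "")
  seq <- paste0(side5, loop, side3)
  np <- nchar(side3)
  v <- .explode(seq)
  i <- seq_len(np)
  h <- data.frame(
    start = 1L, end = nchar(seq),
    loop_start = np + 1L, loop_len = as.integer(loop_len),
    n_stem_pairs = np,
    gc_pair_count = sum(paste0(v[i], v[nchar(seq) - i + 1L]) %in%
                          c("GC", "CG")),
    L = nchar(seq),
    sequence = seq,
    structure = paste0(strrep("(", np), strrep(".", loop_len),
                       strrep(")", np)),
    stringsAsFactors = FALSE)
  h$dG <- hairpin_energy(h, seq, params)
  h$energy_source <- "internal-model"
  h$parent_id <- id
  h <- score_hairpin(h)
  h[, c("parent_id", "start", "end", "loop_start", "loop_len",
        "n_stem_pairs", "gc_pair_count", "L", "sequence", "structure",
        "dG", "energy_source", "gc_nt_count", "stability_ratio", "mfei")]
}
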