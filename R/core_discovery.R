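# Core discovery: collapse retained inserts to exact-copy counts, then
# cluster them into shared exact subsequences ("cores") of >= 16 nt by a
# deterministic greedy longest-common-substring procedure.

#' Collapse inserts to exact-copy counts
#'
#' @param inserts character vector of retained insert sequences.
#' @return data.frame with columns \code{sequence}, \code{count}, one row
#'   per distinct string, sorted by count descending then sequence.
#'   Counts sum to \code{length(inserts)}.
#' @export
collapse_exact <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Keep sequences observed at least \code{min_copies} times
#'
#' @param counted data.frame from \code{\link{collapse_exact}}.
#' @param min_copies minimum exact-copy count (default 3).
#' @return filtered data.frame.
#' @export
abundance_filter <- function(counted, min_copies = 3L) {
  counted[counted$count >= min_copies, , drop = FALSE] |>
    `rownames<-`(NULL)
}

# All substrings of x with length >= min_len (unique).
.substrings <- function(x, min_len = 1L) {
  n <- nchar(x)
  if (n < min_len) return(character())
  out <- unlist(lapply(min_len:n, function(l) {
    st <- seq_len(n - l + 1L)
    substring(x, st, st + l - 1L)
  }))
  unique(out)
}

# All longest common substrings of two strings with length >= min_len;
# returns character() when none qualifies.  Suffix-matrix dynamic program.
.lcs_pair <- function(a, b, min_len = 1L) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ca); nb <- length(cb)
  if (na == 0L || nb == 0L) return(character())
  best <- 0L; ends <- integer()
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(cb == ca[i])
    if (length(match_j)) {
      cur[match_j] <- 1L + c(0L, prev)[match_j]
      mx <- max(cur[match_j])
      if (mx > best) {
        best <- mx
        ends <- i * 10000L + match_j[cur[match_j] == mx]
      } else if (mx == best && best > 0L) {
        ends <- c(ends, i * 10000L + match_j[cur[match_j] == mx])
      }
    }
    prev <- cur
  }
  if (best < min_len) return(character())
  i <- ends %/% 10000L
  sort(unique(substring(a, i - best + 1L, i)))
}

# All longest common substrings (length >= min_len) shared by every member
# of a character vector; character() when none.
.lcs_set <- function(members, min_len = 1L) {
  if (length(members) == 1L) {
    return(if (nchar(members) >= min_len) members else character())
  }
  shortest <- members[which.min(nchar(members))]
  n <- nchar(shortest)
  if (n < min_len) return(character())
  others <- members[-which.min(nchar(members))]
  for (l in seq(n, min_len)) {
    st <- seq_len(n - l + 1L)
    cand <- unique(substring(shortest, st, st + l - 1L))
    ok <- cand[vapply(cand, function(s)
      all(vapply(others, grepl, logical(1L), pattern = s, fixed = TRUE)),
      logical(1L))]
    if (length(ok)) return(sort(ok))
  }
  character()
}

#' Cluster counted sequences into core sequences
#'
#' Deterministic greedy clustering on exact shared substrings.  Repeatedly,
#' among all remaining pairs, the longest common substring of length at
#' least \code{min_core_len} is found; every remaining sequence containing
#' that substring is absorbed into one cluster, whose core is the longest
#' substring common to all absorbed members.  Ties are broken by higher
#' total instance count, then by lexicographic order of the core.
#' Sequences sharing no qualifying substring with any other become
#' singleton cores (the sequence itself).
#'
#' @param counted data.frame with columns \code{sequence}, \code{count}
#'   (from \code{\link{abundance_filter}}).
#' @param min_core_len minimum core length (default 16).
#' @return data.frame with columns \code{core_id}, \code{sequence},
#'   \code{length}, \code{instance_count}, \code{n_members},
#'   \code{members} (semicolon-joined member sequences), sorted by
#'   \code{instance_count} descending then sequence.  Every input sequence
#'   is a member of exactly one core; instance counts are conserved.
#' @export
extract_cores <- function(counted, min_core_len = 16L) {
  min_core_len <- as.integer(min_core_len)
  if (min_core_len < 1L) stop("min_core_len must be >= 1")
  seqs <- counted$sequence
  counts <- counted$count
  cores <- list()
  while (length(seqs) > 0L) {
    n <- length(seqs)
    seeds <- character()
    best_len <- 0L
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        ls <- .lcs_pair(seqs[i], seqs[j], min_core_len)
        if (length(ls)) {
          l <- nchar(ls[1L])
          if (l > best_len) { best_len <- l; seeds <- ls }
          else if (l == best_len) seeds <- c(seeds, ls)
        }
      }
    }
    if (best_len == 0L) {
      # no qualifying shared substring remains: singletons
      keep <- nchar(seqs) >= min_core_len
      if (any(!keep)) {
        message("extract_cores: ", sum(!keep), " sequence(s) shorter than ",
                min_core_len, " nt left unclustered and dropped")
      }
      cores <- c(cores, lapply(which(keep), function(i) {
        list(core = seqs[i], members = seqs[i], count = counts[i])
      }))
      break
    }
    seeds <- unique(seeds)
    # evaluate each candidate seed: absorbed members and final core
    cand <- lapply(seeds, function(s) {
      idx <- which(vapply(seqs, grepl, logical(1L), pattern = s,
                          fixed = TRUE))
      core <- .lcs_set(seqs[idx], min_core_len)[1L]  # lex-smallest
      list(core = core, idx = idx, count = sum(counts[idx]))
    })
    tot <- vapply(cand, `[[`, numeric(1L), "count")
    core_str <- vapply(cand, `[[`, character(1L), "core")
    pick <- cand[[order(-tot, core_str)[1L]]]
    cores <- c(cores, list(list(core = pick$core,
                                members = seqs[pick$idx],
                                count = pick$count)))
    seqs <- seqs[-pick$idx]
    counts <- counts[-pick$idx]
  }
  if (length(cores) == 0L) {
    return(data.frame(core_id = character(), sequence = character(),
                      length = integer(), instance_count = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    sequence = vapply(cores, `[[`, character(1L), "core"),
    instance_count = vapply(cores, function(x) as.integer(x$count),
                            integer(1L)),
    n_members = vapply(cores, function(x) length(x$members), integer(1L)),
    members = vapply(cores, function(x)
      paste(sort(x$members), collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  out <- out[order(-out$instance_count, out$sequence), , drop = FALSE]
  out$core_id <- paste0("core_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("core_id", "sequence", "length", "instance_count",
          "n_members", "members")]
}
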