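# Brute-force oracles, kept deliberately independent of the package's
# implementations: plain loops over every candidate, no shared helpers.

oracle_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# every (start, end, n_pairs) triple tested directly
oracle_hairpins <- function(seq, min_stem_pairs = 2L, min_loop = 3L,
                            max_loop = 30L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  res <- list()
  for (s in seq_len(max(n - 1L, 0L))) for (e in seq(s + 1L, length.out = n - s)) {
    span <- e - s + 1L
    for (p in seq_len(max((span - min_loop) %/% 2L, 0L))) {
      loop <- span - 2L * p
      if (loop < min_loop || loop > max_loop || p < min_stem_pairs) next
      pairs_ok <- TRUE
      for (i in seq_len(p)) {
        if (!oracle_can_pair(v[s + i - 1L], v[e - i + 1L])) {
          pairs_ok <- FALSE
          break
        }
      }
      if (!pairs_ok) next
      if (s > 1L && e < n && oracle_can_pair(v[s - 1L], v[e + 1L])) next
      if (loop - 2L >= min_loop && oracle_can_pair(v[s + p], v[e - p])) next
      res[[length(res) + 1L]] <- c(s, e, p, loop)
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      n_stem_pairs = integer(), loop_len = integer()))
  }
  m <- do.call(rbind, res)
  out <- data.frame(start = m[, 1L], end = m[, 2L], n_stem_pairs = m[, 3L],
                    loop_len = m[, 4L])
  out[order(out$start, out$end), , drop = FALSE] |> `rownames<-`(NULL)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# every (core substring, utr position) pair tested for reverse-complement
# equality; only maximal (non-extendable) matches kept
oracle_target_sites <- function(core, utr, min_site_len = 7L) {
  rc <- oracle_revcomp(core)
  nr <- nchar(rc); nu <- nchar(utr)
  res <- list()
  for (i in seq_len(nr)) for (len in seq(min_site_len, nr - i + 1L)) {
    if (len > nr - i + 1L) break
    sub <- substr(rc, i, i + len - 1L)
    for (j in seq_len(nu - len + 1L)) {
      if (substr(utr, j, j + len - 1L) != sub) next
      left_ext <- i > 1L && j > 1L &&
        substr(rc, i - 1L, i - 1L) == substr(utr, j - 1L, j - 1L)
      right_ext <- i + len <= nr && j + len <= nu &&
        substr(rc, i + len, i + len) == substr(utr, j + len, j + len)
      if (!left_ext && !right_ext) {
        res[[length(res) + 1L]] <- c(i, j, len)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(utr_start = integer(), utr_end = integer(),
                      core_start = integer(), core_end = integer(),
                      match_len = integer()))
  }
  m <- unique(do.call(rbind, res))
  out <- data.frame(
    utr_start = m[, 2L], utr_end = m[, 2L] + m[, 3L] - 1L,
    core_start = nchar(core) - (m[, 1L] + m[, 3L] - 1L) + 1L,
    core_end = nchar(core) - m[, 1L] + 1L,
    match_len = m[, 3L])
  out[order(out$utr_start, out$utr_end), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# greedy core clustering by exhaustive candidate-substring enumeration:
# every substring of every remaining sequence is a candidate; the winner
# maximizes (length, total count, lexicographically smallest)
oracle_extract_cores <- function(counted, min_core_len = 16L) {
  seqs <- counted$sequence
  counts <- counted$count
  all_subs <- function(x) {
    n <- nchar(x)
    if (n < min_core_len) return(character())
    unlist(lapply(min_core_len:n, function(l) {
      st <- seq_len(n - l + 1L)
      substring(x, st, st + l - 1L)
    }))
  }
  out <- list()
  repeat {
    if (!length(seqs)) break
    cands <- unique(unlist(lapply(seqs, all_subs)))
    members <- lapply(cands, function(s) which(grepl(s, seqs, fixed = TRUE)))
    shared <- lengths(members) >= 2L
    if (!any(shared)) {
      for (i in seq_along(seqs)) {
        if (nchar(seqs[i]) >= min_core_len) {
          out[[length(out) + 1L]] <- list(core = seqs[i],
                                          members = seqs[i],
                                          count = counts[i])
        }
      }
      break
    }
    cands <- cands[shared]
    members <- members[shared]
    tot <- vapply(members, function(i) sum(counts[i]), numeric(1L))
    best <- order(-nchar(cands), -tot, cands)[1L]
    out[[length(out) + 1L]] <- list(core = cands[best],
                                    members = seqs[members[[best]]],
                                    count = tot[best])
    seqs <- seqs[-members[[best]]]
    counts <- counts[-members[[best]]]
  }
  df <- data.frame(
    sequence = vapply(out, `[[`, character(1L), "core"),
    instance_count = vapply(out, function(x) as.integer(x$count),
                            integer(1L)),
    n_members = vapply(out, function(x) length(x$members), integer(1L)),
    stringsAsFactors = FALSE)
  df[order(-df$instance_count, df$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
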