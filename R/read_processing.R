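#' Trimming configuration
#'
#' Bundles the parameters of the read-cleanup stage: the Illumina 3'
#' adapter, the minimum adapter prefix that must be seen to anchor the
#' insert's 3' boundary, the cap on trailing A removal, and the retained
#' insert length range.
#'
#' @param adapter adapter sequence (DNA or RNA spelling; normalized
#'   internally).  Default is the Illumina small-RNA 3' adapter.
#' @param min_adapter_prefix minimum number of adapter bases that must
#'   match (default 6).
#' @param max_polyA maximum number of trailing A's removed (default 4).
#' @param min_len,max_len retained insert length range (defaults 16, 29).
#' @return object of class \code{trim_config}.
#' @export
trim_config <- function(adapter = "TCTCGTATGCCGTCTTCTGCTTGAAA",
                        min_adapter_prefix = 6L,
                        max_polyA = 4L,
                        min_len = 16L, max_len = 29L) {
  adapter <- normalize_rna(adapter)
  if (min_adapter_prefix < 1L || min_adapter_prefix > nchar(adapter)) {
    stop("min_adapter_prefix must be between 1 and the adapter length (",
         nchar(adapter), ")")
  }
  if (min_len > max_len) stop("min_len must not exceed max_len")
  structure(list(adapter = adapter,
                 min_adapter_prefix = as.integer(min_adapter_prefix),
                 max_polyA = as.integer(max_polyA),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "trim_config")
}

#' Locate and remove the 3' adapter from reads
#'
#' Finds, per read, the leftmost position where a prefix of the adapter of
#' at least \code{min_adapter_prefix} bases matches exactly and either runs
#' to the read's 3' end or covers the whole adapter (concatenated-adapter
#' case).  The insert is everything before that position.  Reads without
#' such a match are flagged \code{adapter_found = FALSE}: the insert's 3'
#' boundary is unknown, so they are discarded downstream unless
#' \code{keep_unanchored} is set in \code{\link{trim_reads}}.
#'
#' @param sequences character vector of normalized read sequences.
#' @param config a \code{\link{trim_config}}.
#' @return data.frame with columns \code{insert}, \code{adapter_found},
#'   \code{adapter_start} (1-based position of the adapter match, NA when
#'   absent).
#' @export
trim_adapter <- function(sequences, config = trim_config()) {
  stopifnot(inherits(config, "trim_config"))
  sequences <- normalize_rna(sequences)
  n <- nchar(sequences)
  alen <- nchar(config$adapter)
  # 3'-anchored match: longest m with read suffix == adapter[1..m]
  pos <- rep(NA_integer_, length(sequences))
  m_hi <- if (length(n)) min(alen, max(n)) else 0L
  for (m in if (m_hi >= config$min_adapter_prefix)
         seq(m_hi, config$min_adapter_prefix) else integer()) {
    prefix <- substr(config$adapter, 1L, m)
    hit <- is.na(pos) & n >= m & substr(sequences, n - m + 1L, n) == prefix
    pos[hit] <- n[hit] - m + 1L
  }
  # full-adapter match anywhere (adapter followed by more bases)
  full <- regexpr(config$adapter, sequences, fixed = TRUE)
  better <- full > 0L & (is.na(pos) | full < pos)
  pos[better] <- full[better]
  data.frame(
    insert = ifelse(is.na(pos), sequences, substr(sequences, 1L, pos - 1L)),
    adapter_found = !is.na(pos),
    adapter_start = pos,
    stringsAsFactors = FALSE)
}

#' Trim trailing A's from inserts
#'
#' Removes up to \code{max_polyA} consecutive A's from the 3' end of each
#' insert (poly-A tailing is part of the library protocol, not the insert).
#'
#' @param inserts character vector of normalized insert sequences.
#' @param max_polyA cap on the number of A's removed (default 4).
#' @return data.frame with columns \code{insert}, \code{polyA_removed}.
#' @export
trim_polyA <- function(inserts, max_polyA = 4L) {
  inserts <- normalize_rna(inserts)
  n_trailing <- nchar(inserts) - nchar(sub("A*$", "", inserts))
  removed <- pmin(n_trailing, as.integer(max_polyA))
  data.frame(
    insert = substr(inserts, 1L, nchar(inserts) - removed),
    polyA_removed = removed,
    stringsAsFactors = FALSE)
}

#' Insert length filter
#'
#' @param inserts character vector of insert sequences.
#' @param config a \code{\link{trim_config}}.
#' @return logical vector: TRUE iff \code{min_len <= length <= max_len}.
#' @export
length_filter <- function(inserts, config = trim_config()) {
  nchar(inserts) >= config$min_len & nchar(inserts) <= config$max_len
}

#' Full read-cleanup pipeline
#'
#' Applies, in order: adapter removal (\code{\link{trim_adapter}}),
#' poly-A trimming (\code{\link{trim_polyA}}) and the insert length filter
#' (\code{\link{length_filter}}).  The per-read table records the outcome of
#' every stage; the attached \code{"summary"} attribute carries the count
#' conservation identity
#' \code{reads_in = retained + discarded_no_adapter + discarded_length}.
#'
#' @param reads data.frame with columns \code{id}, \code{sequence}
#'   (e.g. from \code{\link{read_fastq}}).
#' @param config a \code{\link{trim_config}}.
#' @param keep_unanchored keep reads without an adapter hit (their full
#'   sequence becomes the insert)?  Default FALSE.
#' @return data.frame with columns \code{source_id}, \code{insert},
#'   \code{adapter_found}, \code{adapter_start}, \code{polyA_removed},
#'   \code{retained}, \code{discard_reason} (NA, \code{"no_adapter"} or
#'   \code{"length"}); attribute \code{"summary"} is a named integer vector.
#' @export
trim_reads <- function(reads, config = trim_config(),
                       keep_unanchored = FALSE) {
  ad <- trim_adapter(reads$sequence, config)
  pa <- trim_polyA(ad$insert, config$max_polyA)
  keep_len <- length_filter(pa$insert, config)
  anchored <- ad$adapter_found | keep_unanchored
  retained <- anchored & keep_len
  reason <- rep(NA_character_, nrow(reads))
  reason[!anchored] <- "no_adapter"
  reason[anchored & !keep_len] <- "length"
  out <- data.frame(
    source_id = reads$id,
    insert = pa$insert,
    adapter_found = ad$adapter_found,
    adapter_start = ad$adapter_start,
    polyA_removed = pa$polyA_removed,
    retained = retained,
    discard_reason = reason,
    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    reads_in = nrow(reads),
    retained = sum(retained),
    discarded_no_adapter = sum(!anchored),
    discarded_length = sum(anchored & !keep_len))
  out
}
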