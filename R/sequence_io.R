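#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and replaces every T with U, so that DNA and RNA spellings of
#' the same molecule compare equal everywhere downstream.
#'
#' @param sequence character vector of nucleotide strings.
#' @return character vector of the same length, uppercase RNA spelling.
#'   Idempotent: applying it twice equals applying it once.
#' @examples
#' normalize_rna("TTCGCGCTTTCCCCTG")  # "UUCGCGCUUUCCCCUG"
#' @export
normalize_rna <- function(sequence) {
  chartr("Tt", "Uu", toupper(sequence))
}

.valid_alphabet <- function(x) !grepl("[^ACGUN]", normalize_rna(x))

#' Read small-RNA reads from a FASTQ file
#'
#' Parses plain (optionally gzipped) 4-line-record FASTQ.  Quality lines are
#' discarded; sequences are uppercased and normalized to the RNA alphabet.
#' Reads containing N are dropped with a message, since every downstream
#' step relies on exact string identity; the number dropped is attached as
#' attribute \code{"n_dropped_N"}.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines, not a multiple of 4 (last complete record ends at line ",
         4L * (length(lines) %/% 4L), ")")
  }
  if (length(lines) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped_N") <- 0L
    return(out)
  }
  rec <- matrix(lines, nrow = 4L)
  bad_hdr <- which(substr(rec[1L, ], 1L, 1L) != "@")
  if (length(bad_hdr)) {
    stop("malformed FASTQ '", path, "': record ", bad_hdr[1L],
         " header at line ", 4L * (bad_hdr[1L] - 1L) + 1L,
         " does not start with '@'")
  }
  bad_sep <- which(substr(rec[3L, ], 1L, 1L) != "+")
  if (length(bad_sep)) {
    stop("malformed FASTQ '", path, "': record ", bad_sep[1L],
         " separator at line ", 4L * (bad_sep[1L] - 1L) + 3L,
         " does not start with '+'")
  }
  id <- sub("^@", "", sub("\\s.*$", "", rec[1L, ]))
  sequence <- normalize_rna(rec[2L, ])
  has_n <- grepl("N", sequence, fixed = TRUE)
  if (any(has_n)) {
    message("read_fastq: dropped ", sum(has_n), " read(s) containing N")
  }
  out <- data.frame(id = id[!has_n], sequence = sequence[!has_n],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_N") <- sum(has_n)
  out
}

#' Read reads from a plain one-sequence-per-line text file
#'
#' Alternative to FASTQ input: one sequence per line, ids generated as
#' \code{read_<line>}.  N-containing reads are dropped as in
#' \code{\link{read_fastq}}.
#'
#' @param path path to a text file.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_plain_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sequence <- normalize_rna(lines)
  bad <- grepl("[^ACGUN]", sequence)
  if (any(bad)) {
    stop("non-nucleotide characters on line ", which(bad)[1L])
  }
  has_n <- grepl("N", sequence, fixed = TRUE)
  if (any(has_n)) {
    message("read_plain_reads: dropped ", sum(has_n),
            " read(s) containing N")
  }
  out <- data.frame(
    id = paste0("read_", seq_along(sequence))[!has_n],
    sequence = sequence[!has_n], stringsAsFactors = FALSE)
  attr(out, "n_dropped_N") <- sum(has_n)
  out
}

#' Read named sequences from a FASTA file
#'
#' Wraps \code{Biostrings::readBStringSet}, then validates the alphabet,
#' normalizes to RNA spelling and checks id uniqueness.  The id is the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @param kind one of \code{"ncRNA"}, \code{"UTR"}, \code{"miRNA"}; recorded
#'   per sequence.
#' @return data.frame with columns \code{id}, \code{sequence}, \code{kind}.
#' @export
read_fasta <- function(path, kind = c("ncRNA", "UTR", "miRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  id <- sub("\\s.*$", "", names(set))
  sequence <- normalize_rna(as.character(set))
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- grepl("[^ACGUN]", sequence)
  if (any(bad)) {
    stop("sequence '", id[which(bad)[1L]],
         "' contains characters outside the A/C/G/T/U/N alphabet")
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id '", id[which(!nzchar(sequence))[1L]], "'")
  }
  data.frame(id = id, sequence = unname(sequence), kind = kind,
             stringsAsFactors = FALSE)
}

#' Write named sequences to a FASTA file
#'
#' @param seqs data.frame with columns \code{id}, \code{sequence}.
#' @param path output path.
#' @param spelling \code{"RNA"} (U) or \code{"DNA"} (T) output alphabet.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, spelling = c("RNA", "DNA")) {
  spelling <- match.arg(spelling)
  s <- normalize_rna(seqs$sequence)
  if (spelling == "DNA") s <- chartr("U", "T", s)
  set <- Biostrings::BStringSet(setNames(s, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a FASTQ file with constant quality
#'
#' Minimal writer used by the read simulator; quality is a constant 'I'
#' since no pipeline stage is quality-aware.
#'
#' @param reads data.frame with columns \code{id}, \code{sequence}.
#' @param path output path.
#' @param spelling output alphabet as in \code{\link{write_fasta}}; reads
#'   default to DNA spelling, matching real sequencer output.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path, spelling = c("DNA", "RNA")) {
  spelling <- match.arg(spelling)
  s <- normalize_rna(reads$sequence)
  if (spelling == "DNA") s <- chartr("U", "T", s)
  qual <- strrep("I", nchar(s))
  writeLines(as.vector(rbind(paste0("@", reads$id), s, "+", qual)), path)
  invisible(path)
}
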