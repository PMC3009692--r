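#' Run the full colligation pipeline
#'
#' Convenience wrapper chaining the five analysis stages: read cleanup,
#' core discovery, hairpin scanning, target scanning, and the triple join.
#'
#' @param reads data.frame of reads (\code{id}, \code{sequence}) or a
#'   FASTQ path.
#' @param ncrnas data.frame of ncRNAs (\code{id}, \code{sequence}) or a
#'   FASTA path.
#' @param utrs data.frame of UTRs or a FASTA path.
#' @param rnp_links data.frame or TSV path of RNP links.
#' @param config a \code{\link{trim_config}}.
#' @param min_copies minimum exact-copy count (default 3).
#' @param min_core_len minimum core length (default 16).
#' @param window,step,min_span,min_ratio hairpin-scan parameters (see
#'   \code{\link{scan_ncrna}}).
#' @param min_site_len minimum target-site length (default 7).
#' @param overlap_min minimum core-in-hairpin overlap fraction (default
#'   0.8).
#' @param params an \code{\link{energy_parameters}} object.
#' @param external_energies optional data.frame from
#'   \code{\link{load_external_energies}}.
#' @return list with elements \code{trimmed}, \code{counted},
#'   \code{cores}, \code{hairpins}, \code{sites}, \code{records}.
#' @export
run_pipeline <- function(reads, ncrnas, utrs, rnp_links,
                         config = trim_config(),
                         min_copies = 3L, min_core_len = 16L,
                         window = 50L, step = 5L, min_span = 25L,
                         min_ratio = 0.30, min_site_len = 7L,
                         overlap_min = 0.8,
                         params = energy_parameters(),
                         external_energies = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.character(ncrnas)) ncrnas <- read_fasta(ncrnas, "ncRNA")
  if (is.character(utrs)) utrs <- read_fasta(utrs, "UTR")
  rnp_links <- read_rnp_links(rnp_links)
  trimmed <- trim_reads(reads, config)
  counted <- collapse_exact(trimmed$insert[trimmed$retained])
  filtered <- abundance_filter(counted, min_copies)
  cores <- extract_cores(filtered, min_core_len)
  hairpins <- do.call(rbind, lapply(seq_len(nrow(ncrnas)), function(i) {
    scan_ncrna(ncrnas[i, ], window = window, step = step,
               min_span = min_span, min_ratio = min_ratio,
               params = params, external_energies = external_energies)
  }))
  if (is.null(hairpins)) hairpins <- scan_ncrna("AAAA")[0L, ]
  sites <- find_all_target_sites(cores, utrs, min_site_len)
  records <- colligate(cores, hairpins, sites, rnp_links, ncrnas,
                       overlap_min = overlap_min, min_ratio = min_ratio,
                       min_site_len = min_site_len)
  list(trimmed = trimmed, counted = counted, cores = cores,
       hairpins = hairpins, sites = sites, records = records)
}
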