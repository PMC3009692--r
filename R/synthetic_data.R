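# Synthetic-data generator with planted ground truth.  Every generator is a
# pure function of (config, seed): identical inputs give identical output.
# Backgrounds are rejection-sampled so that the planted signal is the only
# one each downstream stage can find, which makes recovery tests exact.

#' Simulation configuration
#'
#' Defaults describe a small-RNA library of 35-base reads whose planted
#' inserts are the 16-nt core UUCGCGCUUUCCCCUG followed by 0-4 templated
#' A's and the Illumina 3' adapter, a 164-nt ncRNA carrying the 28-nt
#' reconstructed hairpin of that core, and a 3'UTR carrying the reverse
#' complements of an 11-nt and a 9-nt segment of the core.
#'
#' @param rng_seed integer seed.
#' @param n_reads total number of reads (planted + background).
#' @param read_len read length in nt (default 35).
#' @param adapter 3' adapter sequence.
#' @param planted_cores list of \code{list(sequence =, abundance =)}.
#' @param polyA_distribution probabilities of 0-4 trailing A's (length 5,
#'   sums to 1); uniform by default.
#' @param flank_max maximum random bases added on each side of a planted
#'   insert (default 0, so each planted insert is exactly its core and the
#'   core's instance count equals the planted abundance).
#' @param ncrna_id,ncrna_len id and length of the synthetic ncRNA.
#' @param planted_hairpin_core core whose reconstructed hairpin is embedded
#'   in the ncRNA (NULL for a background-only ncRNA).
#' @param hairpin_loop_len loop length used by the reconstruction.
#' @param utr_id,utr_len id and length of the synthetic 3'UTR.
#' @param planted_sites list of 1-based inclusive core intervals whose
#'   reverse complements are embedded in the UTR; defaults plant an 11-nt
#'   (positions 3-13) and a 9-nt (positions 8-16) block.
#' @param complex_name RNP complex name linking the ncRNA to the UTR gene.
#' @param min_site_len,min_span,min_ratio thresholds the rejection sampler
#'   guards against (no spurious signal passing them).
#' @param max_retries rejection-sampling retry cap.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(rng_seed = 1L,
                              n_reads = 2000L,
                              read_len = 35L,
                              adapter = "TCTCGTATGCCGTCTTCTGCTTGAAA",
                              planted_cores = list(
                                list(sequence = "UUCGCGCUUUCCCCUG",
                                     abundance = 300L)),
                              polyA_distribution = rep(0.2, 5L),
                              flank_max = 0L,
                              ncrna_id = "RNU1L1",
                              ncrna_len = 164L,
                              planted_hairpin_core = "UUCGCGCUUUCCCCUG",
                              hairpin_loop_len = 4L,
                              utr_id = "SFRS1L1",
                              utr_len = 150L,
                              planted_sites = list(c(3L, 13L), c(8L, 16L)),
                              complex_name = "U1-snRNP-like",
                              min_site_len = 7L,
                              min_span = 25L,
                              min_ratio = 0.30,
                              max_retries = 200L) {
  stopifnot(length(polyA_distribution) == 5L,
            abs(sum(polyA_distribution) - 1) < 1e-8,
            all(polyA_distribution >= 0))
  cfg <- list(rng_seed = as.integer(rng_seed), n_reads = as.integer(n_reads),
              read_len = as.integer(read_len),
              adapter = normalize_rna(adapter),
              planted_cores = lapply(planted_cores, function(p) {
                stopifnot(p$abundance >= 1L)
                list(sequence = normalize_rna(p$sequence),
                     abundance = as.integer(p$abundance))
              }),
              polyA_distribution = polyA_distribution,
              flank_max = as.integer(flank_max),
              ncrna_id = ncrna_id, ncrna_len = as.integer(ncrna_len),
              planted_hairpin_core =
                if (is.null(planted_hairpin_core)) NULL
                else normalize_rna(planted_hairpin_core),
              hairpin_loop_len = as.integer(hairpin_loop_len),
              utr_id = utr_id, utr_len = as.integer(utr_len),
              planted_sites = planted_sites,
              complex_name = complex_name,
              min_site_len = as.integer(min_site_len),
              min_span = as.integer(min_span), min_ratio = min_ratio,
              max_retries = as.integer(max_retries))
  class(cfg) <- "simulation_config"
  cfg
}

.random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Simulate a small-RNA read library with planted cores
#'
#' Planted reads are insert (core with up to \code{flank_max} random bases
#' each side) + trailing A's + adapter, truncated to \code{read_len}.
#' Background reads are uniform-random and rejection-sampled so that none
#' contains a planted core and none survives default trimming, so the
#' retained set is exactly the planted set.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param fastq,truth optional output paths (FASTQ in DNA spelling; truth
#'   TSV).
#' @return list with \code{reads} (data.frame \code{id}, \code{sequence},
#'   RNA spelling) and \code{truth} (data.frame \code{read_id},
#'   \code{core}, \code{insert}, \code{polyA}).
#' @export
simulate_reads <- function(config = simulation_config(), fastq = NULL,
                           truth = NULL) {
  set.seed(config$rng_seed)
  tc <- trim_config(adapter = config$adapter)
  for (p in config$planted_cores) {
    if (nchar(p$sequence) + 2L * config$flank_max +
        tc$min_adapter_prefix > config$read_len) {
      stop("planted insert plus ", tc$min_adapter_prefix,
           " adapter bases exceeds read_len")
    }
  }
  planted <- list()
  for (p in config$planted_cores) {
    for (i in seq_len(p$abundance)) {
      f5 <- if (config$flank_max) .random_rna(sample(0:config$flank_max, 1L))
            else ""
      f3 <- if (config$flank_max) .random_rna(sample(0:config$flank_max, 1L))
            else ""
      insert <- paste0(f5, p$sequence, f3)
      polyA <- sample(0:4, 1L, prob = config$polyA_distribution)
      read <- substr(paste0(insert, strrep("A", polyA), config$adapter),
                     1L, config$read_len)
      planted[[length(planted) + 1L]] <-
        data.frame(sequence = read, core = p$sequence, insert = insert,
                   polyA = polyA, stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, planted)
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  n_bg <- config$n_reads - n_planted
  if (n_bg < 0L) stop("n_reads smaller than total planted abundance")
  core_seqs <- vapply(config$planted_cores, `[[`, character(1L), "sequence")
  bg <- character(0L)
  tries <- 0L
  while (length(bg) < n_bg) {
    tries <- tries + 1L
    if (tries > config$max_retries) {
      stop("could not sample clean background reads; relax config")
    }
    needed <- n_bg - length(bg)
    m <- matrix(sample(c("A", "C", "G", "U"),
                       needed * config$read_len, replace = TRUE),
                nrow = config$read_len)
    cand <- apply(m, 2L, paste, collapse = "")
    contains_core <- Reduce(`|`, lapply(core_seqs, function(s)
      grepl(s, cand, fixed = TRUE)), rep(FALSE, needed))
    tr <- trim_reads(data.frame(id = seq_along(cand), sequence = cand), tc)
    bg <- c(bg, cand[!contains_core & !tr$retained])
  }
  sequences <- c(if (n_planted) planted$sequence, bg)
  ids <- sprintf("read_%05d", seq_along(sequences))
  reads <- data.frame(id = ids, sequence = sequences,
                      stringsAsFactors = FALSE)
  truth_df <- if (n_planted) {
    data.frame(read_id = ids[seq_len(n_planted)], core = planted$core,
               insert = planted$insert, polyA = planted$polyA,
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(), core = character(),
               insert = character(), polyA = integer(),
               stringsAsFactors = FALSE)
  }
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth)) {
    write.table(truth_df, truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(reads = reads, truth = truth_df)
}

#' Simulate an ncRNA with one planted stable hairpin
#'
#' Embeds the reconstructed hairpin of \code{planted_hairpin_core} at a
#' random offset in a uniform-random background, rejection-sampled until a
#' hairpin scan of the whole molecule reports exactly the planted span (or,
#' for a background-only config, nothing).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param fasta,truth optional output paths.
#' @return list with \code{ncrna} (data.frame \code{id}, \code{sequence}),
#'   \code{truth} (planted span), \code{hairpin} (the planted hairpin row,
#'   NULL when background-only).
#' @export
simulate_ncrna <- function(config = simulation_config(), fasta = NULL,
                           truth = NULL) {
  set.seed(config$rng_seed + 1L)
  core <- config$planted_hairpin_core
  hp <- if (!is.null(core)) {
    reconstruct_hairpin(core, config$hairpin_loop_len, id = config$ncrna_id)
  } else NULL
  hp_len <- if (is.null(hp)) 0L else hp$L
  if (config$ncrna_len < hp_len + 2L) {
    stop("ncrna_len too short for the reconstructed hairpin")
  }
  for (try in seq_len(config$max_retries)) {
    if (is.null(hp)) {
      cand <- .random_rna(config$ncrna_len)
      offset <- NA_integer_
    } else {
      offset <- sample(2L:(config$ncrna_len - hp_len), 1L)
      bg <- .random_rna(config$ncrna_len - hp_len)
      cand <- paste0(substr(bg, 1L, offset - 1L), hp$sequence,
                     substring(bg, offset))
    }
    found <- scan_ncrna(cand, id = config$ncrna_id,
                        min_span = config$min_span,
                        min_ratio = config$min_ratio)
    ok <- if (is.null(hp)) {
      nrow(found) == 0L
    } else {
      nrow(found) == 1L && found$start == offset &&
        found$end == offset + hp_len - 1L &&
        length(gregexpr(core, cand, fixed = TRUE)[[1L]]) == 1L
    }
    if (ok) break
    if (try == config$max_retries) {
      stop("ncRNA background rejection sampling exhausted ",
           config$max_retries, " retries; use a longer background or ",
           "looser criteria")
    }
  }
  ncrna <- data.frame(id = config$ncrna_id, sequence = cand,
                      kind = "ncRNA", stringsAsFactors = FALSE)
  truth_df <- data.frame(
    ncrna_id = config$ncrna_id,
    hairpin_start = if (is.null(hp)) NA_integer_ else offset,
    hairpin_end = if (is.null(hp)) NA_integer_ else offset + hp_len - 1L,
    core = if (is.null(hp)) NA_character_ else core,
    stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(ncrna, fasta)
  if (!is.null(truth)) {
    write.table(truth_df, truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(ncrna = ncrna, truth = truth_df, hairpin = hp)
}

#' Simulate a 3'UTR with planted reverse-complement target sites
#'
#' Plants the reverse complements of the configured core intervals at
#' non-overlapping random offsets in a uniform-random background,
#' rejection-sampled until a target scan reports exactly the planted sites.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param fasta,truth optional output paths.
#' @return list with \code{utr} (data.frame), \code{truth} (data.frame
#'   \code{utr_id}, \code{utr_start}, \code{utr_end}, \code{core_start},
#'   \code{core_end}, \code{match_len}).
#' @export
simulate_utr <- function(config = simulation_config(), fasta = NULL,
                         truth = NULL) {
  set.seed(config$rng_seed + 2L)
  core <- config$planted_cores[[1L]]$sequence
  blocks <- vapply(config$planted_sites, function(iv) {
    reverse_complement(substring(core, iv[1L], iv[2L]))
  }, character(1L))
  need <- sum(nchar(blocks)) + 2L * (length(blocks) + 1L)
  if (config$utr_len < need) stop("utr_len too short for the planted sites")
  for (try in seq_len(config$max_retries)) {
    # choose non-overlapping offsets with >= 2 nt gaps, left to right
    lens <- nchar(blocks)
    slack <- config$utr_len - sum(lens) - 2L * (length(blocks) + 1L)
    gaps <- if (length(blocks)) {
      extra <- if (slack > 0L) {
        tabulate(sample.int(length(blocks) + 1L, slack, replace = TRUE),
                 nbins = length(blocks) + 1L)
      } else rep(0L, length(blocks) + 1L)
      2L + extra
    } else config$utr_len
    offsets <- integer(length(blocks))
    pos <- 1L
    pieces <- character()
    for (b in seq_along(blocks)) {
      pieces <- c(pieces, .random_rna(gaps[b]))
      pos <- pos + gaps[b]
      offsets[b] <- pos
      pieces <- c(pieces, blocks[b])
      pos <- pos + lens[b]
    }
    pieces <- c(pieces, .random_rna(config$utr_len - pos + 1L))
    cand <- paste(pieces, collapse = "")
    sites <- find_target_sites(core, cand, config$min_site_len)
    want <- data.frame(utr_start = offsets, match_len = lens)
    ok <- nrow(sites) == length(blocks) &&
      (length(blocks) == 0L ||
         identical(sites[order(sites$utr_start),
                         c("utr_start", "match_len")] |>
                     `rownames<-`(NULL),
                   want[order(want$utr_start), , drop = FALSE] |>
                     `rownames<-`(NULL)))
    if (ok) break
    if (try == config$max_retries) {
      stop("UTR background rejection sampling exhausted ",
           config$max_retries, " retries; use a longer background or ",
           "looser criteria")
    }
  }
  utr <- data.frame(id = config$utr_id, sequence = cand, kind = "UTR",
                    stringsAsFactors = FALSE)
  truth_df <- data.frame(
    utr_id = rep(config$utr_id, length(blocks)),
    utr_start = offsets, utr_end = offsets + nchar(blocks) - 1L,
    core_start = vapply(config$planted_sites, `[`, integer(1L), 1L),
    core_end = vapply(config$planted_sites, `[`, integer(1L), 2L),
    match_len = nchar(blocks), stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(utr, fasta)
  if (!is.null(truth)) {
    write.table(truth_df, truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(utr = utr, truth = truth_df)
}

#' Simulate a complete input set for the pipeline
#'
#' Reads, ncRNA, UTR and the RNP link table tying the ncRNA to the UTR's
#' gene, with all truth tables.  When \code{outdir} is given, writes
#' \code{reads.fastq}, \code{ncrna.fa}, \code{utrs.fa},
#' \code{rnp_links.tsv} and \code{truth/*.tsv}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param outdir optional output directory.
#' @return list with \code{reads}, \code{ncrna}, \code{utr},
#'   \code{rnp_links} and \code{truth} (list of the three truth tables).
#' @export
simulate_dataset <- function(config = simulation_config(), outdir = NULL) {
  rd <- simulate_reads(config)
  nc <- simulate_ncrna(config)
  ut <- simulate_utr(config)
  rnp <- data.frame(ncrna_id = config$ncrna_id,
                    protein_gene_id = config$utr_id,
                    complex_name = config$complex_name,
                    stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    write_fastq(rd$reads, file.path(outdir, "reads.fastq"))
    write_fasta(nc$ncrna, file.path(outdir, "ncrna.fa"))
    write_fasta(ut$utr, file.path(outdir, "utrs.fa"))
    write.table(rnp, file.path(outdir, "rnp_links.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in c("reads", "ncrna", "utr")) {
      tdf <- switch(nm, reads = rd$truth, ncrna = nc$truth, utr = ut$truth)
      write.table(tdf, file.path(outdir, "truth", paste0(nm, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(reads = rd$reads, ncrna = nc$ncrna, utr = ut$utr, rnp_links = rnp,
       truth = list(reads = rd$truth, ncrna = nc$truth, utr = ut$truth))
}
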