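# Triple colligation: join cores, hairpins and target sites through an RNP
# (ribonucleoprotein) complex table.  A record is emitted when one core
# (i) lies within a stable hairpin of an ncRNA, and (ii) has a
# reverse-complement site in the 3'UTR of a protein complexed with that
# same ncRNA.

#' Read an RNP complex link table
#'
#' @param path TSV with columns \code{ncrna_id}, \code{protein_gene_id},
#'   \code{complex_name}; or a data.frame with those columns.
#' @return validated data.frame; (ncrna_id, protein_gene_id) pairs unique.
#' @export
read_rnp_links <- function(path) {
  df <- if (is.data.frame(path)) path else read.delim(path)
  need <- c("ncrna_id", "protein_gene_id", "complex_name")
  if (!all(need %in% names(df))) {
    stop("RNP link table must have columns ", paste(need, collapse = ", "))
  }
  key <- paste(df$ncrna_id, df$protein_gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (ncrna_id, protein_gene_id) pair: ",
         key[duplicated(key)][1L])
  }
  df[, need]
}

#' Locate a core within a hairpin of its parent sequence
#'
#' Finds the occurrence of the core in the parent that overlaps the hairpin
#' most, and reports the fraction of core bases inside the hairpin span and
#' which structural element (5'-side, loop, 3'-side) holds the majority of
#' the overlapped bases.
#'
#' @param core core sequence string.
#' @param hairpin one-row data.frame in the \code{\link{scan_ncrna}} schema.
#' @param parent_seq the parent (ncRNA) sequence.
#' @return list with \code{fraction} (0 when the core is absent from the
#'   parent or disjoint from the hairpin) and \code{side} (one of
#'   \code{"5'-side"}, \code{"loop"}, \code{"3'-side"}, or NA when the
#'   fraction is 0).  Ties between elements go to the stem side 3' of the
#'   loop, then the loop.
#' @export
locate_core_in_hairpin <- function(core, hairpin, parent_seq) {
  core <- normalize_rna(core)
  parent_seq <- normalize_rna(parent_seq)
  occ <- gregexpr(core, parent_seq, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(list(fraction = 0, side = NA_character_))
  nc <- nchar(core)
  loop_end <- hairpin$loop_start + hairpin$loop_len - 1L
  best <- list(fraction = 0, side = NA_character_)
  for (p in as.integer(occ)) {
    pos <- p:(p + nc - 1L)
    inside <- pos >= hairpin$start & pos <= hairpin$end
    frac <- mean(inside)
    if (frac <= best$fraction) next
    n5 <- sum(pos[inside] < hairpin$loop_start)
    nl <- sum(pos[inside] >= hairpin$loop_start & pos[inside] <= loop_end)
    n3 <- sum(pos[inside] > loop_end)
    counts <- c("3'-side" = n3, "loop" = nl, "5'-side" = n5)
    best <- list(fraction = frac,
                 side = names(counts)[which.max(counts)])
  }
  best
}

#' Join the three evidence streams into colligation records
#'
#' Inner join: for every core that sits (with overlap fraction at least
#' \code{overlap_min}) inside a hairpin of ncRNA X whose stability ratio
#' passes \code{min_ratio}, and every RNP link X -> protein P, and every
#' target site of that core in P's 3'UTR with match length at least
#' \code{min_site_len}, one record is emitted.  All three evidence flags
#' are TRUE by construction; \code{\link{verify_colligation}} rechecks them
#' from the raw inputs.
#'
#' @param cores data.frame from \code{\link{extract_cores}}.
#' @param hairpins data.frame from \code{\link{scan_ncrna}} (possibly
#'   row-bound over several ncRNAs).
#' @param sites data.frame from \code{\link{find_all_target_sites}}; the
#'   \code{utr_id} of a site must equal the \code{protein_gene_id} of the
#'   RNP link for the join.
#' @param rnp_links data.frame from \code{\link{read_rnp_links}}.
#' @param ncrnas data.frame of ncRNA sequences (\code{id},
#'   \code{sequence}), needed to locate cores inside hairpins.
#' @param overlap_min minimum fraction of core bases inside the hairpin
#'   span (default 0.8).
#' @param min_ratio minimum hairpin stability ratio (default 0.30).
#' @param min_site_len minimum target-site length (default 7).
#' @return data.frame, one row per (core, hairpin, site) triple, sorted by
#'   \code{stability_ratio} then \code{match_len} descending.
#' @export
colligate <- function(cores, hairpins, sites, rnp_links, ncrnas,
                      overlap_min = 0.8, min_ratio = 0.30,
                      min_site_len = 7L) {
  empty <- data.frame(
    core_id = character(), ncrna_id = character(),
    hairpin_start = integer(), hairpin_end = integer(),
    stability_ratio = numeric(), mfei = numeric(),
    core_overlap = numeric(), core_side = character(),
    protein_gene_id = character(), complex_name = character(),
    utr_id = character(), utr_start = integer(), utr_end = integer(),
    match_len = integer(),
    core_in_stem = logical(), ratio_pass = logical(),
    site_pass = logical(), stringsAsFactors = FALSE)
  if (nrow(cores) == 0L || nrow(hairpins) == 0L || nrow(sites) == 0L ||
      nrow(rnp_links) == 0L) {
    return(empty)
  }
  recs <- list()
  for (ci in seq_len(nrow(cores))) {
    core <- cores[ci, ]
    for (hi in seq_len(nrow(hairpins))) {
      hp <- hairpins[hi, ]
      parent <- ncrnas$sequence[ncrnas$id == hp$parent_id]
      if (length(parent) != 1L) next
      loc <- locate_core_in_hairpin(core$sequence, hp, parent)
      core_in_stem <- loc$fraction >= overlap_min
      ratio_pass <- hp$stability_ratio >= min_ratio
      if (!core_in_stem || !ratio_pass) next
      links <- rnp_links[rnp_links$ncrna_id == hp$parent_id, , drop = FALSE]
      for (li in seq_len(nrow(links))) {
        ss <- sites[sites$core_id == core$core_id &
                      sites$utr_id == links$protein_gene_id[li] &
                      sites$match_len >= min_site_len, , drop = FALSE]
        for (si in seq_len(nrow(ss))) {
          recs[[length(recs) + 1L]] <- data.frame(
            core_id = core$core_id, ncrna_id = hp$parent_id,
            hairpin_start = hp$start, hairpin_end = hp$end,
            stability_ratio = hp$stability_ratio, mfei = hp$mfei,
            core_overlap = loc$fraction, core_side = loc$side,
            protein_gene_id = links$protein_gene_id[li],
            complex_name = links$complex_name[li],
            utr_id = ss$utr_id[si], utr_start = ss$utr_start[si],
            utr_end = ss$utr_end[si], match_len = ss$match_len[si],
            core_in_stem = TRUE, ratio_pass = TRUE, site_pass = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  out <- out[order(-out$stability_ratio, -out$match_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-verify colligation records against the raw inputs
#'
#' Defensive recheck: for every record, confirms from the sequences alone
#' that (i) the core overlaps the hairpin span by at least
#' \code{overlap_min}, (ii) the hairpin's stability ratio passes, and
#' (iii) the reverse complement of the matched core segment equals the UTR
#' segment of the reported length.
#'
#' @param records data.frame from \code{\link{colligate}}.
#' @param cores,hairpins,rnp_links,ncrnas,utrs the raw inputs.
#' @inheritParams colligate
#' @return logical vector, one per record; all TRUE for a sound join.
#' @export
verify_colligation <- function(records, cores, hairpins, rnp_links,
                               ncrnas, utrs, overlap_min = 0.8,
                               min_ratio = 0.30, min_site_len = 7L) {
  vapply(seq_len(nrow(records)), function(r) {
    rec <- records[r, ]
    core <- cores[cores$core_id == rec$core_id, ]
    hp <- hairpins[hairpins$parent_id == rec$ncrna_id &
                     hairpins$start == rec$hairpin_start &
                     hairpins$end == rec$hairpin_end, ][1L, ]
    parent <- ncrnas$sequence[ncrnas$id == rec$ncrna_id]
    utr <- utrs$sequence[utrs$id == rec$utr_id]
    if (nrow(core) != 1L || length(parent) != 1L || length(utr) != 1L) {
      return(FALSE)
    }
    loc <- locate_core_in_hairpin(core$sequence, hp, parent)
    link_ok <- any(rnp_links$ncrna_id == rec$ncrna_id &
                     rnp_links$protein_gene_id == rec$protein_gene_id)
    block <- substring(normalize_rna(utr), rec$utr_start, rec$utr_end)
    site_ok <- rec$match_len >= min_site_len &&
      grepl(reverse_complement(block), core$sequence, fixed = TRUE)
    loc$fraction >= overlap_min && hp$stability_ratio >= min_ratio &&
      link_ok && site_ok
  }, logical(1L))
}
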