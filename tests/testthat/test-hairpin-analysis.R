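S <- "UUCGCGCUUUCCCCUG"

test_that("enumeration finds constructed stems and rejects unstructured RNA", {
  h <- enumerate_hairpins("GGGAAAACCC", min_stem_pairs = 3)
  expect_identical(nrow(h), 1L)
  expect_identical(h$n_stem_pairs, 3L)
  expect_identical(h$loop_len, 4L)
  expect_identical(h$gc_pair_count, 3L)
  expect_identical(h$structure, "(((....)))")
  expect_identical(nrow(enumerate_hairpins(strrep("A", 10))), 0L)
  expect_error(enumerate_hairpins("GGGAAAACCC", min_loop = 2), "min_loop")
})

test_that("enumeration matches the exhaustive triple oracle", {
  set.seed(71)
  for (i in 1:60) {
    seq <- random_rna_str(sample(10:20, 1))
    msp <- sample(1:3, 1)
    got <- enumerate_hairpins(seq, min_stem_pairs = msp)
    want <- oracle_hairpins(seq, min_stem_pairs = msp)
    expect_identical(got[, c("start", "end", "n_stem_pairs", "loop_len")],
                     want, info = seq)
  }
})

test_that("energies are the hand-summed stack and loop terms", {
  params <- energy_parameters()
  stack_tab <- read.delim(system.file("extdata",
                                      "nn_stack_turner2004.tsv",
                                      package = "colligator"))
  loop_tab <- read.delim(system.file("extdata",
                                     "nn_hairpin_loop_turner2004.tsv",
                                     package = "colligator"))
  gval <- function(o, i) stack_tab$dG[stack_tab$outer_pair == o &
                                        stack_tab$inner_pair == i]
  h <- enumerate_hairpins("GGGAAAACCC", min_stem_pairs = 3)
  dg <- hairpin_energy(h, "GGGAAAACCC", params)
  expect_equal(dg, 2 * gval("GC", "GC") +
                 loop_tab$dG[loop_tab$loop_len == 4])

  # single stem pair: loop initiation only
  h1 <- enumerate_hairpins("GAAAC", min_stem_pairs = 1)
  expect_equal(hairpin_energy(h1, "GAAAC", params),
               loop_tab$dG[loop_tab$loop_len == 3])

  # tabulated tetraloop context replaces the generic size-4 term
  seqt <- "GCUUCGGC"  # closing C-G pair around UUCG
  ht <- enumerate_hairpins(seqt, min_stem_pairs = 2)
  expect_equal(hairpin_energy(ht, seqt, params),
               gval("GC", "CG") + params$tetraloop[["CUUCGG"]])

  # deterministic
  expect_identical(hairpin_energy(h, "GGGAAAACCC", params),
                   hairpin_energy(h, "GGGAAAACCC", params))
})

test_that("extending a perfect GC stem never raises the free energy", {
  params <- energy_parameters()
  dgs <- vapply(2:8, function(k) {
    seq <- paste0(strrep("G", k), "AAAA", strrep("C", k))
    h <- enumerate_hairpins(seq, min_stem_pairs = k)
    hairpin_energy(h, seq, params)
  }, numeric(1))
  expect_true(all(diff(dgs) <= 0))
  # stability ratio non-decreasing in stem length beyond 2 pairs
  ratios <- -dgs / (2 * (2:8) + 4)
  expect_true(all(diff(ratios) >= -1e-9))
})

test_that("scores implement -dG/L and MFEI with their algebraic identity", {
  h <- data.frame(sequence = "GGCCGGAAUUAACCGGCCAAUUGGCCAA",
                  L = 28L, dG = -8.4)
  sc <- score_hairpin(h)
  expect_equal(sc$stability_ratio, 0.30)
  h2 <- data.frame(sequence = paste0(strrep("GC", 9), "AAAA"),
                   L = 22L, dG = -9)
  expect_equal(score_hairpin(h2)$mfei, 0.5)
  # no G/C: MFEI undefined, ratio still present
  h3 <- data.frame(sequence = "AAAAUUUU", L = 8L, dG = -1)
  expect_true(is.na(score_hairpin(h3)$mfei))
  expect_equal(score_hairpin(h3)$stability_ratio, 0.125)
})

test_that("hairpin reconstruction rebuilds the expected geometry", {
  h <- reconstruct_hairpin(S, 4)
  expect_identical(h$L, 28L)
  expect_identical(h$n_stem_pairs, 12L)
  expect_identical(h$gc_pair_count, 8L)
  expect_identical(substring(h$sequence, 13, 28), S)  # loop + 3' side

  au <- reconstruct_hairpin("AAAAUUUU", 4)
  expect_identical(au$L, 12L)
  expect_identical(au$n_stem_pairs, 4L)
  expect_identical(au$gc_pair_count, 0L)

  # round-trip: the enumerator recovers the same stem from the built RNA
  e <- enumerate_hairpins(h$sequence, min_stem_pairs = 12)
  expect_identical(nrow(e), 1L)
  expect_identical(e$start, 1L)
  expect_identical(e$end, 28L)
  expect_identical(e$n_stem_pairs, 12L)
  expect_identical(e$loop_len, 4L)
})

test_that("windowed scan recovers a planted hairpin and ranks it first", {
  sim <- simulate_ncrna(simulation_config(rng_seed = 12L))
  found <- scan_ncrna(sim$ncrna)
  expect_gte(nrow(found), 1L)
  expect_identical(found$start[1], sim$truth$hairpin_start)
  expect_identical(found$end[1], sim$truth$hairpin_end)
  # identity holds for every scored hairpin
  expect_equal(found$stability_ratio * found$L,
               found$mfei * found$gc_nt_count)
  expect_identical(nrow(scan_ncrna(strrep("A", 164))), 0L)
})

test_that("a window larger than the sequence degenerates gracefully", {
  seq <- paste0(random_rna_str(5), "GGGGGGAAAACCCCCC",
                random_rna_str(5))
  set.seed(3)
  wide <- scan_ncrna(seq, window = 500, min_span = 10, min_ratio = 0)
  narrow <- scan_ncrna(seq, window = nchar(seq), min_span = 10,
                       min_ratio = 0)
  expect_identical(wide, narrow)
})

test_that("external energies override matching spans", {
  sim <- simulate_ncrna(simulation_config(rng_seed = 12L))
  base <- scan_ncrna(sim$ncrna)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("parent_id\tstart\tend\tdG",
               paste("RNU1L1", base$start[1], base$end[1], "-16.5",
                     sep = "\t")), f)
  ext <- load_external_energies(f)
  found <- scan_ncrna(sim$ncrna, external_energies = ext)
  row <- found[found$start == base$start[1], ]
  expect_equal(row$dG, -16.5)
  expect_identical(row$energy_source, "external-table")
  expect_equal(row$stability_ratio, 16.5 / row$L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("parent_id\tstart\tend\tdG", "x\t10\t5\t-1"), bad)
  expect_error(load_external_energies(bad), "row 1")
})
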