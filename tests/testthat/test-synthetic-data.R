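S <- "UUCGCGCUUUCCCCUG"

test_that("generators are pure functions of the seed", {
  cfg <- simulation_config(rng_seed = 99L, n_reads = 200L,
                           planted_cores = list(list(sequence = S,
                                                     abundance = 20L)))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$ncrna, b$ncrna)
  expect_identical(a$utr, b$utr)
  c2 <- simulate_dataset(simulation_config(rng_seed = 100L, n_reads = 200L,
                                           planted_cores = list(
                                             list(sequence = S,
                                                  abundance = 20L))))
  expect_false(identical(a$reads$sequence, c2$reads$sequence))
})

test_that("planted reads are core + adapter when flanks and poly-A are off", {
  cfg <- simulation_config(rng_seed = 1L, n_reads = 5L,
                           planted_cores = list(list(sequence = S,
                                                     abundance = 5L)),
                           polyA_distribution = c(1, 0, 0, 0, 0))
  sim <- simulate_reads(cfg)
  expected <- substr(paste0(S, cfg$adapter), 1, 35)
  expect_identical(unique(sim$reads$sequence), expected)
  expect_identical(nchar(expected), 35L)  # 16-nt insert + 19 adapter bases
  expect_identical(sim$truth$polyA, rep(0L, 5))
})

test_that("an empty library yields empty outputs", {
  cfg <- simulation_config(rng_seed = 1L, n_reads = 0L,
                           planted_cores = list())
  sim <- simulate_reads(cfg)
  expect_identical(nrow(sim$reads), 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("the planted hairpin is embedded at the recorded offset", {
  sim <- simulate_ncrna(simulation_config(rng_seed = 21L))
  hp <- reconstruct_hairpin(S, 4)
  expect_identical(nchar(sim$ncrna$sequence), 164L)
  expect_identical(substring(sim$ncrna$sequence, sim$truth$hairpin_start,
                             sim$truth$hairpin_end), hp$sequence)
  # background-only ncRNA carries no qualifying hairpin
  bg <- simulate_ncrna(simulation_config(rng_seed = 21L,
                                         planted_hairpin_core = NULL))
  expect_identical(nrow(scan_ncrna(bg$ncrna)), 0L)
})

test_that("written files round-trip through the package readers", {
  outdir <- withr::local_tempdir()
  cfg <- simulation_config(rng_seed = 5L, n_reads = 100L,
                           planted_cores = list(list(sequence = S,
                                                     abundance = 10L)))
  sim <- simulate_dataset(cfg, outdir = outdir)
  expect_equal(read_fastq(file.path(outdir, "reads.fastq")),
               sim$reads, ignore_attr = TRUE)
  expect_identical(read_fasta(file.path(outdir, "ncrna.fa"),
                              "ncRNA")$sequence,
                   sim$ncrna$sequence)
  expect_identical(read_rnp_links(file.path(outdir, "rnp_links.tsv")),
                   sim$rnp_links)
  expect_true(file.exists(file.path(outdir, "truth", "utr_truth.tsv")))
})

test_that("infeasible configurations fail loudly", {
  expect_error(simulate_reads(simulation_config(
    n_reads = 5L,
    planted_cores = list(list(sequence = strrep("ACGU", 9),
                              abundance = 2L)))),
    "read_len")
  expect_error(simulate_reads(simulation_config(
    n_reads = 3L,
    planted_cores = list(list(sequence = S, abundance = 10L)))),
    "n_reads")
  expect_error(simulate_ncrna(simulation_config(ncrna_len = 20L)),
               "too short")
})
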