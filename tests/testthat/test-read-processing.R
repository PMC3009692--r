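# brute-force adapter locator: try every (position, prefix length) pair
brute_adapter_pos <- function(read, adapter, min_prefix) {
  n <- nchar(read)
  for (p in seq_len(n)) {
    m <- min(n - p + 1L, nchar(adapter))
    if (m < min_prefix) next
    if (substr(read, p, p + m - 1L) == substr(adapter, 1L, m)) return(p)
  }
  NA_integer_
}

test_that("adapter removal recovers the insert from a composed read", {
  read <- "TTCGCGCTTTCCCCTGTCTCGTATGCCGTCTTCTG"  # 16-nt core + 19-nt adapter
  expect_identical(nchar(read), 35L)
  tr <- trim_adapter(read)
  expect_true(tr$adapter_found)
  expect_identical(tr$insert, "UUCGCGCUUUCCCCUG")
  expect_identical(tr$adapter_start, 17L)  # 1-based
})

test_that("reads without a 6-base adapter prefix are flagged for discard", {
  tr <- trim_adapter("ACGUACGUACGUACGUACGUACGUACGUACGUACG")
  expect_false(tr$adapter_found)
  expect_true(is.na(tr$adapter_start))
})

test_that("adapter matching agrees with a brute-force scan", {
  cfg <- trim_config()
  # exactly six adapter bases ending the read
  read <- "ACGTACGTACGTACGTTCTCGT"
  tr <- trim_adapter(read, cfg)
  expect_identical(tr$adapter_start,
                   brute_adapter_pos(normalize_rna(read), cfg$adapter, 6L))
  expect_identical(tr$insert, "ACGUACGUACGUACGU")
  # randomized reads with adapter prefixes planted at varying depths
  set.seed(31)
  for (i in 1:50) {
    ins <- random_rna_str(sample(10:25, 1))
    alen <- sample(0:26, 1)
    read <- substr(paste0(ins, substr(cfg$adapter, 1, alen),
                          random_rna_str(3)), 1, 35)
    got <- trim_adapter(read, cfg)$adapter_start
    want <- brute_adapter_pos(normalize_rna(read), cfg$adapter, 6L)
    expect_identical(got, want)
  }
})

test_that("a full adapter occurrence mid-read beats a later suffix hit", {
  cfg <- trim_config(adapter = "UCUCGU", min_adapter_prefix = 3L)
  # full 6-mer adapter at position 3, then junk, then a 3-base suffix hit
  read <- paste0("AA", "UCUCGU", "GGGGGGGG", "UCU")
  tr <- trim_adapter(read, cfg)
  expect_identical(tr$adapter_start, 3L)
  expect_identical(tr$insert, "AA")
})

test_that("poly-A trimming removes at most the configured cap", {
  expect_identical(trim_polyA("ACGUAA", 4)$insert, "ACGU")
  expect_identical(trim_polyA("ACGUAA", 4)$polyA_removed, 2L)
  capped <- trim_polyA("ACGUAAAAA", 4)
  expect_identical(capped$insert, "ACGUA")
  expect_identical(capped$polyA_removed, 4L)
  expect_identical(trim_polyA("ACGU", 4)$polyA_removed, 0L)
  # U-side untouched
  expect_identical(trim_polyA("UUUU", 4)$insert, "UUUU")
})

test_that("length filter keeps 16-29 nt inserts inclusively", {
  cfg <- trim_config()
  expect_true(length_filter(strrep("A", 16), cfg))
  expect_true(length_filter(strrep("A", 29), cfg))
  expect_false(length_filter(strrep("A", 15), cfg))
  expect_false(length_filter(strrep("A", 30), cfg))
})

test_that("trim configuration is validated", {
  expect_error(trim_config(adapter = "ACG", min_adapter_prefix = 6),
               "min_adapter_prefix")
  expect_error(trim_config(min_len = 20, max_len = 10), "min_len")
})

test_that("trimming conserves read counts and is idempotent on output", {
  sim <- simulate_reads(simulation_config(rng_seed = 7L, n_reads = 500L,
                                          planted_cores = list(
                                            list(sequence = "UUCGCGCUUUCCCCUG",
                                                 abundance = 60L))))
  tr <- trim_reads(sim$reads)
  s <- attr(tr, "summary")
  expect_identical(s[["reads_in"]],
                   s[["retained"]] + s[["discarded_no_adapter"]] +
                     s[["discarded_length"]])
  # retained inserts contain no adapter hit and no further trimmable A's
  kept <- tr$insert[tr$retained]
  again <- trim_adapter(kept)
  expect_false(any(again$adapter_found))
  # the planted core ends in G, so a second poly-A pass changes nothing
  expect_identical(trim_polyA(kept, 4L)$insert, kept)
  expect_true(all(nchar(kept) >= 16 & nchar(kept) <= 29))
})
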