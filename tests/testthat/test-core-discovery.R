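S <- "UUCGCGCUUUCCCCUG"

test_that("collapse_exact counts distinct strings and conserves totals", {
  ins <- c(rep(strrep("ACGU", 4), 3), strrep("GGCC", 4))
  cc <- collapse_exact(ins)
  expect_identical(nrow(cc), 2L)
  expect_identical(cc$count[cc$sequence == strrep("ACGU", 4)], 3L)
  expect_identical(sum(cc$count), length(ins))
  expect_identical(nrow(collapse_exact(character())), 0L)
  one <- collapse_exact(rep(S, 1000))
  expect_identical(one$count, 1000L)
})

test_that("abundance_filter applies the minimum-copies threshold", {
  cc <- data.frame(sequence = c("A", "B"), count = c(3L, 2L))
  expect_identical(abundance_filter(cc, 3)$sequence, "A")
  expect_identical(nrow(abundance_filter(data.frame(sequence = "A",
                                                    count = 2L), 3)), 0L)
  expect_identical(abundance_filter(cc, 1), cc)
})

test_that("extract_cores merges flanked variants onto the shared core", {
  single <- extract_cores(data.frame(sequence = S, count = 3L))
  expect_identical(single$sequence, S)
  expect_identical(single$instance_count, 3L)

  two <- extract_cores(data.frame(sequence = c(paste0("A", S),
                                               paste0(S, "C")),
                                  count = c(3L, 4L)))
  expect_identical(nrow(two), 1L)
  expect_identical(two$sequence, S)
  expect_identical(two$instance_count, 7L)
  expect_identical(two$n_members, 2L)

  disjoint <- extract_cores(data.frame(
    sequence = c(S, "AGAGAGAGAGAGAGAGAG"), count = c(3L, 5L)))
  expect_identical(nrow(disjoint), 2L)
  expect_identical(disjoint$n_members, c(1L, 1L))
})

test_that("every core is a substring of each member and counts partition", {
  set.seed(5)
  for (rep in 1:10) {
    base <- random_rna_str(20)
    seqs <- unique(c(
      vapply(1:4, function(i)
        paste0(random_rna_str(sample(0:3, 1)), base,
               random_rna_str(sample(0:3, 1))), character(1)),
      vapply(1:3, function(i) random_rna_str(sample(16:24, 1)),
             character(1))))
    counted <- data.frame(sequence = seqs,
                          count = sample(3:20, length(seqs), replace = TRUE))
    cores <- extract_cores(counted, 16)
    expect_identical(sum(cores$instance_count), sum(counted$count))
    expect_identical(sum(cores$n_members), nrow(counted))
    for (i in seq_len(nrow(cores))) {
      members <- strsplit(cores$members[i], ";", fixed = TRUE)[[1]]
      expect_true(all(vapply(members, grepl, logical(1),
                             pattern = cores$sequence[i], fixed = TRUE)))
    }
  }
})

test_that("greedy clustering matches the exhaustive-substring oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    planted <- random_rna_str(17)
    seqs <- unique(vapply(seq_len(n), function(i) {
      if (i <= 2) {
        paste0(random_rna_str(sample(0:4, 1)), planted,
               random_rna_str(sample(0:4, 1)))
      } else {
        random_rna_str(sample(16:26, 1))
      }
    }, character(1)))
    counted <- data.frame(sequence = seqs,
                          count = sample(3:50, length(seqs),
                                         replace = TRUE))
    got <- extract_cores(counted, 16)
    want <- oracle_extract_cores(counted, 16)
    expect_identical(got$sequence, want$sequence)
    expect_identical(got$instance_count, want$instance_count)
    expect_identical(got$n_members, want$n_members)
  }
})

test_that("clustering is insensitive to input order", {
  set.seed(9)
  seqs <- c(paste0("AA", S), paste0(S, "GG"), paste0("C", S, "A"),
            random_rna_str(20), random_rna_str(18))
  counted <- data.frame(sequence = seqs, count = c(5L, 3L, 4L, 3L, 7L))
  ref <- extract_cores(counted, 16)
  for (i in 1:5) {
    perm <- counted[sample(nrow(counted)), , drop = FALSE]
    got <- extract_cores(perm, 16)
    expect_identical(got, ref)
  }
})

test_that("min_core_len is validated", {
  expect_error(extract_cores(data.frame(sequence = S, count = 3L), 0),
               "min_core_len")
})
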