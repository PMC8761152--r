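lib <- synthetic_reference_library(100)

test_that("every library member classifies to itself with score 1", {
  for (ref in lib) {
    fa <- classify_fold(ref$structure, lib)
    expect_equal(fa$best_fold, ref$fold_name)
    expect_equal(fa$best_score, 1.0, tolerance = 1e-9)
    expect_equal(fa$verdict, "same_fold")
    expect_true(all(fa$scores > 0 & fa$scores <= 1 + 1e-12))
  }
})

test_that("noisy rigid copies classify to their source fold above 0.5", {
  picks <- c("Pgp", "BtuC", "MacB")
  for (i in seq_along(picks)) {
    src <- lib[[picks[i]]]
    q <- perturb_structure(src$structure, 40 + i, noise_sigma = 0.5)
    fa <- classify_fold(q, lib)
    expect_equal(fa$best_fold, picks[i])
    expect_gt(fa$best_score, 0.5)
    expect_equal(fa$verdict, "same_fold")
  }
})

test_that("random coils come out unrelated", {
  fa <- classify_fold(generate_coil(60, 77), lib)
  expect_equal(fa$verdict, "unrelated")
  expect_lte(fa$best_score, 0.3)
})

test_that("verdicts are monotone in the best score with pinned boundaries", {
  mk <- function(score) {
    if (score >= 0.5) "same_fold" else if (score <= 0.3) "unrelated" else "twilight"
  }
  for (s in c(0.1, 0.3, 0.31, 0.49, 0.5, 0.9)) {
    v <- mk(s)
    expect_equal(v, c("unrelated", "twilight", "same_fold")[
      1 + (s > 0.3) + (s >= 0.5)])
  }
  expect_error(classify_fold(lib$Pgp$structure, list()), "empty")
})

test_that("hmmsearch domain tables round-trip and parse by position", {
  hits <- data.frame(
    target_id = c("Q00001", "Q00002", "Q00003"),
    hmm_name = c("ABC_membrane", "ABC_membrane_2", "ABC2_membrane"),
    hmm_length = c(100L, 200L, 150L),
    e_value = c(1e-5, 2e-4, 0.05),
    hmm_from = c(1L, 21L, 10L),
    hmm_to = c(100L, 200L, 100L),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".domtbl")
  write_fixture_domtbl(hits, f)
  back <- parse_domtbl(f)
  expect_equal(back[names(hits)], hits)

  ## comment-only file parses to an empty collection
  empty <- tempfile()
  write_fixture_domtbl(hits[0, ], empty)
  expect_equal(nrow(parse_domtbl(empty)), 0)

  ## truncated line names its line number
  bad <- tempfile()
  writeLines(c(readLines(f)[1:3], "Q1 - 400 name"), bad)
  expect_error(parse_domtbl(bad), "line 4")
})

test_that("the PFAM filter keeps E <= 0.001 and coverage >= 90% inclusively", {
  hits <- data.frame(
    target_id = paste0("T", 1:4),
    hmm_name = "ABC_membrane",
    hmm_length = 100L,
    e_value = c(0.01, 1e-4, 1e-4, 1e-3),
    hmm_from = c(1L, 1L, 1L, 11L),
    hmm_to = c(100L, 100L, 89L, 100L),   # coverage 1.0, 1.0, 0.89, 0.90
    stringsAsFactors = FALSE)
  kept <- pfam_filter(hits)
  expect_equal(kept$target_id, c("T2", "T4"))  # T1 fails E, T3 fails coverage
  expect_equal(nrow(pfam_filter(hits, max_e = 0.1)), 3)
})

test_that("the PFAM filter is idempotent, order-independent, and deduplicates by best E", {
  hits <- data.frame(
    target_id = c("A", "A", "B"),
    hmm_name = c("ABC_membrane", "ABC_tran", "ABC_tran"),
    hmm_length = 100L,
    e_value = c(1e-4, 1e-6, 1e-5),
    hmm_from = 1L, hmm_to = 95L,
    stringsAsFactors = FALSE)
  once <- pfam_filter(hits)
  expect_equal(once$hmm_name[once$target_id == "A"], "ABC_tran")
  expect_equal(pfam_filter(once), once)
  shuffled <- hits[c(3, 1, 2), ]
  expect_equal(pfam_filter(shuffled), once)
})

test_that("dimer constructs concatenate with recorded segment ranges", {
  d <- prepare_dimer_sequence("AAA", "CCC", "GG")
  expect_equal(d$sequence, "AAAGGCCC")
  expect_equal(d$ranges$start, c(1L, 4L, 6L))
  expect_equal(d$ranges$end, c(3L, 5L, 8L))

  plain <- prepare_dimer_sequence("AAA", "CCC")
  expect_equal(plain$sequence, "AAACCC")
  expect_equal(nrow(plain$ranges), 2)

  linker <- readLines(extdata("synthetic_disordered_linker_126aa.txt"))[1]
  expect_equal(nchar(linker), 126)
  full <- prepare_dimer_sequence("MKT", "WLV", linker)
  expect_equal(nchar(full$sequence), 3 + 126 + 3)

  expect_error(prepare_dimer_sequence("AAB1", "CCC"), "invalid amino-acid")
})
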