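test_that("site classification matches hand counts on toy columns", {
  # columns: AAAA (constant), ACAA (singleton), AACC (informative)
  mat <- cbind(c("A", "A", "A", "A"), c("A", "C", "A", "A"),
               c("A", "A", "C", "C"))
  rownames(mat) <- paste0("s", 1:4)
  sc <- classify_sites(as_alignment(mat))
  expect_equal(sc$n_total, 3L)
  expect_equal(sc$n_constant, 1L)
  expect_equal(sc$n_variable, 2L)
  expect_equal(sc$n_singleton, 1L)
  expect_equal(sc$n_parsimony_informative, 1L)
})

test_that("an invariant alignment has no variable or informative sites", {
  sc <- classify_sites(make_aln(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(sc$n_variable, 0L)
  expect_equal(sc$n_parsimony_informative, 0L)
  expect_equal(sc$n_constant, 4L)
})

test_that("site classification refuses unfiltered alignments", {
  expect_error(classify_sites(make_aln(a = "AC-T", b = "ACGT")),
               "filter_columns")
})

test_that("site classification equals a brute-force tally on random data", {
  for (seed in 1:100) {
    aln <- random_aln(6, 50, seed = seed)
    sc <- classify_sites(aln)
    or <- oracle_classify(aln)
    expect_equal(unclass(sc)[names(or)], or)
    # internal consistency
    expect_equal(sc$n_constant + sc$n_variable, sc$n_total)
    expect_equal(sc$n_singleton + sc$n_parsimony_informative, sc$n_variable)
  }
})

test_that("p-distance matches hand counts and the brute-force oracle", {
  d <- p_distance(make_aln(a = "ACGTACGT", b = "ACGTACGA"))
  expect_equal(d["a", "b"], 1 / 8)
  expect_equal(diag(d), c(a = 0, b = 0))

  expect_equal(p_distance(make_aln(a = "ACGT", b = "ACGT"))["a", "b"], 0)

  aln <- random_aln(5, 100, seed = 3)
  expect_equal(p_distance(aln), oracle_pdist(aln))
  expect_equal(p_distance(aln, "pairwise"), oracle_pdist(aln, "pairwise"))
})

test_that("pairwise deletion skips unusable columns per pair", {
  aln <- make_aln(a = "AC-TA", b = "ACGTA", c = "TCGT?")
  d <- p_distance(aln, deletion = "pairwise")
  expect_equal(d["a", "b"], 0)        # 4 comparable, 0 mismatches
  expect_equal(d["a", "c"], 1 / 3)    # cols 1,2,4 comparable; col1 differs
  expect_equal(d["b", "c"], 1 / 4)
  # complete deletion drops columns 3 and 5 for everyone
  expect_equal(p_distance(aln, "complete")["a", "b"], 0)
  expect_equal(p_distance(aln, "complete")["a", "c"], 1 / 3)
})

test_that("zero comparable columns is an error naming the pair", {
  aln <- make_aln(a = "A???", b = "?CGT")
  expect_error(p_distance(aln, deletion = "pairwise"), "a / b")
  expect_error(p_distance(make_aln(a = "-?", b = "AC")), "complete deletion")
})

test_that("complete and pairwise deletion agree on a filtered alignment", {
  aln <- filter_columns(make_aln(a = "AC-T?NGGAC", b = "ACGTTAGGAC",
                                 c = "ACGTTAGGTC"))$aln
  expect_equal(p_distance(aln, "complete"), p_distance(aln, "pairwise"))
})

test_that("p-distance agrees with ape's raw distance", {
  aln <- random_aln(6, 200, seed = 11)
  bin <- ape::as.DNAbin(tolower(aln$mat))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(p_distance(aln)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-12)
})

test_that("JC and K2P corrections evaluate their closed forms", {
  expect_equal(correct_distance(0, "JC"), 0)
  expect_equal(correct_distance(0, "K2P", P = 0, Q = 0), 0)
  expect_equal(correct_distance(0.05, "JC"), 0.0517447, tolerance = 1e-6)
  # K2P with an even transition/transversion split approaches JC
  d_jc <- correct_distance(0.05, "JC")
  d_k2p <- correct_distance(0.05, "K2P", P = 0.025, Q = 0.025)
  expect_lt(abs(d_k2p - d_jc), 1e-3)
})

test_that("corrections are monotone, never below p, and error at saturation", {
  p <- seq(0, 0.7, by = 0.01)
  d <- correct_distance(p, "JC")
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  pk <- seq(0, 0.6, by = 0.01)     # K2P saturates at 2P + Q = 1
  dk <- correct_distance(pk, "K2P", P = pk / 2, Q = pk / 2)
  expect_true(all(dk >= pk))
  expect_error(correct_distance(0.75, "JC"), "undefined under model")
  expect_error(correct_distance(0.8, "K2P", P = 0.3, Q = 0.5),
               "undefined under model")
  expect_error(correct_distance(0.1, "K2P", P = 0.02, Q = 0.02), "P \\+ Q")
})

test_that("JC correction inverts the expected-p map to 1e-12", {
  d <- seq(0.001, 2, length.out = 200)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  expect_equal(correct_distance(p, "JC"), d, tolerance = 1e-12)
})

test_that("corrected matrices dominate the uncorrected matrix", {
  sim <- simulate_alignment(scenario_config(seed = 21))
  aln <- sim$aln
  p <- p_distance(aln)
  for (model in c("JC", "K2P")) {
    d <- corrected_distance(aln, model)
    expect_true(all(d >= p - 1e-12))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, nrow(d)))
  }
})

test_that("distance matrices write as TSV and PHYLIP square format", {
  aln <- random_aln(4, 50, seed = 2)
  d <- p_distance(aln)
  tsv <- withr::local_tempfile()
  write_distance_matrix(d, tsv, "tsv")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t", row.names = 1)
  expect_equal(as.matrix(back), d, tolerance = 1e-12,
               ignore_attr = TRUE)
  phy <- withr::local_tempfile()
  write_distance_matrix(d, phy, "phylip")
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 4L)
  expect_length(lines, 5L)
})
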