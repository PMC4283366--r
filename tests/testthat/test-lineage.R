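toy3 <- function() {
  d <- matrix(c(0, 0.02, 0.10,
                0.02, 0, 0.10,
                0.10, 0.10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d
}

test_that("UPGMA agglomerates a three-taxon matrix by hand", {
  tr <- upgma(toy3())
  expect_equal(tr$height, c(0.01, 0.05))
  expect_equal(tr$members[[1]], c(1L, 2L))         # a+b join first
  expect_equal(tr$members[[2]], 1:3)
  nwk <- ape::write.tree(ape::as.phylo(tr))
  expect_match(nwk, "\\(b:0.01,a:0.01\\)|\\(a:0.01,b:0.01\\)")
})

test_that("identical rows join first at height zero", {
  d <- toy3()
  d["a", "b"] <- d["b", "a"] <- 0
  tr <- upgma(d)
  expect_equal(tr$height[1], 0)
  expect_equal(tr$members[[1]], c(1L, 2L))
})

test_that("UPGMA rejects invalid matrices", {
  d <- toy3(); d[1, 2] <- NA; d[2, 1] <- NA
  expect_error(upgma(d), "NA")
  d2 <- toy3(); d2[1, 2] <- d2[2, 1] <- -0.1
  expect_error(upgma(d2), "negative")
  expect_error(upgma(matrix(0, 1, 1)), "two labels")
})

test_that("UPGMA agrees with phangorn's reference agglomeration", {
  skip_if_not_installed("phangorn")
  for (seed in 1:25) {
    set.seed(seed)
    n <- 8
    h <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(h))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- ape::as.phylo(upgma(d))
    ref <- phangorn::upgma(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    # same ultrametric root height
    mine_depth <- max(ape::node.depth.edgelength(mine))
    ref_depth <- max(ape::node.depth.edgelength(ref))
    expect_equal(mine_depth, ref_depth, tolerance = 1e-9)
  }
})

test_that("UPGMA exactly recovers a noise-free ultrametric tree", {
  skip_if_not_installed("phangorn")
  sim <- simulate_alignment(scenario_config(seed = 5))
  d <- sim$truth$expected_d        # exactly ultrametric by construction
  # the within-lineage stars are tied joins; collapse the arbitrary
  # zero-length resolutions before comparing topologies
  tr <- ape::di2multi(ape::as.phylo(upgma(d)), tol = 1e-10)
  gen <- ape::read.tree(text = sim$truth$newick)
  expect_equal(
    phangorn::RF.dist(ape::unroot(tr), ape::unroot(gen)), 0,
    ignore_attr = TRUE)
  # and the recovered node heights equal the generating divergences
  expect_equal(max(ape::node.depth.edgelength(tr)),
               max(d) / 2, tolerance = 1e-9)
})

test_that("cutting the tree yields threshold-consistent groups", {
  tr <- upgma(toy3())
  part <- cut_tree(tr, 0.03)
  expect_equal(unname(part[c("a", "b", "c")]),
               c("group1", "group1", "group2"))
  expect_equal(length(unique(cut_tree(tr, 0))), 3L)      # singletons
  expect_equal(length(unique(cut_tree(tr, 1))), 1L)      # above root
  expect_equal(attr(part, "source"), "tree-cut")
})

test_that("group labels are ordered by smallest member id", {
  d <- toy3()
  rownames(d) <- colnames(d) <- c("z", "y", "a")   # pair (z,y), singleton a
  part <- cut_tree(upgma(d), 0.03)
  expect_equal(unname(part["a"]), "group1")
  expect_equal(unname(part["z"]), "group2")
})

test_that("distance summaries match brute-force pair enumeration", {
  set.seed(42)
  n <- 9
  d <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  part <- setNames(rep(c("g1", "g2", "g3"), each = 3), rownames(d))
  s <- summarize_distances(d, part)
  for (k in seq_len(nrow(s))) {
    vals <- oracle_summary_cell(d, as.list(part), s$group1[k], s$group2[k])
    expect_equal(s$n_pairs[k], length(vals))
    expect_equal(s$min[k], min(vals))
    expect_equal(s$mean[k], mean(vals))
    expect_equal(s$max[k], max(vals))
  }
})

test_that("all pairwise distances are conserved across summary cells", {
  set.seed(1)
  n <- 10
  d <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  part <- setNames(sample(c("x", "y", "z"), n, replace = TRUE,
                          prob = c(.5, .3, .2)), rownames(d))
  part[1:3] <- c("x", "y", "z")   # ensure non-empty groups
  s <- summarize_distances(d, part)
  expect_equal(sum(s$n_pairs), choose(n, 2))
  expect_equal(sum(s$n_pairs * s$mean, na.rm = TRUE), sum(d[upper.tri(d)]))
})

test_that("two tight pairs summarize to zero intra cells", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- d["a", "d"] <- d["d", "a"] <- 0.1
  d["b", "c"] <- d["c", "b"] <- d["b", "d"] <- d["d", "b"] <- 0.1
  part <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  s <- summarize_distances(d, part)
  intra <- s[s$kind == "intra", ]
  expect_equal(intra$min, c(0, 0))
  expect_equal(intra$max, c(0, 0))
  inter <- s[s$kind == "inter", ]
  expect_equal(inter$n_pairs, 4)
  expect_equal(inter$mean, 0.1)
})

test_that("singleton groups report undefined intra cells, not zero", {
  d <- toy3()
  part <- c(a = "g1", b = "g1", c = "solo")
  s <- summarize_distances(d, part)
  solo <- s[s$kind == "intra" & s$group1 == "solo", ]
  expect_true(is.na(solo$min))
  expect_equal(solo$n_pairs, 0)
})

test_that("summaries reject incomplete or empty partitions", {
  d <- toy3()
  expect_error(summarize_distances(d, c(a = "g1", b = "g1")), "unassigned.*c")
})

test_that("predefined partitions come from the metadata lineage column", {
  sim <- simulate_alignment(scenario_config(seed = 2))
  part <- partition_from_metadata(sim$aln)
  expect_equal(attr(part, "source"), "predefined")
  expect_setequal(unique(unname(part)),
                  c("carteri", "ivonicus_yuna", "outgroup"))
  expect_error(partition_from_metadata(sim$aln, column = "nope"),
               "not available")
})
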