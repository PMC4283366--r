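test_that("perfectly separated characters become candidates", {
  m <- tiny_morph(list(app_masc = list(a = rep("long", 5),
                                       b = rep("short", 5))))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_equal(cands$character, "app_masc")
  expect_equal(cands$const_a, 1.0)
  expect_equal(cands$const_b, 1.0)
  expect_equal(cands$state_a, "long")
  expect_equal(cands$state_b, "short")
})

test_that("constancy exactly at the threshold is not retained", {
  # 4/5 = 0.80 is not strictly greater than 0.80
  m <- tiny_morph(list(ch = list(a = c(rep("long", 4), "short"),
                                 b = rep("short", 5))))
  cands <- initial_screen(m, c("cladeA", "cladeB"), threshold = 0.80)
  expect_equal(nrow(cands), 0L)
  # just above the boundary it is retained
  cands2 <- initial_screen(m, c("cladeA", "cladeB"), threshold = 0.79)
  expect_equal(nrow(cands2), 1L)
})

test_that("identical modal states never yield a candidate", {
  m <- tiny_morph(list(ch = list(a = c(rep("long", 9), "short"),
                                 b = c(rep("long", 9), "mid"))))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_equal(nrow(cands), 0L)
})

test_that("constancy ignores unknown states", {
  m <- tiny_morph(list(ch = list(a = c(rep("long", 4), "unknown"),
                                 b = rep("short", 5))))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_equal(cands$const_a, 1.0)     # 4/4 known
  expect_equal(cands$known_a, 4L)
})

test_that("screening validates its inputs and flags degenerate characters", {
  m <- tiny_morph(list(ch = list(a = rep("long", 5), b = rep("short", 5))))
  expect_error(initial_screen(m, c("cladeA", "nope")), "absent")
  m2 <- tiny_morph(list(ch = list(a = rep("unknown", 5),
                                  b = rep("short", 5))))
  expect_warning(out <- initial_screen(m2, c("cladeA", "cladeB")),
                 "entirely unknown")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "skipped")$reason, "entirely unknown in a clade")
  # modal tie within a clade: skipped and recorded
  m3 <- tiny_morph(list(ch = list(a = c("long", "long", "short", "short"),
                                  b = rep("mid", 4))))
  out3 <- initial_screen(m3, c("cladeA", "cladeB"))
  expect_equal(attr(out3, "skipped")$reason, "modal-state tie within a clade")
})

test_that("juveniles are excluded by default but usable on demand", {
  m <- tiny_morph(list(ch = list(a = rep("long", 6),
                                 b = rep("short", 6))),
                  stage_a = c(rep("adult", 4), "juvenile", "juvenile"))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_equal(cands$known_a, 4L)
  cands2 <- initial_screen(m, c("cladeA", "cladeB"), adults_only = FALSE)
  expect_equal(cands2$known_a, 6L)
})

# build a matrix with 10 vouchers per clade (9/10 matching in A), plus a
# validation pool of 10 same-lot specimens per clade with `n_match`
# matching in clade A; clade B is perfectly constant throughout.
block_case <- function(n_match) {
  a_v <- c(rep("long", 9), "short")
  a_p <- c(rep("long", n_match), rep("short", 10 - n_match))
  b_v <- rep("short", 10)
  b_p <- rep("short", 10)
  tiny_morph(list(ch = list(a = c(a_v, a_p), b = c(b_v, b_p))),
             voucher_a = rep(c(TRUE, FALSE), each = 10),
             voucher_b = rep(c(TRUE, FALSE), each = 10),
             lot_a = rep("lotA1", 20), lot_b = rep("lotB1", 20))
}

test_that("cumulative block constancy drives retention and discard", {
  # 9/10 initial + 9/10 block -> 18/20 = 0.90, retained
  m <- block_case(9)
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_equal(cands$const_a, 0.9)
  val <- block_validate(cands, m, block_size = 10, seed = 3)
  expect_equal(nrow(val$survivors), 1L)
  expect_equal(val$survivors$const_a, 18 / 20)
  expect_equal(val$trace$decisions$decision, "retained")

  # 9/10 initial + 6/10 block -> 15/20 = 0.75 < 0.8, discarded at block 1
  m2 <- block_case(6)
  cands2 <- initial_screen(m2, c("cladeA", "cladeB"))
  val2 <- block_validate(cands2, m2, block_size = 10, seed = 3)
  expect_equal(nrow(val2$survivors), 0L)
  expect_equal(val2$trace$decisions$decision, "discarded")
  expect_equal(val2$trace$decisions$block, 1)
  expect_equal(val2$trace$decisions$cum_const_a, 0.75)
})

test_that("block composition and trace are reproducible from the seed", {
  m <- simulate_morphology(morph_scenario(seed = 11))
  cands <- initial_screen(m, c("carteri", "ivonicus_yuna"))
  v1 <- block_validate(cands, m, seed = 5)
  v2 <- block_validate(cands, m, seed = 5)
  expect_identical(v1$trace, v2$trace)
  expect_identical(v1$survivors, v2$survivors)
})

test_that("an empty validation pool passes candidates through with a note", {
  m <- tiny_morph(list(ch = list(a = rep("long", 5), b = rep("short", 5))))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  val <- block_validate(cands, m)
  expect_identical(val$survivors$character, cands$character)
  expect_match(val$trace$notes, "empty")
})

test_that("block specimen counts are conserved over the validation pool", {
  m <- simulate_morphology(morph_scenario(seed = 21))
  cands <- initial_screen(m, c("carteri", "ivonicus_yuna"))
  val <- block_validate(cands, m, block_size = 10, seed = 2)
  s <- m$specimens
  vouchers <- s$id[s$voucher]
  pool_size <- function(cl) {
    lots <- unique(s$lot[s$voucher & s$clade == cl])
    sum(s$clade == cl & s$lot %in% lots & !(s$id %in% vouchers) &
        s$stage == "adult")
  }
  expect_equal(sum(val$trace$blocks$n_a), pool_size("carteri"))
  expect_equal(sum(val$trace$blocks$n_b), pool_size("ivonicus_yuna"))
})

test_that("hold-out confirmation keeps perfect and drops failing survivors", {
  # survivor matrix: one voucher lot (screen data perfect) and one
  # hold-out lot per clade with controllable agreement
  holdout_case <- function(n_match) {
    a_v <- rep("long", 10); b_v <- rep("short", 10)
    a_h <- c(rep("long", n_match), rep("short", 10 - n_match))
    b_h <- rep("short", 10)
    tiny_morph(list(ch = list(a = c(a_v, a_h), b = c(b_v, b_h))),
               voucher_a = rep(c(TRUE, FALSE), each = 10),
               voucher_b = rep(c(TRUE, FALSE), each = 10),
               lot_a = rep(c("lotA1", "lotA2"), each = 10),
               lot_b = rep(c("lotB1", "lotB2"), each = 10))
  }
  m <- holdout_case(10)
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  fin <- final_check(cands, m, block_size = 10, seed = 1)
  expect_equal(nrow(fin), 1L)
  expect_equal(fin$holdout_const_a, 1.0)

  # 7/10 on hold-out -> 0.7 < 0.8: removed, and the trace says where
  m2 <- holdout_case(7)
  cands2 <- initial_screen(m2, c("cladeA", "cladeB"))
  fin2 <- final_check(cands2, m2, block_size = 10, seed = 1)
  expect_equal(nrow(fin2), 0L)
  tr <- attr(fin2, "trace")$decisions
  expect_equal(tr$decision, "discarded")
  expect_equal(tr$block, 1)
  expect_equal(tr$cum_const_a, 0.7)
})

test_that("without hold-out lots survivors are confirmed with a warning", {
  m <- tiny_morph(list(ch = list(a = rep("long", 5), b = rep("short", 5))))
  cands <- initial_screen(m, c("cladeA", "cladeB"))
  expect_warning(fin <- final_check(cands, m), "hold-out pool empty")
  expect_equal(fin$character, cands$character)
  expect_true(is.na(fin$holdout_const_a))
})

test_that("lowering the threshold never removes a survivor", {
  for (seed in 1:20) {
    m <- simulate_morphology(morph_scenario(seed = seed))
    hi <- screen_characters(m, c("carteri", "ivonicus_yuna"),
                            threshold = 0.90, seed = 1)
    lo <- screen_characters(m, c("carteri", "ivonicus_yuna"),
                            threshold = 0.70, seed = 1)
    expect_true(all(hi$validated$character %in% lo$validated$character))
    expect_true(all(hi$confirmed$character %in% lo$confirmed$character))
  }
})

test_that("a character with zero state overlap survives any threshold < 1", {
  chars <- data.frame(name = "perfect", type = "diagnostic",
                      constancy = 1.0, n_states = 2L)
  m <- simulate_morphology(morph_scenario(characters = chars,
                                          unknown_fraction = 0, seed = 3))
  for (thr in c(0.5, 0.8, 0.95)) {
    res <- screen_characters(m, c("carteri", "ivonicus_yuna"),
                             threshold = thr, seed = 2)
    expect_equal(res$confirmed$character, "perfect")
  }
})

test_that("retention tracks true constancy at the 0.80 threshold", {
  # >= 40 scored specimens per clade in the initial screen
  scen <- function(cc, seed) {
    morph_scenario(n_per_clade = 80, n_lots = 16, voucher_lots = 14,
                   vouchers_per_lot = 3,
                   characters = data.frame(name = "ch", type = "diagnostic",
                                           constancy = cc, n_states = 2L),
                   seed = seed)
  }
  retained <- function(cc) {
    hits <- 0L
    for (seed in 1:500) {
      m <- simulate_morphology(scen(cc, seed))
      cands <- initial_screen(m, c("carteri", "ivonicus_yuna"))
      if (nrow(cands)) {
        val <- block_validate(cands, m, seed = seed)
        if (nrow(val$survivors)) hits <- hits + 1L
      }
    }
    hits / 500
  }
  expect_gte(retained(0.95), 0.95)
  expect_lte(retained(0.60), 0.05)
})
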