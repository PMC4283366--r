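# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (explicit loops over columns and pairs) so they share
# no code path with the package implementation they check.

make_aln <- function(...) {
  v <- c(...)
  as_alignment(v)
}

random_aln <- function(n, L, seed) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(mat) <- paste0("s", seq_len(n))
  as_alignment(mat)
}

# per-column tally of site categories
oracle_classify <- function(aln) {
  n_const <- n_single <- n_pi <- 0L
  for (j in seq_len(ncol(aln$mat))) {
    tab <- table(aln$mat[, j])
    if (length(tab) == 1L) {
      n_const <- n_const + 1L
    } else if (sum(tab >= 2L) >= 2L) {
      n_pi <- n_pi + 1L
    } else {
      n_single <- n_single + 1L
    }
  }
  list(n_total = ncol(aln$mat), n_constant = n_const,
       n_variable = n_single + n_pi, n_singleton = n_single,
       n_parsimony_informative = n_pi)
}

# double loop over pairs and columns
oracle_pdist <- function(aln, deletion = "complete") {
  mat <- aln$mat
  acgt <- c("A", "C", "G", "T")
  if (deletion == "complete") {
    keep <- rep(TRUE, ncol(mat))
    for (j in seq_len(ncol(mat))) {
      for (i in seq_len(nrow(mat))) {
        if (!(mat[i, j] %in% acgt)) keep[j] <- FALSE
      }
    }
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mism <- comp <- 0L
      for (s in seq_len(ncol(mat))) {
        a <- mat[i, s]; b <- mat[j, s]
        if (a %in% acgt && b %in% acgt) {
          comp <- comp + 1L
          if (a != b) mism <- mism + 1L
        }
      }
      d[i, j] <- mism / comp
    }
  }
  d
}

# enumerate pairs into intra/inter cells
oracle_summary_cell <- function(dm, part, g, h) {
  labs <- rownames(dm)
  vals <- c()
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j) next
      gi <- part[[labs[i]]]; gj <- part[[labs[j]]]
      if ((gi == g && gj == h) || (gi == h && gj == g)) {
        vals <- c(vals, dm[i, j])
      }
    }
  }
  vals
}

# tiny morphology matrix builder: states is a named list character ->
# list(a = vector of clade-A states, b = clade-B states); all specimens
# adult vouchers in one lot per clade unless overridden.
tiny_morph <- function(states, voucher_a = NULL, voucher_b = NULL,
                       lot_a = NULL, lot_b = NULL, stage_a = NULL,
                       stage_b = NULL) {
  n_a <- length(states[[1L]]$a)
  n_b <- length(states[[1L]]$b)
  if (is.null(voucher_a)) voucher_a <- rep(TRUE, n_a)
  if (is.null(voucher_b)) voucher_b <- rep(TRUE, n_b)
  if (is.null(lot_a)) lot_a <- rep("lotA1", n_a)
  if (is.null(lot_b)) lot_b <- rep("lotB1", n_b)
  if (is.null(stage_a)) stage_a <- rep("adult", n_a)
  if (is.null(stage_b)) stage_b <- rep("adult", n_b)
  specimens <- data.frame(
    id = c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b))),
    lot = c(lot_a, lot_b),
    clade = c(rep("cladeA", n_a), rep("cladeB", n_b)),
    stage = c(stage_a, stage_b),
    voucher = c(voucher_a, voucher_b))
  st <- sapply(states, function(s) c(s$a, s$b))
  if (!is.matrix(st)) st <- matrix(st, ncol = length(states),
                                   dimnames = list(NULL, names(states)))
  character_matrix(specimens, st)
}
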