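#' Classify alignment columns into site-pattern categories
#'
#' A column is variable when at least two distinct nucleotide states occur;
#' a variable column is parsimony-informative when at least two states are
#' each carried by at least two sequences, and singleton-variable otherwise.
#' The alignment must already be restricted to unambiguous A/C/G/T columns
#' (see [filter_columns()]).
#'
#' @param aln an `aln` object containing only A, C, G, T.
#' @return object of class `site_classification` with counts `n_total`,
#'   `n_constant`, `n_variable`, `n_singleton`,
#'   `n_parsimony_informative`.
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  bad <- setdiff(unique(as.vector(aln$mat)), c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("non-ACGT symbol(s) present (", paste(bad, collapse = " "),
         "); run filter_columns() first", call. = FALSE)
  }
  counts <- apply(aln$mat, 2L, function(col) {
    tab <- tabulate(match(col, c("A", "C", "G", "T")), 4L)
    states <- sum(tab > 0L)
    c(variable = states >= 2L, pi = sum(tab >= 2L) >= 2L && states >= 2L)
  })
  n_var <- sum(counts["variable", ])
  n_pi <- sum(counts["pi", ])
  structure(list(n_total = ncol(aln$mat),
                 n_constant = ncol(aln$mat) - n_var,
                 n_variable = n_var,
                 n_singleton = n_var - n_pi,
                 n_parsimony_informative = n_pi),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(paste0("%d aligned positions: %d constant, %d variable ",
                     "(%d singleton, %d parsimony-informative)\n"),
              x$n_total, x$n_constant, x$n_variable, x$n_singleton,
              x$n_parsimony_informative))
  invisible(x)
}

# TRUE where the matrix holds a plain nucleotide.
.is_acgt <- function(mat) {
  matrix(mat %in% c("A", "C", "G", "T"), nrow(mat), dimnames = dimnames(mat))
}

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

# Pairwise mismatch bookkeeping shared by p_distance() and the corrected
# matrices: per pair, the number of compared columns, total mismatches and
# the transition subset.
.pair_counts <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  mat <- aln$mat
  ok <- .is_acgt(mat)
  if (deletion == "complete") {
    keep <- apply(ok, 2L, all)
    if (!any(keep)) {
      stop("no columns free of gap/missing/ambiguous symbols under ",
           "complete deletion", call. = FALSE)
    }
    mat <- mat[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  ids <- aln$ids
  zero <- matrix(0, n, n, dimnames = list(ids, ids))
  out <- list(n_compared = zero, mismatch = zero, transitions = zero)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      if (nc == 0L) {
        stop("no comparable columns for pair ", ids[i], " / ", ids[j],
             call. = FALSE)
      }
      a <- mat[i, use]
      b <- mat[j, use]
      mism <- a != b
      ts <- mism & (.TRANSITIONS[a] == b)
      out$n_compared[i, j] <- out$n_compared[j, i] <- nc
      out$mismatch[i, j] <- out$mismatch[j, i] <- sum(mism)
      out$transitions[i, j] <- out$transitions[j, i] <- sum(ts)
    }
  }
  out
}

#' Uncorrected pairwise distance matrix (p-distance)
#'
#' Entry (i, j) is the proportion of compared columns at which sequences i
#' and j differ. Under complete deletion every column containing a gap,
#' missing or ambiguous symbol in any sequence is dropped before
#' comparison; under pairwise deletion such columns are skipped per pair.
#'
#' @param aln an `aln` object with at least two sequences.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return symmetric numeric matrix of proportions with a zero diagonal,
#'   labelled by sequence id.
#' @export
p_distance <- function(aln, deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "aln"))
  if (length(aln$ids) < 2L) stop("need at least two sequences", call. = FALSE)
  pc <- .pair_counts(aln, deletion)
  d <- pc$mismatch / pc$n_compared
  diag(d) <- 0
  d
}

#' Transition/transversion components of pairwise divergence
#'
#' @inheritParams p_distance
#' @return list of symmetric matrices: `P` (transition proportion), `Q`
#'   (transversion proportion), `p` (= P + Q) and `n_compared`.
#' @export
pair_components <- function(aln, deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "aln"))
  pc <- .pair_counts(aln, deletion)
  P <- pc$transitions / pc$n_compared
  Q <- (pc$mismatch - pc$transitions) / pc$n_compared
  diag(P) <- diag(Q) <- 0
  list(P = P, Q = Q, p = P + Q, n_compared = pc$n_compared)
}

#' Multiple-hit correction of an uncorrected distance
#'
#' Converts a proportion of differing sites into an estimated number of
#' substitutions per site under the Jukes-Cantor (JC) or Kimura
#' two-parameter (K2P) model. JC: d = -(3/4) log(1 - 4p/3). K2P:
#' d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q), with `P` the transition
#' and `Q` the transversion proportion (P + Q = p). Both corrections are
#' monotone in p and never smaller than p.
#'
#' @param p uncorrected proportion(s) of differing sites.
#' @param model `"K2P"` (default) or `"JC"`.
#' @param P,Q transition and transversion proportions, required for K2P.
#' @return corrected divergence(s), substitutions per site.
#' @export
correct_distance <- function(p, model = c("K2P", "JC"), P = NULL, Q = NULL) {
  model <- match.arg(model)
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  if (model == "JC") {
    if (any(p >= 0.75)) {
      stop("distance undefined under model: p >= 3/4 (JC saturation)",
           call. = FALSE)
    }
    return(-0.75 * log(1 - 4 * p / 3))
  }
  if (is.null(P) || is.null(Q)) {
    stop("K2P correction needs transition (P) and transversion (Q) ",
         "proportions", call. = FALSE)
  }
  if (any(abs(P + Q - p) > 1e-9)) {
    stop("P + Q must equal p", call. = FALSE)
  }
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0)) {
    stop("distance undefined under model: K2P log argument non-positive",
         call. = FALSE)
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Model-corrected pairwise distance matrix
#'
#' @inheritParams p_distance
#' @param model `"K2P"` (default) or `"JC"`.
#' @return symmetric matrix of corrected divergences (substitutions/site).
#' @export
corrected_distance <- function(aln, model = c("K2P", "JC"),
                               deletion = c("complete", "pairwise")) {
  model <- match.arg(model)
  comp <- pair_components(aln, deletion)
  d <- matrix(0, nrow(comp$p), ncol(comp$p), dimnames = dimnames(comp$p))
  up <- upper.tri(d)
  d[up] <- if (model == "JC") {
    correct_distance(comp$p[up], "JC")
  } else {
    correct_distance(comp$p[up], "K2P", P = comp$P[up], Q = comp$Q[up])
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param d labelled square matrix.
#' @param path output path.
#' @param format `"tsv"` (header row and column) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(sprintf("%5d", nrow(d)),
               vapply(seq_len(nrow(d)), function(i) {
                 paste0(formatC(rownames(d)[i], width = -12),
                        paste(sprintf("%.8f", d[i, ]), collapse = " "))
               }, character(1L)))
    writeLines(lines, path)
  }
  invisible(path)
}
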