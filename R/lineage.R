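#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group agglomeration with arithmetic means. At each step
#' the pair of clusters at minimum distance is joined; ties are broken by
#' the lexicographically smallest pair of cluster representatives (each
#' cluster represented by its alphabetically first member id). The node
#' height of a join is half the joining distance, so root-to-tip height is
#' on the divergence scale.
#'
#' @param d labelled symmetric numeric matrix (or `dist`) with zero
#'   diagonal and no negative or missing entries.
#' @return object of class `upgma_tree`: `labels`, `merge` (hclust-style
#'   merge matrix), `height` (node heights, half joining distances) and
#'   `members` (leaf index sets per internal node).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2L) stop("need at least two labels", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix has NA/NaN/Inf entries",
                               call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric",
                                       call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)

  active <- seq_len(n)                       # indices into cur* vectors
  cur_d <- d
  cur_id <- -seq_len(n)                      # hclust convention
  cur_size <- rep(1L, n)
  cur_rep <- labels                          # lexicographic representative
  cur_members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    dm <- cur_d
    diag(dm) <- Inf
    dmin <- min(dm)
    cand <- which(dm == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # tie-break: smallest (sorted) representative pair, lexicographically
    key <- apply(cand, 1L, function(ij) {
      r <- sort(c(cur_rep[ij[1L]], cur_rep[ij[2L]]))
      paste(r, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]

    merge[step, ] <- sort(c(cur_id[i], cur_id[j]))
    height[step] <- dmin / 2
    members[[step]] <- sort(c(cur_members[[i]], cur_members[[j]]))

    # UPGMA update: size-weighted average to all other clusters
    others <- setdiff(seq_len(m), c(i, j))
    newrow <- (cur_size[i] * cur_d[i, others] +
               cur_size[j] * cur_d[j, others]) / (cur_size[i] + cur_size[j])
    keep <- others
    nd <- cur_d[keep, keep, drop = FALSE]
    cur_d <- rbind(cbind(nd, newrow), c(newrow, 0))
    cur_id <- c(cur_id[keep], step)
    cur_size <- c(cur_size[keep], cur_size[i] + cur_size[j])
    cur_rep <- c(cur_rep[keep], min(cur_rep[i], cur_rep[j]))
    cur_members <- c(cur_members[keep], list(members[[step]]))
    active <- seq_along(cur_id)
  }
  structure(list(labels = labels, merge = merge, height = height,
                 members = members),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree> ", length(x$labels), " leaves, root height ",
      signif(max(x$height), 4), "\n", sep = "")
  invisible(x)
}

# Recursive leaf ordering so the object can masquerade as an hclust.
.tree_order <- function(merge) {
  leaves <- function(k) {
    if (k < 0L) return(-k)
    c(leaves(merge[k, 1L]), leaves(merge[k, 2L]))
  }
  leaves(nrow(merge))
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' Branch lengths are on the node-height (divergence) scale, so the tree
#' is ultrametric with root-to-tip distance equal to the root height.
#'
#' @param x an `upgma_tree`.
#' @param ... ignored.
#' @return a rooted ultrametric `phylo` object.
#' @exportS3Method ape::as.phylo
as.phylo.upgma_tree <- function(x, ...) {
  hc <- structure(list(merge = x$merge, height = 2 * x$height,
                       order = .tree_order(x$merge), labels = x$labels,
                       method = "average"),
                  class = "hclust")
  ape::as.phylo(hc)
}

#' Write a UPGMA tree as Newick
#'
#' @param tree an `upgma_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Cut a UPGMA tree at a divergence height
#'
#' Leaves joined by nodes strictly below `height` form one group, so a cut
#' at 0 yields singletons and a cut above the root a single group. Groups
#' are labelled `group1..groupK` in order of their alphabetically smallest
#' member id.
#'
#' @param tree an `upgma_tree`.
#' @param height non-negative divergence threshold (node-height scale,
#'   i.e. half the joining distance).
#' @return a lineage partition: named character vector mapping id to group
#'   label, with attribute `source = "tree-cut"`.
#' @export
cut_tree <- function(tree, height) {
  stopifnot(inherits(tree, "upgma_tree"), height >= 0)
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
  for (k in seq_along(tree$height)) {
    if (tree$height[k] < height) {
      mem <- tree$members[[k]]
      r0 <- find(parent, mem[1L])
      for (m in mem[-1L]) parent[find(parent, m)] <- r0
    }
  }
  root <- vapply(seq_len(n), function(i) find(parent, i), integer(1L))
  groups <- split(seq_len(n), root)
  first_id <- vapply(groups, function(g) min(tree$labels[g]), character(1L))
  groups <- groups[order(first_id)]
  assignment <- character(n)
  for (g in seq_along(groups)) assignment[groups[[g]]] <- paste0("group", g)
  names(assignment) <- tree$labels
  attr(assignment, "source") <- "tree-cut"
  assignment
}

#' Lineage partition from a metadata column
#'
#' @param aln an `aln` with joined metadata, or a metadata data frame.
#' @param column metadata column holding the group label.
#' @return named character vector id -> group, attribute
#'   `source = "predefined"`.
#' @export
partition_from_metadata <- function(aln, column = "lineage") {
  meta <- if (inherits(aln, "aln")) aln$meta else aln
  if (is.null(meta) || !column %in% names(meta)) {
    stop("metadata column '", column, "' not available", call. = FALSE)
  }
  lab <- meta[[column]]
  if (any(!nzchar(lab))) {
    stop("empty group label for id(s): ",
         paste(meta$id[!nzchar(lab)], collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(lab, meta$id)
  attr(out, "source") <- "predefined"
  out
}

#' Intra- and inter-group divergence summary
#'
#' For every group the min/mean/max over all within-group pairs, and for
#' every unordered pair of groups the min/mean/max over all cross pairs.
#' Means are unweighted arithmetic means over pairs. Intra cells of
#' singleton groups are reported as undefined (`NA`) with `n_pairs = 0`,
#' never as zero.
#'
#' @param d labelled symmetric distance matrix.
#' @param partition named character vector mapping every matrix label to a
#'   group.
#' @return data frame with columns `kind` ("intra"/"inter"), `group1`,
#'   `group2`, `n_pairs`, `min`, `mean`, `max`.
#' @export
summarize_distances <- function(d, partition) {
  labs <- rownames(d)
  missing <- setdiff(labs, names(partition))
  if (length(missing)) {
    stop("unassigned id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  part <- partition[labs]
  groups <- sort(unique(as.character(part)))
  empty <- groups[!groups %in% part]
  if (length(empty)) stop("group(s) with no members: ",
                          paste(empty, collapse = ", "), call. = FALSE)
  cell <- function(vals) {
    if (!length(vals)) return(c(n_pairs = 0, min = NA, mean = NA, max = NA))
    c(n_pairs = length(vals), min = min(vals), mean = mean(vals),
      max = max(vals))
  }
  rows <- list()
  for (g in groups) {
    idx <- which(part == g)
    vals <- if (length(idx) >= 2L) d[idx, idx][upper.tri(d[idx, idx])] else numeric(0)
    rows[[length(rows) + 1L]] <- data.frame(kind = "intra", group1 = g,
                                            group2 = g, t(cell(vals)))
  }
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        vi <- which(part == groups[i]); vj <- which(part == groups[j])
        vals <- as.vector(d[vi, vj, drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(kind = "inter",
                                                group1 = groups[i],
                                                group2 = groups[j],
                                                t(cell(vals)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
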