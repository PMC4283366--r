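#' Calibrate a strict-clock substitution rate from a dated sister pair
#'
#' Under a strict clock two lineages that split t million years ago have
#' accumulated d = 2 r t substitutions per site between them, so a dated
#' split with known corrected divergence fixes the rate as
#' r = d / (2 t).
#'
#' @param d_cal corrected divergence (substitutions/site) between the
#'   calibration pair.
#' @param t_cal split time of the pair, Ma.
#' @param pair optional character vector of the two calibration ids, kept
#'   for provenance.
#' @return object of class `rate_calibration` with fields `rate`
#'   (substitutions/site/Myr), `d_cal`, `t_cal`, `pair`.
#' @examples
#' calibrate_rate(0.0498, 3)  # rate 0.0083 subs/site/Myr
#' @export
calibrate_rate <- function(d_cal, t_cal, pair = NULL) {
  if (!is.numeric(d_cal) || d_cal <= 0) stop("d_cal must be > 0", call. = FALSE)
  if (!is.numeric(t_cal) || t_cal <= 0) stop("t_cal must be > 0", call. = FALSE)
  structure(list(rate = d_cal / (2 * t_cal), d_cal = d_cal, t_cal = t_cal,
                 pair = pair),
            class = "rate_calibration")
}

#' Use a published substitution rate directly
#'
#' @param rate substitutions/site/Myr, > 0.
#' @return a `rate_calibration` with no calibration pair recorded.
#' @export
rate_constant <- function(rate) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  structure(list(rate = rate, d_cal = NULL, t_cal = NULL, pair = NULL),
            class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat("strict-clock rate:", signif(x$rate, 6), "subs/site/Myr")
  if (!is.null(x$t_cal)) {
    cat(" (d =", x$d_cal, "at", x$t_cal, "Ma")
    if (!is.null(x$pair)) cat(", pair ", paste(x$pair, collapse = " / "))
    cat(")")
  }
  cat("\n")
  invisible(x)
}

.as_rate <- function(cal) {
  if (inherits(cal, "rate_calibration")) cal$rate
  else if (is.numeric(cal) && length(cal) == 1L && cal > 0) cal
  else stop("need a rate_calibration or a positive rate", call. = FALSE)
}

#' Convert a corrected divergence to a divergence time
#'
#' Inverse of the clock relation: t = d / (2 r), in Ma.
#'
#' @param d corrected divergence (substitutions/site), >= 0.
#' @param cal a `rate_calibration` (or a bare positive rate).
#' @return divergence time in Ma.
#' @export
estimate_divergence_time <- function(d, cal) {
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  d / (2 * .as_rate(cal))
}

#' Mean corrected divergence between two groups
#'
#' The group-level divergence is the unweighted mean of corrected
#' distances over all cross pairs (one member from each group).
#'
#' @param aln a column-filtered `aln`.
#' @param partition named character vector id -> group.
#' @param groups the two group labels to compare.
#' @param model `"K2P"` (default) or `"JC"`.
#' @return mean corrected cross-pair divergence (substitutions/site).
#' @export
group_divergence <- function(aln, partition, groups, model = c("K2P", "JC")) {
  model <- match.arg(model)
  stopifnot(length(groups) == 2L)
  dm <- corrected_distance(aln, model = model, deletion = "complete")
  ids_g <- names(partition)[partition == groups[1L]]
  ids_h <- names(partition)[partition == groups[2L]]
  if (!length(ids_g) || !length(ids_h)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mean(dm[ids_g, ids_h])
}

# Per-cross-pair, per-column transition/transversion mismatch indicators;
# the bootstrap statistic only needs these.
.cross_pair_indicators <- function(aln, ids_g, ids_h) {
  mat <- aln$mat
  bad <- setdiff(unique(as.vector(mat[c(ids_g, ids_h), ])),
                 c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("alignment must be column-filtered before bootstrapping (found ",
         paste(bad, collapse = " "), ")", call. = FALSE)
  }
  pairs <- expand.grid(g = ids_g, h = ids_h, stringsAsFactors = FALSE)
  L <- ncol(mat)
  ts <- tv <- matrix(0, nrow(pairs), L)
  for (k in seq_len(nrow(pairs))) {
    a <- mat[pairs$g[k], ]
    b <- mat[pairs$h[k], ]
    mism <- a != b
    is_ts <- mism & (.TRANSITIONS[a] == b)
    ts[k, ] <- as.numeric(is_ts)
    tv[k, ] <- as.numeric(mism & !is_ts)
  }
  list(ts = ts, tv = tv, pairs = pairs, L = L)
}

#' Site-bootstrap interval for a divergence time
#'
#' Resamples alignment columns with replacement; each replicate recomputes
#' the mean corrected cross-group divergence and the corresponding clock
#' time t = d / (2 r). The interval is the 2.5/97.5 percentile of the
#' replicate times. Replicates in which any cross pair reaches the model's
#' saturation bound are dropped and counted; more than 10% dropped is an
#' error. This is a site-resampling uncertainty construct, not a Bayesian
#' credible interval.
#'
#' @param aln column-filtered `aln`.
#' @param partition named character vector id -> group.
#' @param groups the two group labels.
#' @param cal a `rate_calibration`.
#' @param model `"K2P"` or `"JC"`.
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param seed integer seed; the result is fully reproducible from it.
#' @return object of class `time_estimate`: `t_hat` (point estimate from
#'   the original columns), `lo`, `hi`, `method`, `n_reps`,
#'   `n_dropped`, `seed`, `model`, `rate`.
#' @export
bootstrap_time <- function(aln, partition, groups, cal,
                           model = c("K2P", "JC"), n_reps = 1000L,
                           seed = 1L) {
  model <- match.arg(model)
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  rate <- .as_rate(cal)
  ids_g <- names(partition)[partition == groups[1L]]
  ids_h <- names(partition)[partition == groups[2L]]
  if (!length(ids_g) || !length(ids_h)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ind <- .cross_pair_indicators(aln, ids_g, ids_h)
  L <- ind$L

  pair_time <- function(ts_cnt, tv_cnt) {
    P <- ts_cnt / L; Q <- tv_cnt / L; p <- P + Q
    if (model == "JC") {
      if (any(p >= 0.75)) return(NA_real_)
      d <- -0.75 * log(1 - 4 * p / 3)
    } else {
      if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0)) return(NA_real_)
      d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
    mean(d) / (2 * rate)
  }

  t_hat <- pair_time(rowSums(ind$ts), rowSums(ind$tv))
  if (is.na(t_hat)) {
    stop("observed divergence at model saturation; cannot date", call. = FALSE)
  }

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  reps <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    cnt <- tabulate(idx, L)
    reps[r] <- pair_time(as.vector(ind$ts %*% cnt), as.vector(ind$tv %*% cnt))
  }
  dropped <- sum(is.na(reps))
  if (dropped > 0.1 * n_reps) {
    stop("more than 10% of bootstrap replicates at model saturation (",
         dropped, "/", n_reps, ")", call. = FALSE)
  }
  qs <- stats::quantile(reps[!is.na(reps)], c(0.025, 0.975), names = FALSE)
  structure(list(t_hat = t_hat, lo = qs[1L], hi = qs[2L],
                 method = "site-bootstrap", n_reps = n_reps,
                 n_dropped = dropped, seed = as.integer(seed), model = model,
                 rate = rate),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("divergence time %.3f Ma (%s 95%%: %.3f-%.3f, %d reps, %s)\n",
              x$t_hat, x$method, x$lo, x$hi, x$n_reps, x$model))
  invisible(x)
}

#' Tajima relative-rate test for clock-like evolution
#'
#' For an ingroup pair (A, B) and an outgroup O, counts the sites at which
#' A alone differs from the other two (B matches O) against the sites at
#' which B alone differs (A matches O). Under a molecular clock the two
#' counts have equal expectation; the test statistic is
#' (nA - nB)^2 / (nA + nB), compared to a chi-square with 1 df. Sites
#' where any of the three sequences carries a non-ACGT symbol are skipped.
#'
#' @param aln an `aln` containing all three ids.
#' @param pair character vector of the two ingroup ids.
#' @param outgroup outgroup id.
#' @return object of class `relative_rate_test`: `n_a`, `n_b`,
#'   `statistic`, `p_value` (both `NA` with `defined = FALSE` when no
#'   informative sites exist).
#' @export
relative_rate_check <- function(aln, pair, outgroup) {
  stopifnot(inherits(aln, "aln"), length(pair) == 2L)
  ids <- c(pair, outgroup)
  if (length(unique(ids)) != 3L) stop("need three distinct ids", call. = FALSE)
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) stop("id(s) not in alignment: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  a <- aln$mat[pair[1L], ]; b <- aln$mat[pair[2L], ]; o <- aln$mat[outgroup, ]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") &
        o %in% c("A", "C", "G", "T")
  n_a <- sum(ok & a != o & b == o)
  n_b <- sum(ok & b != o & a == o)
  if (n_a + n_b == 0L) {
    out <- list(n_a = n_a, n_b = n_b, statistic = NA_real_,
                p_value = NA_real_, defined = FALSE)
  } else {
    stat <- (n_a - n_b)^2 / (n_a + n_b)
    out <- list(n_a = n_a, n_b = n_b, statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                defined = TRUE)
  }
  structure(out, class = "relative_rate_test")
}

#' @export
print.relative_rate_test <- function(x, ...) {
  if (!x$defined) {
    cat("relative-rate test undefined: no informative sites\n")
  } else {
    cat(sprintf("relative-rate test: nA=%d nB=%d chisq=%.4f p=%.4f\n",
                x$n_a, x$n_b, x$statistic, x$p_value))
  }
  invisible(x)
}
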