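#' Scenario configuration for clock-like sequence simulation
#'
#' The default scenario mirrors the study conditions the pipeline targets:
#' a three-lineage ingroup (two sister lineages splitting 2.6 Ma inside a
#' 10 Ma deep split) plus an older outgroup, evolving a 435-site
#' mitochondrial 16S-like fragment under a strict clock of 0.0083
#' substitutions/site/Myr. Within-lineage variation is modelled as a star
#' of short terminal branches of age `within_age`.
#'
#' @param split_ingroup age (Ma) of the split between lineage 1 and the
#'   sister pair (default 10).
#' @param split_sisters age (Ma) of the sister-lineage split (default 2.6).
#' @param age_outgroup root age (Ma; default 25, comfortably older than
#'   all ingroup splits yet below the saturation regime at the default
#'   rate).
#' @param within_age age (Ma) of the within-lineage star (default 1.1, so
#'   expected intra-lineage divergence sits in the low single-digit
#'   percent range typical of such data).
#' @param rate strict-clock substitution rate, substitutions/site/Myr
#'   (default 0.0083).
#' @param n_sites alignment length (default 435).
#' @param model `"JC"` (default) or `"K2P"`.
#' @param kappa K2P transition/transversion rate ratio (default 4).
#' @param n_per_tip named integer vector: sequences per lineage (default
#'   `c(carteri = 4, ivonicus = 4, yuna = 1)`, plus one outgroup
#'   sequence).
#' @param seed integer seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(split_ingroup = 10, split_sisters = 2.6,
                            age_outgroup = 25, within_age = 1.1,
                            rate = 0.0083, n_sites = 435L,
                            model = c("JC", "K2P"), kappa = 4,
                            n_per_tip = c(carteri = 4L, ivonicus = 4L,
                                          yuna = 1L),
                            seed = 1L) {
  model <- match.arg(model)
  stopifnot(rate >= 0, n_sites > 0, length(n_per_tip) == 3L,
            all(n_per_tip >= 1L), !is.null(names(n_per_tip)))
  if (!(within_age < split_sisters && split_sisters < split_ingroup &&
        split_ingroup < age_outgroup)) {
    stop("node ages must increase root-ward: within_age < split_sisters < ",
         "split_ingroup < age_outgroup", call. = FALSE)
  }
  structure(list(split_ingroup = split_ingroup,
                 split_sisters = split_sisters,
                 age_outgroup = age_outgroup, within_age = within_age,
                 rate = rate, n_sites = as.integer(n_sites), model = model,
                 kappa = kappa, n_per_tip = n_per_tip,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

.BASES <- c("A", "C", "G", "T")

# Apply k successive substitutions to one base (multiple hits overwrite,
# so observed divergence saturates exactly as the JC/K2P expectations
# assume).
.mutate_base <- function(base, k, model, kappa) {
  for (i in seq_len(k)) {
    if (model == "JC") {
      base <- sample(setdiff(.BASES, base), 1L)
    } else {
      ts <- .TRANSITIONS[[base]]
      tv <- setdiff(.BASES, c(base, ts))
      base <- if (runif(1L) < kappa / (kappa + 2)) ts else sample(tv, 1L)
    }
  }
  base
}

.evolve <- function(seqv, t, rate, model, kappa) {
  k <- rpois(length(seqv), rate * t)
  hit <- which(k > 0L)
  for (i in hit) seqv[i] <- .mutate_base(seqv[i], k[i], model, kappa)
  seqv
}

#' Simulate a clock-like alignment
#'
#' Evolves a uniform-random root sequence down the scenario tree, placing
#' per-site Poisson substitution counts on every branch (expected
#' substitutions/site = rate x branch duration in Myr) with multiple-hit
#' overwriting. The truth record stores the generating tree, the total
#' path time between every pair of tips, the model-free expected
#' divergence (rate x path time) and, under JC, the expected p-distance
#' E[p] = (3/4)(1 - exp(-4 r T / 3)) for total path time T.
#'
#' @param cfg a [scenario_config()].
#' @return list with `aln` (an `aln` with metadata joined), `metadata`
#'   (data frame: id, taxon, locality_code, lot, lineage) and `truth`
#'   (list: `newick`, `pair_time`, `expected_d`, `expected_p_jc`,
#'   `config`).
#' @export
simulate_alignment <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  lineages <- names(cfg$n_per_tip)
  # tip ages: every sampled sequence is at the present (age 0); a lineage
  # with n > 1 sequences hangs them on a star node of age within_age.
  tip_ids <- list(); tip_lineage <- character(0)
  for (ln in lineages) {
    n <- cfg$n_per_tip[[ln]]
    ids <- if (n == 1L) ln else paste0(ln, "_", seq_len(n))
    tip_ids[[ln]] <- ids
    tip_lineage <- c(tip_lineage, rep(ln, n))
  }
  out_id <- "outgroup"

  # divergence (split) age between two tips
  split_age <- function(id1, id2) {
    l1 <- tip_lineage[[match(id1, unlist(tip_ids))]]
    l2 <- tip_lineage[[match(id2, unlist(tip_ids))]]
    if (l1 == l2) return(cfg$within_age)
    sisters <- lineages[2:3]
    if (l1 %in% sisters && l2 %in% sisters) cfg$split_sisters
    else cfg$split_ingroup
  }

  # evolve down the fixed topology
  L <- cfg$n_sites
  root <- sample(.BASES, L, replace = TRUE)
  ev <- function(s, t) .evolve(s, t, cfg$rate, cfg$model, cfg$kappa)
  seq_out <- ev(root, cfg$age_outgroup)
  node_ing <- ev(root, cfg$age_outgroup - cfg$split_ingroup)   # age 10
  node_sis <- ev(node_ing, cfg$split_ingroup - cfg$split_sisters) # age 2.6
  lineage_anc <- list()
  lineage_anc[[lineages[1L]]] <- node_ing
  lineage_anc[[lineages[2L]]] <- node_sis
  lineage_anc[[lineages[3L]]] <- node_sis
  lineage_depth <- c(cfg$split_ingroup, cfg$split_sisters, cfg$split_sisters)
  names(lineage_depth) <- lineages

  seqs <- list()
  for (ln in lineages) {
    n <- cfg$n_per_tip[[ln]]
    if (n == 1L) {
      seqs[[tip_ids[[ln]]]] <- ev(lineage_anc[[ln]], lineage_depth[[ln]])
    } else {
      star <- ev(lineage_anc[[ln]], lineage_depth[[ln]] - cfg$within_age)
      for (id in tip_ids[[ln]]) seqs[[id]] <- ev(star, cfg$within_age)
    }
  }
  seqs[[out_id]] <- seq_out

  ids <- names(seqs)
  mat <- do.call(rbind, seqs)
  rownames(mat) <- ids

  loc_prefix <- c(substr(lineages, 1L, 1L), "o")
  names(loc_prefix) <- c(lineages, out_id)
  lineage_of <- c(stats::setNames(tip_lineage, unlist(tip_ids)),
                  stats::setNames(out_id, out_id))
  # the two sister lineages form one molecular lineage for dating
  group_of <- function(ln) {
    if (ln == lineages[1L]) ln
    else if (ln == out_id) "outgroup"
    else paste(lineages[2:3], collapse = "_")
  }
  counter <- stats::setNames(rep(0L, length(loc_prefix)), names(loc_prefix))
  meta <- do.call(rbind, lapply(ids, function(id) {
    ln <- lineage_of[[id]]
    counter[[ln]] <<- counter[[ln]] + 1L
    data.frame(id = id, taxon = ln,
               locality_code = paste0(loc_prefix[[ln]], counter[[ln]]),
               lot = paste0("LOT-", toupper(substr(ln, 1L, 2L)),
                            sprintf("%02d", counter[[ln]])),
               lineage = group_of(ln))
  }))

  # truth record
  pair_time <- matrix(0, length(ids), length(ids),
                      dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      age <- if (ids[i] == out_id || ids[j] == out_id) cfg$age_outgroup
             else split_age(ids[i], ids[j])
      pair_time[i, j] <- 2 * age
    }
  }
  expected_d <- cfg$rate * pair_time
  expected_p_jc <- 0.75 * (1 - exp(-4 * expected_d / 3))

  nwk_lineage <- function(ln, depth) {
    n <- cfg$n_per_tip[[ln]]
    if (n == 1L) return(paste0(tip_ids[[ln]], ":", depth))
    inner <- paste(paste0(tip_ids[[ln]], ":", cfg$within_age),
                   collapse = ",")
    paste0("(", inner, "):", depth - cfg$within_age)
  }
  newick <- paste0("((", nwk_lineage(lineages[1L], cfg$split_ingroup), ",(",
                   nwk_lineage(lineages[2L], cfg$split_sisters), ",",
                   nwk_lineage(lineages[3L], cfg$split_sisters), "):",
                   cfg$split_ingroup - cfg$split_sisters, "):",
                   cfg$age_outgroup - cfg$split_ingroup, ",",
                   out_id, ":", cfg$age_outgroup, ");")

  max_exp <- cfg$rate * max(pair_time)
  if (max_exp > 0.7) {
    warning("expected substitutions/site ", signif(max_exp, 3),
            " on the deepest path: saturation regime", call. = FALSE)
  }

  aln <- as_alignment(mat, meta = meta)
  list(aln = aln, metadata = meta,
       truth = list(newick = newick, pair_time = pair_time,
                    expected_d = expected_d,
                    expected_p_jc = expected_p_jc,
                    config = unclass(cfg)))
}

#' Morphology simulation scenario
#'
#' Emulates a museum-style sampling design: per clade, specimens spread
#' round-robin over lots; a subset of lots contains sequenced voucher
#' specimens (always adults), the remaining lots are hold-out material.
#' Characters come in three kinds: `diagnostic` (clade-specific modal
#' state drawn with probability `constancy`), `overlapping` (one common,
#' mildly skewed state distribution in both clades) and `ontogenetic`
#' (diagnostic in adults, but juveniles flip toward the other clade's
#' state with probability `juvenile_flip`).
#'
#' @param n_per_clade specimens per clade (default 60).
#' @param n_lots lots per clade (default 12).
#' @param voucher_lots lots per clade holding vouchers (default 8).
#' @param vouchers_per_lot sequenced adults per voucher lot (default 3).
#' @param juvenile_fraction probability a non-voucher specimen is a
#'   juvenile (default 0.15).
#' @param juvenile_flip probability a juvenile shows the other clade's
#'   modal state for an ontogenetic character (default 0.5).
#' @param unknown_fraction probability a cell is unscored (default 0.02).
#' @param characters data frame with columns `name`, `type`
#'   (`diagnostic`/`overlapping`/`ontogenetic`), `constancy` (in (0.5, 1]
#'   for diagnostic/ontogenetic; ignored for overlapping) and `n_states`.
#' @param seed integer seed.
#' @return object of class `morph_scenario`.
#' @export
morph_scenario <- function(n_per_clade = 60L, n_lots = 12L,
                           voucher_lots = 8L, vouchers_per_lot = 3L,
                           juvenile_fraction = 0.15, juvenile_flip = 0.5,
                           unknown_fraction = 0.02,
                           characters = default_morph_characters(),
                           seed = 1L) {
  stopifnot(n_per_clade >= 2L, n_lots >= 1L, voucher_lots >= 1L,
            voucher_lots <= n_lots,
            juvenile_fraction >= 0, juvenile_fraction <= 1,
            juvenile_flip >= 0, juvenile_flip <= 1,
            unknown_fraction >= 0, unknown_fraction <= 1,
            is.data.frame(characters),
            all(c("name", "type", "constancy", "n_states") %in%
                names(characters)))
  diag_c <- characters$constancy[characters$type != "overlapping"]
  if (any(!is.na(diag_c) & (diag_c <= 0.5 | diag_c > 1))) {
    stop("diagnostic/ontogenetic constancy must lie in (0.5, 1]",
         call. = FALSE)
  }
  structure(list(n_per_clade = as.integer(n_per_clade),
                 n_lots = as.integer(n_lots),
                 voucher_lots = as.integer(voucher_lots),
                 vouchers_per_lot = as.integer(vouchers_per_lot),
                 juvenile_fraction = juvenile_fraction,
                 juvenile_flip = juvenile_flip,
                 unknown_fraction = unknown_fraction,
                 characters = characters, seed = as.integer(seed)),
            class = "morph_scenario")
}

#' Default character panel for morphology simulation
#'
#' Named after structures routinely coded in palaemonid taxonomy; the
#' names are labels only, the states are opaque tokens.
#'
#' @return data frame usable as the `characters` argument of
#'   [morph_scenario()].
#' @export
default_morph_characters <- function() {
  data.frame(
    name = c("branchiostegal_tooth_position", "rostral_tooth_count",
             "appendix_masculina_size", "antennular_spine",
             "pereiopod_setation", "telson_spinules"),
    type = c("diagnostic", "diagnostic", "diagnostic", "overlapping",
             "overlapping", "ontogenetic"),
    constancy = c(1.0, 0.95, 0.90, NA, NA, 0.95),
    n_states = c(2L, 2L, 3L, 2L, 3L, 2L))
}

#' Simulate a clade-structured morphology matrix
#'
#' @param ms a [morph_scenario()].
#' @param clades character vector of the two clade labels (default
#'   `c("carteri", "ivonicus_yuna")`).
#' @return a `char_matrix` with attribute `truth`: the character table
#'   plus the modal state assigned to each clade.
#' @export
simulate_morphology <- function(ms = morph_scenario(),
                                clades = c("carteri", "ivonicus_yuna")) {
  stopifnot(inherits(ms, "morph_scenario"), length(clades) == 2L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(ms$seed)

  specs <- list()
  for (ci in 1:2) {
    cl <- clades[ci]
    n <- ms$n_per_clade
    lot <- paste0(cl, "_lot", sprintf("%02d", ((seq_len(n) - 1L) %% ms$n_lots) + 1L))
    id <- paste0(cl, "_", sprintf("%03d", seq_len(n)))
    lot_idx <- ((seq_len(n) - 1L) %% ms$n_lots) + 1L
    # vouchers: first vouchers_per_lot specimens (by round-robin order)
    # falling in the voucher lots
    rank_in_lot <- stats::ave(seq_len(n), lot_idx, FUN = seq_along)
    voucher <- lot_idx <= ms$voucher_lots & rank_in_lot <= ms$vouchers_per_lot
    stage <- ifelse(voucher, "adult",
                    ifelse(runif(n) < ms$juvenile_fraction, "juvenile",
                           "adult"))
    specs[[ci]] <- data.frame(id = id, lot = lot, clade = cl, stage = stage,
                              voucher = voucher)
  }
  specimens <- rbind(specs[[1L]], specs[[2L]])
  nspec <- nrow(specimens)

  chars <- ms$characters
  states <- matrix("unknown", nspec, nrow(chars),
                   dimnames = list(specimens$id, chars$name))
  truth_modal <- matrix(NA_character_, nrow(chars), 2L,
                        dimnames = list(chars$name, clades))
  for (k in seq_len(nrow(chars))) {
    alphabet <- paste0("s", seq_len(chars$n_states[k]))
    type <- chars$type[k]
    if (type == "overlapping") {
      probs <- c(0.55, rep(0.45 / (chars$n_states[k] - 1L),
                           chars$n_states[k] - 1L))
      states[, k] <- sample(alphabet, nspec, replace = TRUE, prob = probs)
      truth_modal[k, ] <- alphabet[1L]
    } else {
      cc <- chars$constancy[k]
      modal <- c(alphabet[1L], alphabet[2L])  # distinct per clade
      truth_modal[k, ] <- modal
      for (ci in 1:2) {
        rows <- which(specimens$clade == clades[ci])
        other <- setdiff(alphabet, modal[ci])
        draw <- ifelse(runif(length(rows)) < cc, modal[ci],
                       sample(other, length(rows), replace = TRUE))
        if (type == "ontogenetic") {
          juv <- specimens$stage[rows] == "juvenile"
          flip <- juv & runif(length(rows)) < ms$juvenile_flip
          draw[flip] <- modal[3L - ci]
        }
        states[rows, k] <- draw
      }
    }
  }
  if (ms$unknown_fraction > 0) {
    mask <- matrix(runif(length(states)) < ms$unknown_fraction,
                   nrow(states))
    states[mask] <- "unknown"
  }
  m <- character_matrix(specimens, states)
  attr(m, "truth") <- list(characters = chars, modal = truth_modal,
                           scenario = unclass(ms))
  m
}
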