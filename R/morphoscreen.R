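#' Construct a specimen-by-character morphology matrix
#'
#' Categorical state codes are opaque tokens; `"unknown"` marks an
#' unscored cell and is excluded from all constancy denominators.
#'
#' @param specimens data frame with columns `id`, `lot`, `clade`, `stage`
#'   (`"adult"`/`"juvenile"`) and `voucher` (logical: was the specimen
#'   sequenced for the molecular analysis).
#' @param states character matrix, one row per specimen (rownames = id),
#'   one column per character.
#' @return object of class `char_matrix`.
#' @export
character_matrix <- function(specimens, states) {
  req <- c("id", "lot", "clade", "stage", "voucher")
  stopifnot(is.data.frame(specimens), all(req %in% names(specimens)),
            is.matrix(states))
  if (any(duplicated(specimens$id))) stop("duplicate specimen id",
                                          call. = FALSE)
  if (nrow(states) != nrow(specimens)) {
    stop("states matrix and specimen table disagree in size", call. = FALSE)
  }
  rownames(states) <- specimens$id
  specimens$voucher <- as.logical(specimens$voucher)
  structure(list(specimens = specimens, states = states,
                 characters = colnames(states)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", nrow(x$specimens), " specimens x ",
      length(x$characters), " characters; clades: ",
      paste(sort(unique(x$specimens$clade)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a morphology matrix as CSV
#'
#' Layout: one row per specimen; columns `id, lot, clade, stage, voucher`
#' followed by one column per character. `voucher` is `yes`/`no`.
#'
#' @param path CSV path.
#' @return a `char_matrix` (for the reader); `path` invisibly (writer).
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("id", "lot", "clade", "stage", "voucher")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("morphology CSV lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  chars <- setdiff(names(df), req)
  specimens <- df[, req]
  specimens$voucher <- tolower(specimens$voucher) %in% c("yes", "true", "1")
  states <- as.matrix(df[, chars, drop = FALSE])
  character_matrix(specimens, states)
}

#' @rdname read_character_matrix
#' @param m a `char_matrix`.
#' @export
write_character_matrix <- function(m, path) {
  df <- cbind(m$specimens[, c("id", "lot", "clade", "stage")],
              voucher = ifelse(m$specimens$voucher, "yes", "no"),
              as.data.frame(m$states, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Specimen selector shared by all screening stages.
.screen_rows <- function(m, clade, adults_only, voucher = NULL, lots = NULL,
                         exclude_ids = NULL, lots_not = NULL) {
  s <- m$specimens
  keep <- s$clade == clade
  if (adults_only) keep <- keep & s$stage == "adult"
  if (!is.null(voucher)) keep <- keep & s$voucher == voucher
  if (!is.null(lots)) keep <- keep & s$lot %in% lots
  if (!is.null(lots_not)) keep <- keep & !(s$lot %in% lots_not)
  if (!is.null(exclude_ids)) keep <- keep & !(s$id %in% exclude_ids)
  s$id[keep]
}

# Modal state and counts among known states; NULL on a modal tie or when
# everything is unknown.
.modal <- function(states) {
  known <- states[states != "unknown"]
  if (!length(known)) return(NULL)
  tab <- sort(table(known), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) {
    return(list(tie = TRUE, n_known = length(known)))
  }
  list(tie = FALSE, state = names(tab)[1L], n_match = as.integer(tab[1L]),
       n_known = length(known))
}

#' Initial screen for candidate diagnostic characters
#'
#' Restricted to sequenced voucher specimens (the specimens placed in the
#' molecular tree), and by default to adults. For each character the modal
#' state per clade is found among known states; the character becomes a
#' candidate when the two modal states differ and the constancy (modal
#' count / known count) is strictly above the threshold in both clades.
#'
#' @param m a `char_matrix`.
#' @param clades the two clade labels to compare.
#' @param threshold constancy retention threshold (default 0.80, strict).
#' @param adults_only drop juveniles before screening (default `TRUE`).
#' @return data frame of class `candidate_set`: one row per candidate with
#'   the modal states, per-clade constancy and match/known counts;
#'   attribute `skipped` lists characters skipped (entirely unknown or
#'   modal tie in a clade) with the reason.
#' @export
initial_screen <- function(m, clades, threshold = 0.80, adults_only = TRUE) {
  stopifnot(inherits(m, "char_matrix"), length(clades) == 2L)
  absent <- setdiff(clades, unique(m$specimens$clade))
  if (length(absent)) stop("clade(s) absent from matrix: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  ids_a <- .screen_rows(m, clades[1L], adults_only, voucher = TRUE)
  ids_b <- .screen_rows(m, clades[2L], adults_only, voucher = TRUE)
  if (!length(ids_a) || !length(ids_b)) {
    stop("no voucher specimens for one or both clades", call. = FALSE)
  }
  rows <- list(); skipped <- list()
  for (ch in m$characters) {
    ma <- .modal(m$states[ids_a, ch])
    mb <- .modal(m$states[ids_b, ch])
    if (is.null(ma) || is.null(mb)) {
      warning("character '", ch, "' entirely unknown in a clade; skipped",
              call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        data.frame(character = ch, reason = "entirely unknown in a clade")
      next
    }
    if (ma$tie || mb$tie) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(character = ch, reason = "modal-state tie within a clade")
      next
    }
    const_a <- ma$n_match / ma$n_known
    const_b <- mb$n_match / mb$n_known
    if (ma$state != mb$state && const_a > threshold && const_b > threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        character = ch, state_a = ma$state, state_b = mb$state,
        const_a = const_a, const_b = const_b,
        match_a = ma$n_match, known_a = ma$n_known,
        match_b = mb$n_match, known_b = mb$n_known)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = character(0), state_a = character(0),
               state_b = character(0), const_a = numeric(0),
               const_b = numeric(0), match_a = integer(0),
               known_a = integer(0), match_b = integer(0),
               known_b = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            clades = clades, threshold = threshold,
            adults_only = adults_only,
            screen_ids = list(a = ids_a, b = ids_b),
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

# Seed-scoped shuffle-and-chunk of a specimen pool into blocks.
.make_blocks <- function(ids, block_size, seed) {
  if (!length(ids)) return(list())
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ids <- sample(ids)
  split(ids, ceiling(seq_along(ids) / block_size))
}

# Shared block-wise cumulative screening engine. `start` gives per-
# character starting counts (may be zeros for a fresh tally).
.run_blocks <- function(cands, m, blocks_a, blocks_b, threshold, stage_name,
                        start) {
  alive <- cands$character
  cum <- start
  n_blocks <- max(length(blocks_a), length(blocks_b))
  block_rows <- list(); decision_rows <- list()
  for (b in seq_len(n_blocks)) {
    ids_a <- if (b <= length(blocks_a)) blocks_a[[b]] else character(0)
    ids_b <- if (b <= length(blocks_b)) blocks_b[[b]] else character(0)
    block_rows[[b]] <- data.frame(stage = stage_name, block = b,
                                  n_a = length(ids_a), n_b = length(ids_b))
    for (ch in alive) {
      k <- match(ch, cands$character)
      sa <- m$states[ids_a, ch]
      sb <- m$states[ids_b, ch]
      cum$match_a[k] <- cum$match_a[k] + sum(sa == cands$state_a[k])
      cum$known_a[k] <- cum$known_a[k] + sum(sa != "unknown")
      cum$match_b[k] <- cum$match_b[k] + sum(sb == cands$state_b[k])
      cum$known_b[k] <- cum$known_b[k] + sum(sb != "unknown")
      ca <- if (cum$known_a[k] > 0L) cum$match_a[k] / cum$known_a[k] else NA
      cb <- if (cum$known_b[k] > 0L) cum$match_b[k] / cum$known_b[k] else NA
      discard <- (!is.na(ca) && ca < threshold) ||
                 (!is.na(cb) && cb < threshold)
      decision_rows[[length(decision_rows) + 1L]] <- data.frame(
        stage = stage_name, block = b, character = ch,
        scored_a = sum(sa != "unknown"), scored_b = sum(sb != "unknown"),
        cum_const_a = ca, cum_const_b = cb,
        decision = if (discard) "discarded" else "retained")
      if (discard) alive <- setdiff(alive, ch)
    }
  }
  list(alive = alive, cum = cum,
       blocks = do.call(rbind, block_rows),
       decisions = if (length(decision_rows)) do.call(rbind, decision_rows)
                   else NULL)
}

.empty_trace <- function() {
  list(blocks = NULL, decisions = NULL, notes = character(0))
}

#' Block-wise validation of candidate diagnostic characters
#'
#' The validation pool contains the remaining specimens from the same lots
#' as the molecular vouchers (the vouchers themselves are excluded).
#' Each clade's pool is shuffled with the given seed and split into
#' blocks; after each block the cumulative constancy (initial-screen
#' specimens plus all blocks so far) is recomputed per clade against the
#' candidate's fixed modal states, and a character is discarded at the
#' first block where either clade's cumulative constancy falls strictly
#' below the threshold. Discarded characters are not evaluated in later
#' blocks.
#'
#' @param cands a `candidate_set` from [initial_screen()].
#' @param m the `char_matrix`.
#' @param clades,threshold,adults_only as in [initial_screen()].
#' @param block_size specimens per clade per block (default 10).
#' @param seed integer controlling the block shuffle.
#' @return list with `survivors` (the updated `candidate_set`) and
#'   `trace` (list: `blocks` data frame of block sizes, `decisions` data
#'   frame of every per-character per-block decision, `notes`).
#' @export
block_validate <- function(cands, m, clades = attr(cands, "clades"),
                           block_size = 10L, threshold = 0.80, seed = 1L,
                           adults_only = attr(cands, "adults_only")) {
  stopifnot(inherits(cands, "candidate_set"), inherits(m, "char_matrix"))
  screen_ids <- attr(cands, "screen_ids")
  vouch_a <- .screen_rows(m, clades[1L], adults_only = FALSE, voucher = TRUE)
  vouch_b <- .screen_rows(m, clades[2L], adults_only = FALSE, voucher = TRUE)
  lots_a <- unique(m$specimens$lot[m$specimens$id %in% vouch_a])
  lots_b <- unique(m$specimens$lot[m$specimens$id %in% vouch_b])
  pool_a <- .screen_rows(m, clades[1L], adults_only, lots = lots_a,
                         exclude_ids = c(screen_ids$a, vouch_a))
  pool_b <- .screen_rows(m, clades[2L], adults_only, lots = lots_b,
                         exclude_ids = c(screen_ids$b, vouch_b))
  trace <- .empty_trace()
  if (!length(pool_a) && !length(pool_b)) {
    trace$notes <- "validation pool empty; candidates passed through unchanged"
    return(list(survivors = cands, trace = trace))
  }
  blocks_a <- .make_blocks(pool_a, block_size, seed)
  blocks_b <- .make_blocks(pool_b, block_size, seed + 1L)
  start <- cands[, c("match_a", "known_a", "match_b", "known_b")]
  res <- .run_blocks(cands, m, blocks_a, blocks_b, threshold, "validation",
                     start)
  surv <- cands[cands$character %in% res$alive, , drop = FALSE]
  keep <- match(surv$character, cands$character)
  surv$match_a <- res$cum$match_a[keep]; surv$known_a <- res$cum$known_a[keep]
  surv$match_b <- res$cum$match_b[keep]; surv$known_b <- res$cum$known_b[keep]
  surv$const_a <- surv$match_a / surv$known_a
  surv$const_b <- surv$match_b / surv$known_b
  attributes(surv) <- c(attributes(surv),
                        attributes(cands)[c("clades", "threshold",
                                            "adults_only", "screen_ids",
                                            "skipped")])
  class(surv) <- class(cands)
  trace$blocks <- res$blocks
  trace$decisions <- res$decisions
  list(survivors = surv, trace = trace)
}

#' Final check of surviving characters on hold-out lots
#'
#' The hold-out pool holds every specimen whose lot contains no molecular
#' voucher. The same block-wise cumulative rule as in [block_validate()]
#' is applied, but the tally starts fresh over the hold-out blocks so the
#' confirmation is independent of the data that selected the characters.
#'
#' @inheritParams block_validate
#' @param survivors a `candidate_set` (output of [block_validate()]).
#' @return object of class `diagnosis_set`: data frame of confirmed
#'   characters with screening and hold-out constancies; attribute
#'   `trace` as in [block_validate()].
#' @export
final_check <- function(survivors, m, clades = attr(survivors, "clades"),
                        block_size = 10L, threshold = 0.80, seed = 1L,
                        adults_only = attr(survivors, "adults_only")) {
  stopifnot(inherits(survivors, "candidate_set"), inherits(m, "char_matrix"))
  vouchers <- m$specimens$id[m$specimens$voucher]
  voucher_lots <- unique(m$specimens$lot[m$specimens$id %in% vouchers])
  pool_a <- .screen_rows(m, clades[1L], adults_only, lots_not = voucher_lots)
  pool_b <- .screen_rows(m, clades[2L], adults_only, lots_not = voucher_lots)
  trace <- .empty_trace()
  mk <- function(df, ho) {
    out <- data.frame(character = df$character, state_a = df$state_a,
                      state_b = df$state_b, screen_const_a = df$const_a,
                      screen_const_b = df$const_b,
                      holdout_const_a = ho$a, holdout_const_b = ho$b)
    structure(out, class = c("diagnosis_set", "data.frame"),
              clades = clades, trace = trace)
  }
  if (!length(pool_a) && !length(pool_b)) {
    warning("hold-out pool empty; survivors confirmed without final check",
            call. = FALSE)
    trace$notes <- "hold-out pool empty; survivors confirmed without final check"
    return(mk(survivors, list(a = rep(NA_real_, nrow(survivors)),
                              b = rep(NA_real_, nrow(survivors)))))
  }
  blocks_a <- .make_blocks(pool_a, block_size, seed)
  blocks_b <- .make_blocks(pool_b, block_size, seed + 1L)
  start <- data.frame(match_a = rep(0L, nrow(survivors)),
                      known_a = 0L, match_b = 0L, known_b = 0L)
  res <- .run_blocks(survivors, m, blocks_a, blocks_b, threshold, "final",
                     start)
  trace$blocks <- res$blocks
  trace$decisions <- res$decisions
  keep <- survivors$character %in% res$alive
  idx <- match(survivors$character[keep], survivors$character)
  ho_a <- ifelse(res$cum$known_a[idx] > 0,
                 res$cum$match_a[idx] / res$cum$known_a[idx], NA_real_)
  ho_b <- ifelse(res$cum$known_b[idx] > 0,
                 res$cum$match_b[idx] / res$cum$known_b[idx], NA_real_)
  mk(survivors[keep, , drop = FALSE], list(a = ho_a, b = ho_b))
}

#' Run the full optimized-comparison screen
#'
#' Convenience wrapper chaining [initial_screen()], [block_validate()] and
#' [final_check()] with one set of parameters and a combined trace.
#'
#' @inheritParams block_validate
#' @return list with `candidates`, `validated`, `confirmed`
#'   (a `diagnosis_set`) and `trace` (combined blocks/decisions/notes).
#' @export
screen_characters <- function(m, clades, threshold = 0.80, block_size = 10L,
                              seed = 1L, adults_only = TRUE) {
  cands <- initial_screen(m, clades, threshold, adults_only)
  val <- block_validate(cands, m, clades, block_size, threshold, seed,
                        adults_only)
  fin <- final_check(val$survivors, m, clades, block_size, threshold,
                     seed + 1000L, adults_only)
  ftrace <- attr(fin, "trace")
  trace <- list(blocks = rbind(val$trace$blocks, ftrace$blocks),
                decisions = rbind(val$trace$decisions, ftrace$decisions),
                notes = c(val$trace$notes, ftrace$notes),
                skipped = attr(cands, "skipped"))
  list(candidates = cands, validated = val$survivors, confirmed = fin,
       trace = trace)
}
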