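#' Build a run configuration
#'
#' Collects every tunable of the end-to-end analysis. Exactly one of
#' `rate` and `calibration` must be supplied for dating.
#'
#' @param fasta,metadata,morphology input paths (aligned FASTA, specimen
#'   table, morphology CSV).
#' @param deletion `"complete"` or `"pairwise"`.
#' @param model `"K2P"` or `"JC"` (both are always reported by the dating
#'   stage; this sets the headline model).
#' @param rate strict-clock rate, substitutions/site/Myr, or `NULL`.
#' @param calibration list with `d_cal`, `t_cal` and optionally `pair`,
#'   or `NULL`.
#' @param partition `"metadata"` (use the `lineage` column) or
#'   `"tree-cut"`.
#' @param cut_height divergence threshold for `"tree-cut"`.
#' @param groups the two group labels dated against each other.
#' @param threshold,block_size,adults_only morphology-screen parameters.
#' @param n_reps bootstrap replicates for the dating interval.
#' @param seed integer seed recorded in every output.
#' @param outdir output directory.
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(fasta = NULL, metadata = NULL, morphology = NULL,
                       deletion = "complete", model = "K2P", rate = 0.0083,
                       calibration = NULL, partition = "metadata",
                       cut_height = NULL,
                       groups = c("carteri", "ivonicus_yuna"),
                       threshold = 0.80, block_size = 10L,
                       adults_only = TRUE, n_reps = 1000L, seed = 1L,
                       outdir = ".") {
  deletion <- match.arg(deletion, c("complete", "pairwise"))
  model <- match.arg(model, c("K2P", "JC"))
  partition <- match.arg(partition, c("metadata", "tree-cut"))
  if (is.null(rate) == is.null(calibration)) {
    stop("config error: supply exactly one of 'rate' and 'calibration'",
         call. = FALSE)
  }
  if (partition == "tree-cut" && is.null(cut_height)) {
    stop("config error: partition 'tree-cut' needs a cut_height",
         call. = FALSE)
  }
  structure(list(fasta = fasta, metadata = metadata, morphology = morphology,
                 deletion = deletion, model = model, rate = rate,
                 calibration = calibration, partition = partition,
                 cut_height = cut_height, groups = groups,
                 threshold = threshold, block_size = as.integer(block_size),
                 adults_only = adults_only, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; `overrides` (a named
#' list, e.g. from command-line flags) take precedence.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

.cal_from_config <- function(config) {
  if (!is.null(config$rate)) rate_constant(config$rate)
  else calibrate_rate(config$calibration$d_cal, config$calibration$t_cal,
                      config$calibration$pair)
}

.out_path <- function(config, name) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$outdir, name)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

.stamp <- function(config, x) {
  c(x, list(seed = config$seed, package_version =
              as.character(utils::packageVersion("shrimpdelim"))))
}

.load_alignment <- function(config, filtered = TRUE) {
  if (is.null(config$fasta)) {
    stop("missing upstream file: no FASTA configured", call. = FALSE)
  }
  if (!file.exists(config$fasta)) {
    stop("missing upstream file: expected FASTA at ", config$fasta,
         call. = FALSE)
  }
  meta <- if (!is.null(config$metadata)) read_metadata(config$metadata)
  aln <- as_alignment(read_fasta(config$fasta), meta = meta)
  if (!filtered) return(aln)
  filter_columns(aln)
}

#' Pipeline stage: alignment column filter and site-pattern counts
#'
#' Reads the aligned FASTA, applies complete-deletion column filtering,
#' classifies the retained sites and writes `align_stats.json` plus a
#' plain-text summary.
#'
#' @param config a `run_config`.
#' @return (invisibly) list with the filter `report` and `sites`
#'   classification.
#' @export
run_align_stats <- function(config) {
  fc <- .load_alignment(config)
  sites <- classify_sites(fc$aln)
  out <- .stamp(config, list(
    filter = list(n_input_columns = fc$report$n_input_columns,
                  n_excluded = fc$report$n_excluded,
                  n_retained = fc$report$n_retained,
                  excluded_reasons = as.list(fc$report$excluded_reasons)),
    sites = unclass(sites)))
  .write_json(out, .out_path(config, "align_stats.json"))
  txt <- c(sprintf("%d columns in, %d excluded, %d retained",
                   fc$report$n_input_columns, fc$report$n_excluded,
                   fc$report$n_retained),
           utils::capture.output(print(sites)))
  writeLines(txt, .out_path(config, "align_stats.txt"))
  invisible(list(report = fc$report, sites = sites))
}

#' Pipeline stage: distance matrices
#'
#' Writes the uncorrected p-distance matrix under the configured deletion
#' mode (TSV and PHYLIP square) and the JC- and K2P-corrected matrices
#' (complete deletion).
#'
#' @param config a `run_config`.
#' @return (invisibly) list of the three matrices.
#' @export
run_distances <- function(config) {
  aln <- .load_alignment(config, filtered = FALSE)
  p <- p_distance(aln, deletion = config$deletion)
  fc <- filter_columns(aln)
  jc <- corrected_distance(fc$aln, "JC")
  k2p <- corrected_distance(fc$aln, "K2P")
  write_distance_matrix(p, .out_path(config, "p_distance.tsv"), "tsv")
  write_distance_matrix(p, .out_path(config, "p_distance.phy"), "phylip")
  write_distance_matrix(jc, .out_path(config, "dist_jc.tsv"), "tsv")
  write_distance_matrix(k2p, .out_path(config, "dist_k2p.tsv"), "tsv")
  invisible(list(p = p, jc = jc, k2p = k2p))
}

.partition_from_config <- function(config, aln, dm) {
  if (config$partition == "metadata") {
    partition_from_metadata(aln)
  } else {
    cut_tree(upgma(dm), config$cut_height)
  }
}

#' Pipeline stage: lineage partition and divergence summary
#'
#' Partitions the sequences (predefined metadata labels, or a UPGMA tree
#' cut at `cut_height`), writes the UPGMA tree as Newick and the
#' intra/inter divergence summary as TSV and JSON. Summaries are written
#' under both deletion modes; distances are stored as proportions, the
#' percent rendering in the text output multiplies by 100.
#'
#' @param config a `run_config`.
#' @return (invisibly) list with `partition` and the two summaries.
#' @export
run_lineages <- function(config) {
  aln <- .load_alignment(config, filtered = FALSE)
  dm0 <- p_distance(aln, deletion = config$deletion)
  part <- .partition_from_config(config, aln, dm0)
  write_newick(upgma(dm0), .out_path(config, "upgma.nwk"))
  sums <- list()
  for (del in c("complete", "pairwise")) {
    dm <- if (del == config$deletion) dm0 else p_distance(aln, deletion = del)
    sums[[del]] <- summarize_distances(dm, part)
    utils::write.table(sums[[del]],
                       .out_path(config, paste0("lineage_summary_", del,
                                                ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_json(.stamp(config, list(
    partition = as.list(unclass(part)[seq_along(part)]),
    source = attr(part, "source"),
    summary = sums)), .out_path(config, "lineages.json"))
  invisible(list(partition = part, summary = sums))
}

#' Pipeline stage: strict-clock divergence dating
#'
#' Dates the split between the two configured groups under both JC and
#' K2P corrections, with a site-bootstrap 95% interval for each, and
#' writes `dating.json` plus a readable report.
#'
#' @param config a `run_config`.
#' @return (invisibly) named list of `time_estimate`s (`JC`, `K2P`).
#' @export
run_dating <- function(config) {
  fc <- .load_alignment(config)
  cal <- .cal_from_config(config)
  dm <- p_distance(fc$aln)
  part <- .partition_from_config(config, fc$aln, dm)
  est <- lapply(c(JC = "JC", K2P = "K2P"), function(mdl) {
    bootstrap_time(fc$aln, part, config$groups, cal, model = mdl,
                   n_reps = config$n_reps, seed = config$seed)
  })
  .write_json(.stamp(config, list(
    rate = cal$rate,
    calibration = cal[c("d_cal", "t_cal", "pair")],
    groups = config$groups,
    interval_construct = "site-bootstrap (not a Bayesian credible interval)",
    estimates = lapply(est, unclass))), .out_path(config, "dating.json"))
  txt <- c(sprintf("strict-clock rate: %g subs/site/Myr", cal$rate),
           sprintf("groups: %s vs %s", config$groups[1L], config$groups[2L]),
           vapply(names(est), function(m) {
             e <- est[[m]]
             sprintf("%s: t = %.2f Ma, site-bootstrap 95%% (%d reps): %.2f-%.2f Ma",
                     m, e$t_hat, e$n_reps, e$lo, e$hi)
           }, character(1L)))
  writeLines(txt, .out_path(config, "dating.txt"))
  invisible(est)
}

#' Pipeline stage: diagnostic-character screen
#'
#' Runs the full optimized-comparison screen on the configured morphology
#' CSV and writes the confirmed diagnoses and the complete audit trace as
#' JSON plus a readable audit table.
#'
#' @param config a `run_config`; `morphology` and `groups` must be set.
#' @return (invisibly) the [screen_characters()] result.
#' @export
run_screen <- function(config) {
  if (is.null(config$morphology)) {
    stop("missing upstream file: no morphology CSV configured", call. = FALSE)
  }
  if (!file.exists(config$morphology)) {
    stop("missing upstream file: expected morphology CSV at ",
         config$morphology, call. = FALSE)
  }
  m <- read_character_matrix(config$morphology)
  res <- screen_characters(m, config$groups, threshold = config$threshold,
                           block_size = config$block_size,
                           seed = config$seed,
                           adults_only = config$adults_only)
  .write_json(.stamp(config, list(
    candidates = res$candidates,
    confirmed = as.data.frame(res$confirmed),
    trace = res$trace)), .out_path(config, "screen.json"))
  txt <- utils::capture.output({
    cat("candidates after initial screen:",
        paste(res$candidates$character, collapse = ", "), "\n")
    cat("confirmed diagnostic characters:\n")
    print(as.data.frame(res$confirmed), row.names = FALSE)
    if (!is.null(res$trace$decisions)) {
      cat("\naudit trail:\n")
      print(res$trace$decisions, row.names = FALSE)
    }
  })
  writeLines(txt, .out_path(config, "screen_audit.txt"))
  invisible(res)
}

#' Pipeline stage: write a synthetic dataset
#'
#' Simulates the default (or a supplied) sequence scenario and morphology
#' scenario and writes `synthetic_16s.fasta`, `synthetic_metadata.tsv`,
#' `synthetic_morphology.csv` and `synthetic_truth.json` into the output
#' directory. File names carry the `synthetic_` prefix because these are
#' simulated stand-ins, not observed data.
#'
#' @param config a `run_config` (only `outdir` and `seed` are used).
#' @param cfg optional [scenario_config()]; defaults to the study-like
#'   scenario with the config seed.
#' @param ms optional [morph_scenario()]; same default behaviour.
#' @return (invisibly) list with the simulation outputs and file paths.
#' @export
run_simulate <- function(config, cfg = NULL, ms = NULL) {
  if (is.null(cfg)) cfg <- scenario_config(seed = config$seed)
  if (is.null(ms)) ms <- morph_scenario(seed = config$seed)
  sim <- simulate_alignment(cfg)
  morph <- simulate_morphology(ms)
  fa <- .out_path(config, "synthetic_16s.fasta")
  write_fasta(sim$aln, fa)
  mdpath <- .out_path(config, "synthetic_metadata.tsv")
  utils::write.table(sim$metadata, mdpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mo <- .out_path(config, "synthetic_morphology.csv")
  write_character_matrix(morph, mo)
  truth <- sim$truth
  truth$morphology <- attr(morph, "truth")
  .write_json(.stamp(config, truth),
              .out_path(config, "synthetic_truth.json"))
  invisible(list(sim = sim, morph = morph,
                 paths = list(fasta = fa, metadata = mdpath,
                              morphology = mo)))
}

#' Run the full pipeline
#'
#' Chains simulate (optional) -> align stats -> distances -> lineages ->
#' dating -> screen and writes a run manifest with input hashes, the
#' seed, the configuration and the package version, so a rerun with the
#' same config and seed reproduces every output byte-identically.
#'
#' @param config a `run_config`.
#' @param simulate when `TRUE`, first writes the synthetic dataset into
#'   `outdir` and points the config at it.
#' @return (invisibly) list of stage results.
#' @export
run_all <- function(config, simulate = is.null(config$fasta)) {
  if (simulate) {
    simres <- run_simulate(config)
    config$fasta <- simres$paths$fasta
    config$metadata <- simres$paths$metadata
    config$morphology <- simres$paths$morphology
  }
  stats <- run_align_stats(config)
  dists <- run_distances(config)
  lins <- run_lineages(config)
  dating <- run_dating(config)
  screen <- if (!is.null(config$morphology)) run_screen(config)
  inputs <- c(config$fasta, config$metadata, config$morphology)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null", digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   inputs = as.list(tools::md5sum(inputs)),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("shrimpdelim")))
  unlink(tmp)
  .write_json(manifest, .out_path(config, "manifest.json"))
  invisible(list(align_stats = stats, distances = dists, lineages = lins,
                 dating = dating, screen = screen))
}
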