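#' Assemble a validated pipeline configuration
#'
#' Configuration merges three layers with increasing precedence: package
#' defaults, a YAML config file, and programmatic/CLI overrides. Unknown
#' keys are rejected so typos fail at load time rather than silently
#' falling back to defaults.
#'
#' @param config named list of overrides.
#' @param config_file optional YAML file.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), config_file = NULL) {
  defaults <- list(
    out_dir = ".",
    # inputs
    gene_stats = NULL, similarity = NULL, family = NULL,
    tree_a = NULL, tree_b = NULL, clade_map = NULL,
    # synthetic generation
    preset = "headline", n_nem = 300L, n_nonnem = 3000L, sim_lag = 40,
    sim_root_age = 740, sim_n_taxa = 8L,
    # matching scheme
    alpha = 0.95, x_period = 3L, band_low = 0.95, band_high = 1.05,
    initial_free_draws = 5L, max_tries_per_slot = 10000L,
    # quantification
    threshold = 0.5,
    thresholds = c(0.9, 0.5, 0.1, 0.05, 0.01, 1e-3, 1e-4, 1e-5),
    n_perm = 200L,
    # calibration
    alpha_grid = c(0.90, 0.95, 1.0), x_grid = c(2L, 3L, 5L), n_cal = 200L,
    # enrichment / GO / classification
    levels = c(0.05, 0.01, 0.001), go_min_genes = 20L, go_top_k = 10L,
    evalue_cutoff = 1e-5,
    seed = 1L, verbosity = 1L)
  file_cfg <- if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop(sprintf("config file not found: %s", config_file), call. = FALSE)
    yaml::read_yaml(config_file) %||% list()
  } else list()
  for (layer in list(file_cfg, config)) {
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    defaults <- modifyList(defaults, layer, keep.null = TRUE)
  }
  structure(defaults, class = "pipeline_config")
}

plog <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1) > 0) message("[nemadapt] ", ...)
}

# temp-then-rename so partial outputs never appear under final names
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move output into place: %s", path),
         call. = FALSE)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, paste, "", collapse = ";") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  write_atomic(path, function(tmp)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE))
}

scheme_from_config <- function(cfg) {
  matching_scheme(alpha = cfg$alpha, x_period = cfg$x_period,
                  band_low = cfg$band_low, band_high = cfg$band_high,
                  initial_free_draws = cfg$initial_free_draws,
                  max_tries_per_slot = cfg$max_tries_per_slot)
}

need_input <- function(cfg, key) {
  v <- cfg[[key]]
  if (is.null(v))
    stop(sprintf("config error: '%s' input path is required", key),
         call. = FALSE)
  if (!file.exists(v))
    stop(sprintf("config error: '%s' file not found: %s", key, v),
         call. = FALSE)
  v
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions. Every stage writes its
#' declared outputs atomically into `out_dir`, logs parameters to standard
#' error, and returns its main result invisibly. The `demo` subcommand
#' runs simulate, classify, curve, go-excess, enrich and lag end-to-end on
#' synthetic data and bundles a machine-readable `report.json` (no
#' timestamps, so same-seed runs are byte-identical).
#'
#' @param subcommand one of `simulate`, `classify`, `setops`, `quantify`,
#'   `curve`, `calibrate`, `go-excess`, `enrich`, `lag`, `demo`.
#' @param config named list of overrides (see [pipeline_config()]).
#' @param config_file optional YAML config file.
#' @return the stage's main result, invisibly.
#' @export
run_pipeline <- function(subcommand, config = list(), config_file = NULL) {
  sub <- match.arg(subcommand,
                   c("simulate", "classify", "setops", "quantify", "curve",
                     "calibrate", "go-excess", "enrich", "lag", "demo"))
  cfg <- pipeline_config(config, config_file)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  res <- switch(sub,
    simulate = {
      plog(cfg, sprintf("simulate: preset=%s n_nem=%d n_nonnem=%d seed=%d",
                        cfg$preset, cfg$n_nem, cfg$n_nonnem, cfg$seed))
      sc <- scenario_preset(cfg$preset, n_nem = cfg$n_nem,
                            n_nonnem = cfg$n_nonnem, seed = cfg$seed)
      recs <- generate_gene_stats(sc)
      sim <- generate_similarity_table(recs, seed = sub_seed(cfg$seed, 1))
      trees <- generate_paired_chronograms(cfg$sim_n_taxa, cfg$sim_lag,
                                           cfg$sim_root_age,
                                           seed = sub_seed(cfg$seed, 2))
      write_atomic(out("gene_stats.tsv"),
                   function(t) write_gene_stats(recs, t))
      write_tsv_atomic(sim, out("similarity.tsv"))
      write_atomic(out("nem_tree.nwk"),
                   function(t) write_dated_newick(trees$nem_tree, t))
      write_atomic(out("org_tree.nwk"),
                   function(t) write_dated_newick(trees$org_tree, t))
      write_tsv_atomic(trees$clade_map, out("clade_map.tsv"))
      list(records = recs, similarity = sim, trees = trees)
    },
    classify = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      sim_df <- read.delim(need_input(cfg, "similarity"))
      plog(cfg, sprintf("classify: cutoff=%g over %d genes",
                        cfg$evalue_cutoff, nrow(recs)))
      recs <- classify_records(recs, sim_df, cfg$evalue_cutoff)
      write_atomic(out("gene_stats_classified.tsv"),
                   function(t) write_gene_stats(recs, t))
      recs
    },
    setops = {
      fam <- read_ortholog_family(need_input(cfg, "family"))
      plog(cfg, sprintf("setops: %d species", length(fam)))
      prof <- intersection_profile(fam)
      core <- core_set(fam)
      write_tsv_atomic(
        data.frame(subset = names(prof$exclusive),
                   exclusive_count = as.integer(prof$exclusive)),
        out("intersection_profile.tsv"))
      write_json_atomic(list(core_set = core,
                             union_size = prof$union_size,
                             exclusive = as.list(prof$exclusive),
                             pairwise = prof$pairwise),
                        out("setops.json"))
      list(profile = prof, core = core)
    },
    quantify = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      plog(cfg, sprintf("quantify: threshold=%g n_perm=%d seed=%d",
                        cfg$threshold, cfg$n_perm, cfg$seed))
      est <- quantify_excess(recs, cfg$threshold, scheme_from_config(cfg),
                             cfg$n_perm, cfg$seed)
      write_tsv_atomic(est, out("excess_estimate.tsv"))
      est
    },
    curve = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      plog(cfg, sprintf("curve: %d thresholds, n_perm=%d",
                        length(cfg$thresholds), cfg$n_perm))
      cv <- excess_curve(recs, cfg$thresholds, scheme_from_config(cfg),
                         cfg$n_perm, cfg$seed)
      write_tsv_atomic(cv, out("excess_curve.tsv"))
      cv
    },
    calibrate = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      plog(cfg, sprintf("calibrate: %dx%d grid, n_cal=%d",
                        length(cfg$alpha_grid), length(cfg$x_grid),
                        cfg$n_cal))
      cal <- calibrate_matching(recs, cfg$alpha_grid, cfg$x_grid,
                                cfg$n_cal, cfg$seed)
      write_tsv_atomic(cal$grid, out("calibration_grid.tsv"))
      write_json_atomic(list(chosen = as.list(cal$chosen),
                             fallback = cal$fallback),
                        out("calibration_chosen.json"))
      cal
    },
    `go-excess` = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      plog(cfg, sprintf("go-excess: threshold=%g min_genes=%d top_k=%d",
                        cfg$threshold, cfg$go_min_genes, cfg$go_top_k))
      ge <- go_excess(recs, cfg$threshold, scheme_from_config(cfg),
                      cfg$n_perm, cfg$go_min_genes, cfg$go_top_k, cfg$seed)
      write_tsv_atomic(ge, out("go_excess.tsv"))
      ge
    },
    enrich = {
      recs <- read_gene_stats(need_input(cfg, "gene_stats"))
      plog(cfg, sprintf("enrich: levels %s",
                        paste(cfg$levels, collapse = ", ")))
      en <- enrichment_test(recs, cfg$levels)
      write_tsv_atomic(en, out("enrichment.tsv"))
      en
    },
    lag = {
      ta <- read_dated_newick(need_input(cfg, "tree_a"))
      tb <- read_dated_newick(need_input(cfg, "tree_b"))
      cm <- read.delim(need_input(cfg, "clade_map"),
                       colClasses = "character")
      plog(cfg, sprintf("lag: %d mapped clades", nrow(cm)))
      lr <- compute_lag(ta, tb, cm)
      write_tsv_atomic(lr$per_clade, out("lag_per_clade.tsv"))
      write_json_atomic(list(per_clade = lr$per_clade,
                             summary = as.list(lr$summary)),
                        out("lag_summary.json"))
      lr
    },
    demo = run_demo(cfg))
  invisible(res)
}

#' End-to-end demo on synthetic data
#'
#' Runs simulate, classify, excess curve, GO-stratified excess, Fisher
#' enrichment and chronogram lag on one synthetic dataset and writes all
#' stage outputs plus a `report.json` embedding every parameter needed to
#' regenerate it. Deterministic given the seed.
#'
#' @param cfg a [pipeline_config()] (or a named list of overrides).
#' @return the report payload, invisibly.
#' @export
run_demo <- function(cfg = list()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  plog(cfg, sprintf("demo: seed=%d out_dir=%s", cfg$seed, cfg$out_dir))
  sim <- run_pipeline("simulate", unclass(cfg))
  recs_true <- sim$records
  recs <- classify_records(recs_true, sim$similarity, cfg$evalue_cutoff)
  accuracy <- mean(recs$nem_status == recs_true$nem_status)
  plog(cfg, sprintf("demo: classification accuracy %.3f vs ground truth",
                    accuracy))
  scheme <- scheme_from_config(cfg)
  cv <- excess_curve(recs, cfg$thresholds, scheme, cfg$n_perm,
                     sub_seed(cfg$seed, 10))
  ge <- go_excess(recs, cfg$threshold, scheme, cfg$n_perm,
                  cfg$go_min_genes, cfg$go_top_k, sub_seed(cfg$seed, 11))
  en <- enrichment_test(recs, cfg$levels)
  lr <- compute_lag(sim$trees$nem_tree, sim$trees$org_tree,
                    sim$trees$clade_map)
  out <- function(f) file.path(cfg$out_dir, f)
  write_tsv_atomic(cv, out("excess_curve.tsv"))
  write_tsv_atomic(ge, out("go_excess.tsv"))
  write_tsv_atomic(en, out("enrichment.tsv"))
  write_tsv_atomic(lr$per_clade, out("lag_per_clade.tsv"))
  report <- list(
    parameters = unclass(cfg),
    classification_accuracy = accuracy,
    excess_curve = cv,
    go_excess = ge,
    enrichment = en,
    lag = list(per_clade = lr$per_clade, summary = as.list(lr$summary)))
  write_json_atomic(report, out("report.json"))
  plog(cfg, "demo: wrote report.json")
  invisible(report)
}
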