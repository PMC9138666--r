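#' Assemble and validate a pipeline configuration
#'
#' A single configuration object drives [run_pipeline()]: either a path to
#' a protein-group table plus design, or `simulate = TRUE` with generator
#' settings; all processing thresholds; and a mandatory seed (imputation
#' and simulation are stochastic). May be built from a YAML file.
#'
#' @param config Named list of settings, or a path to a YAML file holding
#'   one. Recognised fields and defaults: `simulate` (FALSE), `sim`
#'   (list passed to [sim_config()]), `table`, `design`, `control`
#'   ("control"), `annotation` (optional TSV path), `min_peptides` (2),
#'   `min_runs` (2), `q_low` (0.25), `q_high` (0.75), `impute_method`
#'   ("probabilistic_minimum"), `spread_factor` (0.25), `downshift` (1.8),
#'   `downshift_width` (0.3), `gate_alpha` (0.05), `p_threshold` (0.05),
#'   `fc_cutoff` (2), `p_adjust` ("none"), `seed` (required).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(simulate = FALSE, sim = list(), table = NULL,
                   design = NULL, control = "control", annotation = NULL,
                   min_peptides = 2L, min_runs = 2L,
                   q_low = 0.25, q_high = 0.75,
                   impute_method = "probabilistic_minimum",
                   spread_factor = 0.25, downshift = 1.8,
                   downshift_width = 0.3,
                   gate_alpha = 0.05, p_threshold = 0.05, fc_cutoff = 2,
                   p_adjust = "none", seed = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("configuration error: seed is required")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$fc_cutoff <= 1) {
    stop("configuration error: fc_cutoff must be > 1")
  }
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1 ||
      cfg$gate_alpha < 0 || cfg$gate_alpha > 1) {
    stop("configuration error: p_threshold/gate_alpha out of range")
  }
  if (cfg$min_peptides < 1L) {
    stop("configuration error: min_peptides must be >= 1")
  }
  if (!cfg$simulate && (is.null(cfg$table) || is.null(cfg$design))) {
    stop("configuration error: table and design paths required unless ",
         "simulate = TRUE")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full differential-abundance pipeline
#'
#' Chains the stages end to end: obtain a quantification table (read or
#' simulate), filter by peptide evidence and by quantified runs, log2
#' transform, normalize by median then by distribution width, impute
#' left-censored missing values, run the gated comparisons against control,
#' and write results, set intersections, figures and a provenance record
#' into `out_dir`. Re-running with the same configuration and inputs
#' reproduces byte-identical result tables.
#'
#' @param config A [pipeline_config()], a named list, or a YAML path.
#' @param out_dir Output directory (created if absent).
#' @param figures Write volcano plots (and heat maps when an annotation is
#'   supplied)? Default `TRUE`.
#' @param quiet Suppress per-stage messages? Default `FALSE`.
#' @return Invisibly, a list with `stats`, `sets`, `counts`, `norm`,
#'   `table` (post-filter), `truth` (when simulated) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config, out_dir, figures = TRUE, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  checksums <- list()

  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- simulate_lfq(do.call(sim_config,
                                c(cfg$sim, list(seed = cfg$seed))))
    table <- sim$table
    truth <- sim$truth
    truth_file <- file.path(out_dir, "truth.tsv")
    write_truth(truth, truth_file)
    files <- c(files, truth_file)
    say("simulate: ", nrow(table$proteins), " proteins x ",
        nrow(table$design), " runs")
  } else {
    design <- read_design(cfg$design, control = cfg$control)
    table <- read_protein_groups(cfg$table, design)
    checksums$table <- unname(tools::md5sum(cfg$table))
    checksums$design <- unname(tools::md5sum(cfg$design))
    say("read: ", nrow(table$proteins), " proteins x ",
        nrow(table$design), " runs")
  }

  n0 <- nrow(table$proteins)
  table <- filter_by_peptides(table, cfg$min_peptides)
  say("peptide filter (>= ", cfg$min_peptides, "): ", n0, " -> ",
      nrow(table$proteins), " proteins")
  n1 <- nrow(table$proteins)
  table <- filter_by_quantified(table, cfg$min_runs)
  say("quantified-run filter (>= ", cfg$min_runs, "): ", n1, " -> ",
      nrow(table$proteins), " proteins")

  norm <- log2_transform(table)
  norm <- normalize_median(norm)
  norm <- normalize_width(norm, q_low = cfg$q_low, q_high = cfg$q_high)
  norm <- impute_probabilistic_minimum(
    norm, seed = cfg$seed, method = cfg$impute_method,
    spread_factor = cfg$spread_factor, downshift = cfg$downshift,
    downshift_width = cfg$downshift_width)
  say("preprocess: ", sum(norm$imputed_mask), " cells imputed")

  stats <- run_comparisons(norm, gate_alpha = cfg$gate_alpha,
                           p_threshold = cfg$p_threshold,
                           fc_cutoff = cfg$fc_cutoff,
                           p_adjust = cfg$p_adjust)
  counts <- dap_counts(stats)
  say("dap: ", paste(counts$treatment, counts$total, sep = "=",
                     collapse = ", "), " DAPs")
  stats_file <- file.path(out_dir, "stats.tsv")
  write_results(stats, stats_file)
  files <- c(files, stats_file)

  sets <- shared_sets(stats)
  sets_file <- file.path(out_dir, "sets.tsv")
  write.table(sets$intersections, sets_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, sets_file)

  annotation <- NULL
  if (!is.null(cfg$annotation)) {
    annotation <- read_annotation(cfg$annotation)
    checksums$annotation <- unname(tools::md5sum(cfg$annotation))
    summary_file <- file.path(out_dir, "category_summary.tsv")
    write.table(category_summary(stats, annotation), summary_file,
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, summary_file)
  }

  if (isTRUE(figures)) {
    for (trt in treatments(table$design)) {
      stem <- file.path(out_dir, paste0("volcano_", trt))
      volcano(stats, treatment = trt, p_threshold = cfg$p_threshold,
              fc_cutoff = cfg$fc_cutoff, path = stem)
      files <- c(files, paste0(stem, c(".png", ".tsv")))
    }
    if (!is.null(annotation)) {
      for (categ in setdiff(unique(annotation$category), "unannotated")) {
        if (!any(annotation$accession[annotation$category == categ] %in%
                 norm$proteins$accession)) next
        stem <- file.path(out_dir,
                          paste0("heatmap_", gsub("\\W+", "_", categ)))
        heatmap_abundance(norm, annotation, categ, stats, path = stem)
        files <- c(files, paste0(stem, c(".png", ".tsv")))
      }
    }
  }

  prov <- list(
    package = "lfqdap",
    version = as.character(utils::packageVersion("lfqdap")),
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1L))],
    input_checksums = checksums,
    stages = vapply(norm$provenance, `[[`, "", "step"),
    n_proteins = nrow(table$proteins),
    dap_counts = setNames(as.list(counts$total), counts$treatment))
  prov_file <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(prov, prov_file)
  files <- c(files, prov_file)

  invisible(list(stats = stats, sets = sets, counts = counts, norm = norm,
                 table = table, truth = truth, files = files))
}
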