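#' Configuration for the synthetic LFQ data generator
#'
#' Defaults emulate the pooled-plasma design the pipeline targets: one
#' control and three treatment groups, each a pooled sample injected in
#' triplicate (12 runs), around 160 plasma proteins with log-normal LFQ
#' intensities, per-run location/scale biases, a minority of proteins with
#' treatment effects that are mostly down-regulation with magnitudes up to
#' |log2FC| = 10, intensity-dependent (left-censored) missingness, and a
#' small fraction of single-peptide identifications.
#'
#' @param n_proteins Number of proteins (default 160).
#' @param groups Group labels, control first (default
#'   `c("control","T1","T2","T3")`).
#' @param reps_per_group Technical replicates per group (default 3).
#' @param baseline_mean,baseline_sd Distribution of per-protein baseline
#'   log2 intensity (defaults 25 and 2).
#' @param tech_sd Technical replicate SD on the log2 scale (default 0.25).
#' @param dap_fraction Probability that a protein carries a treatment effect
#'   (default 0.2).
#' @param effect_range Bounds of |log2FC| for affected proteins (default
#'   `c(1.5, 10)`).
#' @param down_probability Probability an effect is negative (default 0.8).
#' @param run_shift_sd SD of the per-run additive location bias (default
#'   0.5).
#' @param run_scale_range Bounds of the per-run multiplicative spread bias
#'   (default `c(0.8, 1.25)`).
#' @param censor_quantile Quantile of the biased log2 values at which the
#'   soft censoring threshold sits (default 0.05).
#' @param censor_softness Logistic scale of the censoring probability
#'   (default 0.5); smaller values approach a hard cut.
#' @param single_peptide_fraction Fraction of proteins forced to a single
#'   peptide (default 0.07).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 160L,
                       groups = c("control", "T1", "T2", "T3"),
                       reps_per_group = 3L,
                       baseline_mean = 25, baseline_sd = 2,
                       tech_sd = 0.25,
                       dap_fraction = 0.2,
                       effect_range = c(1.5, 10),
                       down_probability = 0.8,
                       run_shift_sd = 0.5,
                       run_scale_range = c(0.8, 1.25),
                       censor_quantile = 0.05,
                       censor_softness = 0.5,
                       single_peptide_fraction = 0.07,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), groups = groups,
              reps_per_group = as.integer(reps_per_group),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              tech_sd = tech_sd, dap_fraction = dap_fraction,
              effect_range = effect_range,
              down_probability = down_probability,
              run_shift_sd = run_shift_sd,
              run_scale_range = run_scale_range,
              censor_quantile = censor_quantile,
              censor_softness = censor_softness,
              single_peptide_fraction = single_peptide_fraction,
              seed = as.integer(seed))
  probs <- c(dap_fraction = dap_fraction,
             down_probability = down_probability,
             censor_quantile = censor_quantile,
             single_peptide_fraction = single_peptide_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         " must lie in [0, 1]")
  }
  if (cfg$n_proteins < 1L || length(groups) < 2L) {
    stop("configuration error: need >= 1 protein and >= 2 groups")
  }
  if (cfg$reps_per_group < 2L) {
    stop("configuration error: reps_per_group must be >= 2")
  }
  if (!(effect_range[1L] > 0 && effect_range[1L] < effect_range[2L])) {
    stop("configuration error: effect_range must be 0 < low < high")
  }
  if (tech_sd <= 0 || censor_softness <= 0) {
    stop("configuration error: tech_sd and censor_softness must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic quantification table with known ground truth
#'
#' Simulates the generative model described in [sim_config()]. Per protein
#' `i` a baseline `b_i ~ N(baseline_mean, baseline_sd^2)` is drawn; an
#' affected protein (probability `dap_fraction`) receives a direction (down
#' with probability `down_probability`, shared across treatments so that
#' cross-treatment DAP sets overlap, as they do in real exposure series)
#' and, per treatment, a magnitude uniform in `effect_range`. The true log2
#' level of protein `i` in group `g` is `b_i + delta_ig` (zero delta for
#' control and unaffected proteins). Each run `r` has an additive location
#' bias `shift_r ~ N(0, run_shift_sd^2)` and a spread bias `scale_r ~
#' U(run_scale_range)`; a replicate value is `x = level + N(0, tech_sd^2)`
#' biased to `shift_r + scale_r * (x - baseline_mean) + baseline_mean`, and
#' the stored intensity is `2^x`. Left-censoring makes a cell missing with
#' probability `plogis((tau - x) / censor_softness)` where `tau` is the
#' `censor_quantile` quantile of all biased values. Peptide counts are
#' `1 + Poisson(5)`, with a `single_peptide_fraction` subset forced to 1.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (a [quant_table()]) and `truth` (class
#'   `synthetic_truth`): `true_log2fc` and `is_affected` matrices (proteins
#'   x treatments), `run_shift` and `run_scale` per run, and
#'   `censor_threshold` on the log2 scale.
#' @export
simulate_lfq <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  groups <- config$groups
  ctrl <- groups[1L]
  trts <- groups[-1L]
  reps <- config$reps_per_group
  runs <- as.vector(vapply(groups, function(g) paste(g, seq_len(reps),
                                                     sep = "_"),
                           character(reps)))
  design <- sample_design(run = runs,
                          group = rep(groups, each = reps),
                          replicate = rep(seq_len(reps), length(groups)),
                          control = ctrl)
  acc <- sprintf("SYN%04d", seq_len(n))
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  affected <- runif(n) < config$dap_fraction
  sign_of <- ifelse(runif(n) < config$down_probability, -1, 1)
  true_lfc <- matrix(0, n, length(trts), dimnames = list(acc, trts))
  for (g in seq_along(trts)) {
    mag <- runif(n, config$effect_range[1L], config$effect_range[2L])
    true_lfc[affected, g] <- (sign_of * mag)[affected]
  }
  run_shift <- rnorm(length(runs), 0, config$run_shift_sd)
  run_scale <- runif(length(runs), config$run_scale_range[1L],
                     config$run_scale_range[2L])
  names(run_shift) <- names(run_scale) <- runs
  x <- matrix(NA_real_, n, length(runs), dimnames = list(acc, runs))
  for (r in seq_along(runs)) {
    g <- design$group[r]
    level <- baseline + if (g == ctrl) 0 else true_lfc[, match(g, trts)]
    raw <- level + rnorm(n, 0, config$tech_sd)
    x[, r] <- run_shift[r] + run_scale[r] * (raw - config$baseline_mean) +
      config$baseline_mean
  }
  if (config$censor_quantile > 0) {
    tau <- quantile(x, config$censor_quantile, names = FALSE)
    censored <- matrix(runif(length(x)) <
                         plogis((tau - x) / config$censor_softness),
                       n, length(runs))
  } else {                      # censor_quantile 0 switches censoring off
    tau <- -Inf
    censored <- matrix(FALSE, n, length(runs))
  }
  intensities <- 2^x
  intensities[censored] <- NA_real_
  peptide_count <- 1L + rpois(n, 5)
  single <- sample.int(n, size = round(config$single_peptide_fraction * n))
  peptide_count[single] <- 1L
  table <- quant_table(
    proteins = data.frame(accession = acc,
                          name = paste0("synthetic protein ", seq_len(n)),
                          peptide_count = peptide_count,
                          stringsAsFactors = FALSE),
    intensities = intensities, design = design)
  truth <- structure(list(true_log2fc = true_lfc,
                          is_affected = matrix(affected, n, length(trts),
                                               dimnames = list(acc, trts)),
                          run_shift = run_shift, run_scale = run_scale,
                          censor_threshold = tau,
                          baseline = setNames(baseline, acc),
                          config = config),
                     class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' Confusion counts of DAP calling against simulation ground truth
#'
#' Scores a result table against the generator's truth, per treatment. An
#' affected protein counts as a true positive only when it is called in the
#' correct direction; an affected protein called `ns` or in the wrong
#' direction is a false negative. Unaffected proteins called `up` or `down`
#' are false positives. The four counts partition all tested proteins.
#'
#' @param stats A result table from [run_comparisons()].
#' @param truth A `synthetic_truth` from [simulate_lfq()]. Proteins dropped
#'   by upstream filters are scored only if present in `stats`.
#' @return `data.frame` with one row per treatment: `tp`, `fp`, `tn`, `fn`.
#' @export
truth_confusion <- function(stats, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  trts <- colnames(truth$true_log2fc)
  if (!all(unique(stats$treatment) %in% trts)) {
    stop("treatments in stats do not match truth")
  }
  if (!all(stats$accession %in% rownames(truth$true_log2fc))) {
    stop("accessions in stats do not match truth")
  }
  out <- lapply(intersect(trts, unique(stats$treatment)), function(trt) {
    s <- stats[stats$treatment == trt, ]
    tl <- truth$true_log2fc[s$accession, trt]
    aff <- truth$is_affected[s$accession, trt]
    correct_dir <- (s$status == "up" & tl > 0) | (s$status == "down" & tl < 0)
    called <- s$status != "ns"
    data.frame(treatment = trt,
               tp = sum(aff & correct_dir),
               fp = sum(!aff & called),
               tn = sum(!aff & !called),
               fn = sum(aff & !correct_dir),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the simulation ground truth as TSV
#'
#' One row per protein x treatment: `accession`, `treatment`,
#' `true_log2fc`, `is_affected`.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  trts <- colnames(truth$true_log2fc)
  long <- do.call(rbind, lapply(trts, function(trt) {
    data.frame(accession = rownames(truth$true_log2fc), treatment = trt,
               true_log2fc = truth$true_log2fc[, trt],
               is_affected = truth$is_affected[, trt],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a quantification table and design in the tab-separated input dialect
#'
#' Writes `table` in the protein-groups dialect read by
#' [read_protein_groups()] (missing intensities written as 0, the LFQ
#' non-detection convention) and its design in the dialect of
#' [read_design()].
#'
#' @param table A [quant_table()].
#' @param path Output path for the protein-group table.
#' @param design_path Optional output path for the design TSV.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path, design_path = NULL) {
  stopifnot(inherits(table, "quant_table"))
  ints <- table$intensities
  ints[is.na(ints)] <- 0
  out <- data.frame(table$proteins$accession, table$proteins$name,
                    table$proteins$peptide_count,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("Majority protein IDs", "Protein names", "Peptides")
  ints_df <- as.data.frame(apply(ints, 2L, function(col) sprintf("%.15g", col)),
                           stringsAsFactors = FALSE)
  names(ints_df) <- paste0("LFQ intensity ", colnames(ints))
  out <- cbind(out, ints_df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    write.table(as.data.frame(table$design), design_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
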