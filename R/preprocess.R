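#' Filter proteins by peptide evidence
#'
#' Retains only proteins identified by at least `min_peptides` distinct
#' peptides; single-peptide identifications are commonly regarded as
#' unreliable. Row order is preserved.
#'
#' @param table A [quant_table()].
#' @param min_peptides Minimum peptide count (default 2).
#' @return A [quant_table()] with the retained proteins.
#' @export
filter_by_peptides <- function(table, min_peptides = 2L) {
  stopifnot(inherits(table, "quant_table"))
  if (min_peptides < 1L) stop("configuration error: min_peptides must be >= 1")
  keep <- table$proteins$peptide_count >= min_peptides
  subset_quant(table, keep)
}

#' Filter proteins by number of quantified runs
#'
#' Retains proteins observed (non-missing intensity) in at least `min_runs`
#' runs, counted across all runs jointly, not per group.
#'
#' @param table A [quant_table()].
#' @param min_runs Minimum number of runs with an observed intensity
#'   (default 2).
#' @return A [quant_table()] with the retained proteins.
#' @export
filter_by_quantified <- function(table, min_runs = 2L) {
  stopifnot(inherits(table, "quant_table"))
  if (min_runs > ncol(table$intensities)) {
    stop("configuration error: min_runs (", min_runs,
         ") exceeds the number of runs (", ncol(table$intensities), ")")
  }
  keep <- rowSums(!is.na(table$intensities)) >= min_runs
  subset_quant(table, keep)
}

subset_quant <- function(table, keep) {
  quant_table(proteins = table$proteins[keep, , drop = FALSE],
              intensities = table$intensities[keep, , drop = FALSE],
              design = table$design)
}

#' Log2-transform a quantification table
#'
#' Converts raw LFQ intensities to the log2 scale, on which technical
#' variance is approximately constant and abundance ratios become
#' differences. Missing values propagate.
#'
#' @param table A [quant_table()] (all present intensities positive).
#' @return A [log_matrix] carrying the protein metadata and design.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (any(table$intensities <= 0, na.rm = TRUE)) {
    stop("nonpositive present intensity: zeros must be stored as NA upstream")
  }
  log_matrix(values = log2(table$intensities),
             proteins = table$proteins, design = table$design,
             provenance = list(list(step = "log2_transform")))
}

#' Log2-scale abundance matrix with imputation mask and provenance
#'
#' Holds log2 abundances (or `NA`), a boolean mask marking imputed cells,
#' the protein metadata and design carried over from the source
#' [quant_table()], and an ordered provenance list recording every applied
#' processing step with its parameters.
#'
#' @param values Numeric matrix, proteins x runs, log2 scale or `NA`.
#' @param proteins,design As in [quant_table()].
#' @param imputed_mask Logical matrix of the same shape; `TRUE` where the
#'   value was imputed (imputed cells are never `NA`).
#' @param provenance List of steps, each a named list with at least `step`.
#' @return An object of class `log_matrix`.
#' @export
log_matrix <- function(values, proteins, design, imputed_mask = NULL,
                       provenance = list()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!"name" %in% names(proteins)) proteins$name <- NA_character_
  if (is.null(imputed_mask)) {
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  }
  stopifnot(identical(dim(values), dim(imputed_mask)))
  if (any(imputed_mask & is.na(values))) {
    stop("imputed_mask marks a cell that holds no value")
  }
  structure(list(values = values, proteins = proteins, design = design,
                 imputed_mask = imputed_mask, provenance = provenance),
            class = "log_matrix")
}

#' @export
print.log_matrix <- function(x, ...) {
  cat("log_matrix: ", nrow(x$values), " proteins x ", ncol(x$values),
      " runs; ", sum(is.na(x$values)), " missing, ",
      sum(x$imputed_mask), " imputed\n  steps: ",
      paste(vapply(x$provenance, `[[`, "", "step"), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

has_step <- function(m, step) {
  step %in% vapply(m$provenance, `[[`, "", "step")
}

add_step <- function(m, ...) {
  m$provenance <- c(m$provenance, list(list(...)))
  m
}

#' Median normalization of log2 abundances
#'
#' First step of the two-step normalization: each run (column) is shifted so
#' that all column medians of observed values coincide. The common median is
#' the mean of the original column medians, which keeps the matrix on the
#' original intensity scale — important because the later imputation is
#' anchored at per-run observed minima.
#'
#' @param m A [log_matrix()].
#' @return The normalized [log_matrix()]; missing cells untouched.
#' @export
normalize_median <- function(m) {
  stopifnot(inherits(m, "log_matrix"))
  v <- m$values
  meds <- apply(v, 2L, median, na.rm = TRUE)
  if (anyNA(meds)) {
    stop("run(s) with no observed values: ",
         paste(colnames(v)[is.na(meds)], collapse = ", "))
  }
  m$values <- sweep(v, 2L, meds - mean(meds))
  add_step(m, step = "normalize_median", target_median = mean(meds))
}

#' Distribution-width normalization of log2 abundances
#'
#' Second step of the two-step normalization: each run's observed values are
#' rescaled about the run median so that all runs share the same
#' distribution width, measured as the `q_high - q_low` inter-quantile range
#' (the interquartile range by default). Column medians are preserved. Must
#' be applied after [normalize_median()].
#'
#' @param m A median-normalized [log_matrix()].
#' @param q_low,q_high Quantile pair defining the width (defaults 0.25 and
#'   0.75).
#' @return The normalized [log_matrix()].
#' @export
normalize_width <- function(m, q_low = 0.25, q_high = 0.75) {
  stopifnot(inherits(m, "log_matrix"))
  if (!(q_low >= 0 && q_high <= 1 && q_low < q_high)) {
    stop("configuration error: need 0 <= q_low < q_high <= 1")
  }
  if (!has_step(m, "normalize_median")) {
    stop("ordering error: normalize_width requires normalize_median first")
  }
  v <- m$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 3L)) {
    stop("run(s) with fewer than 3 observed values: ",
         paste(colnames(v)[n_obs < 3L], collapse = ", "))
  }
  meds <- apply(v, 2L, median, na.rm = TRUE)
  widths <- apply(v, 2L, function(col) {
    q <- quantile(col, c(q_low, q_high), na.rm = TRUE, names = FALSE)
    q[2L] - q[1L]
  })
  if (any(widths <= 0)) {
    stop("zero distribution width in run(s): ",
         paste(colnames(v)[widths <= 0], collapse = ", "))
  }
  target <- mean(widths)
  for (j in seq_len(ncol(v))) {
    v[, j] <- meds[j] + (v[, j] - meds[j]) * (target / widths[j])
  }
  m$values <- v
  add_step(m, step = "normalize_width", q_low = q_low, q_high = q_high,
           target_width = target)
}

#' Impute left-censored missing values
#'
#' LFQ missingness is predominantly missing-not-at-random: low-abundance
#' proteins fall below the detection limit. Missing cells are therefore
#' filled with small values drawn near the bottom of each run's observed
#' distribution.
#'
#' Two methods are provided. `probabilistic_minimum` (the default) draws,
#' per run, from a normal distribution centred at the run's observed minimum
#' with standard deviation `spread_factor` times the run's observed SD,
#' truncated above at that minimum — so an imputed value never exceeds the
#' smallest observed value of its run. `downshifted_normal` draws from a
#' normal centred `downshift` observed SDs below the run mean with SD
#' `downshift_width` times the observed SD (the common global-downshift
#' alternative), without truncation.
#'
#' Reproducibility: run (column) `j` uses the RNG substream seeded with
#' `seed + j`, so results do not depend on column iteration order; the
#' caller's RNG state is left untouched.
#'
#' @param m A normalized [log_matrix()].
#' @param seed Integer seed (mandatory).
#' @param method `"probabilistic_minimum"` or `"downshifted_normal"`.
#' @param spread_factor Truncated-normal SD as a fraction of the run SD
#'   (default 0.25).
#' @param downshift,downshift_width Location shift and SD, in units of the
#'   run SD, for `downshifted_normal` (defaults 1.8 and 0.3).
#' @return A complete [log_matrix()] with `imputed_mask` marking exactly the
#'   previously missing cells; observed cells are never altered.
#' @export
impute_probabilistic_minimum <- function(m, seed,
                                         method = c("probabilistic_minimum",
                                                    "downshifted_normal"),
                                         spread_factor = 0.25,
                                         downshift = 1.8,
                                         downshift_width = 0.3) {
  stopifnot(inherits(m, "log_matrix"))
  method <- match.arg(method)
  if (missing(seed) || !is.numeric(seed)) stop("seed is required")
  if (spread_factor <= 0 || downshift <= 0 || downshift_width <= 0) {
    stop("configuration error: spread/downshift parameters must be positive")
  }
  v <- m$values
  miss <- is.na(v)
  if (any(colSums(!miss) == 0L)) {
    stop("run(s) entirely missing: ",
         paste(colnames(v)[colSums(!miss) == 0L], collapse = ", "))
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (j in seq_len(ncol(v))) {
    idx <- which(miss[, j])
    if (length(idx) == 0L) next
    obs <- v[!miss[, j], j]
    col_sd <- stats::sd(obs)
    if (is.na(col_sd) || col_sd == 0) col_sd <- 1e-6  # degenerate column
    set.seed(seed + j)
    v[idx, j] <- if (method == "probabilistic_minimum") {
      rtruncnorm_upper(length(idx), mean = min(obs),
                       sd = spread_factor * col_sd, upper = min(obs))
    } else {
      rnorm(length(idx), mean = mean(obs) - downshift * col_sd,
            sd = downshift_width * col_sd)
    }
  }
  m$values <- v
  m$imputed_mask <- m$imputed_mask | miss
  add_step(m, step = "impute", method = method, seed = seed,
           spread_factor = spread_factor, downshift = downshift,
           downshift_width = downshift_width)
}

# Upper-truncated normal draws by inverse CDF: u ~ U(0,1) mapped through
# the CDF restricted to (-Inf, upper]. Deterministic given the RNG stream.
rtruncnorm_upper <- function(n, mean, sd, upper) {
  p_up <- pnorm(upper, mean, sd)
  u <- runif(n)
  qnorm(u * p_up, mean, sd)
}
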