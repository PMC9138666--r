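#' Log2 fold change between treatment and control replicates
#'
#' On the log2 scale the fold change of mean abundances is the difference of
#' means: `mean(x) - mean(y)`. The reporting-scale fold change is
#' `2^log2fc`.
#'
#' @param x Numeric vector of treatment replicate values (log2 scale,
#'   complete).
#' @param y Numeric vector of control replicate values (log2 scale,
#'   complete).
#' @return The log2 fold change (a single number).
#' @export
log2_fold_change <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty replicate vector")
  if (anyNA(x) || anyNA(y)) stop("replicate values must be complete (imputed)")
  mean(x) - mean(y)
}

#' Variance-ratio gate choosing the t-test variant
#'
#' Performs a two-tailed F-test of equal variances between the two replicate
#' groups: the larger sample variance goes in the numerator and the p-value
#' is `2 * min(tail, 1 - tail)` capped at 1. If the gate rejects at
#' `gate_alpha` the comparison uses the unequal-variance Welch t-test
#' (spreadsheet "type 3"), otherwise the pooled-variance Student t-test
#' (spreadsheet "type 2"). Equal variances give `gate_p = 1`; if exactly one
#' group has zero variance the ratio is infinite, `gate_p = 0`, and the
#' Welch branch is taken; if both variances are zero the gate is degenerate
#' and reports `gate_p = 1` with the Student branch.
#'
#' @param x,y Numeric replicate vectors, each of length >= 2.
#' @param gate_alpha Significance level of the gate (default 0.05).
#' @return List with `gate_p` and `test_type` (`"student_type2"` or
#'   `"welch_type3"`).
#' @export
variance_gate <- function(x, y, gate_alpha = 0.05) {
  if (gate_alpha < 0 || gate_alpha > 1) {
    stop("configuration error: gate_alpha must be in [0, 1]")
  }
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  p <- gate_p_vec(var(x), length(x), var(y), length(y))
  list(gate_p = p,
       test_type = if (p < gate_alpha) "welch_type3" else "student_type2")
}

#' Two-sample t-test p-value, Student or Welch variant
#'
#' Two-tailed p-value of the two-sample t-test. `student_type2` is the
#' pooled-variance Student test with `n1 + n2 - 2` degrees of freedom;
#' `welch_type3` is the unequal-variance Welch test with
#' Welch-Satterthwaite degrees of freedom (the spreadsheet TTEST "type 2"
#' and "type 3" semantics). Degenerate limits: if both groups are constant,
#' the p-value is 1 when the constants are equal and 0 when they differ.
#'
#' @param x,y Numeric replicate vectors, each of length >= 2.
#' @param test_type `"student_type2"` or `"welch_type3"`, typically chosen
#'   by [variance_gate()].
#' @return Two-tailed p-value.
#' @export
t_test_p <- function(x, y, test_type = c("student_type2", "welch_type3")) {
  test_type <- match.arg(test_type)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  t_p_vec(mean(x), var(x), length(x), mean(y), var(y), length(y),
          welch = test_type == "welch_type3")
}

# Vectorized cores shared by the scalar API and run_comparisons().
gate_p_vec <- function(v1, n1, v2, n2) {
  hi <- pmax(v1, v2)
  lo <- pmin(v1, v2)
  df_hi <- ifelse(v1 >= v2, n1 - 1L, n2 - 1L)
  df_lo <- ifelse(v1 >= v2, n2 - 1L, n1 - 1L)
  tail <- pf(hi / lo, df_hi, df_lo, lower.tail = FALSE)
  p <- ifelse(hi == lo, 1,
              ifelse(lo == 0, 0, 2 * pmin(tail, 1 - tail)))
  as.numeric(p)
}

t_p_vec <- function(m1, v1, n1, m2, v2, n2, welch) {
  if (length(welch) == 1L) welch <- rep(welch, length(m1))
  se2 <- ifelse(welch,
                v1 / n1 + v2 / n2,
                (((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) *
                  (1 / n1 + 1 / n2))
  df <- ifelse(welch,
               (v1 / n1 + v2 / n2)^2 /
                 ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(se2 == 0,
              ifelse(m1 == m2, 1, 0),           # both groups constant
              2 * pt(abs(m1 - m2) / sqrt(se2), df, lower.tail = FALSE))
  as.numeric(p)
}

#' Call differentially abundant proteins
#'
#' A protein is up-regulated in a treatment iff its t-test p-value is
#' strictly below `p_threshold` and its log2 fold change strictly exceeds
#' `log2(fc_cutoff)`; down-regulated symmetrically; otherwise not
#' significant (`ns`). Both inequalities are strict, so a protein sitting
#' exactly on a threshold is `ns`.
#'
#' @param stats A result table from [run_comparisons()] (needs columns
#'   `t_p` and `log2fc`).
#' @param p_threshold p-value threshold (default 0.05).
#' @param fc_cutoff Fold-change cutoff on the raw scale, must exceed 1
#'   (default 2).
#' @return `stats` with its `status` column set to `"up"`, `"down"` or
#'   `"ns"`.
#' @export
call_daps <- function(stats, p_threshold = 0.05, fc_cutoff = 2) {
  if (fc_cutoff <= 1) stop("configuration error: fc_cutoff must be > 1")
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("configuration error: p_threshold must be in (0, 1]")
  }
  lfc_cut <- log2(fc_cutoff)
  sig <- stats$t_p < p_threshold
  stats$status <- ifelse(sig & stats$log2fc > lfc_cut, "up",
                         ifelse(sig & stats$log2fc < -lfc_cut, "down", "ns"))
  stats
}

#' Per-protein gated differential-abundance tests against control
#'
#' For every protein and every treatment group, compares the treatment
#' replicates with the control replicates of the normalized, imputed log2
#' matrix: computes the log2 fold change, runs the variance gate
#' ([variance_gate()]), applies the selected t-test variant ([t_test_p()]),
#' and calls DAP status ([call_daps()]). Imputed cells enter the comparison
#' as ordinary values but are counted in `n_imputed` so that extreme fold
#' changes driven by imputation can be audited.
#'
#' @param norm A complete (imputed) [log_matrix()].
#' @param gate_alpha Variance-gate level (default 0.05).
#' @param p_threshold,fc_cutoff DAP thresholds, see [call_daps()].
#' @param p_adjust `"none"` (default; raw p-values are compared with
#'   `p_threshold`) or `"BH"` (Benjamini-Hochberg adjustment across proteins
#'   within each treatment before calling).
#' @return A `data.frame` with one row per protein x treatment: `accession`,
#'   `name`, `treatment`, `log2fc`, `fc`, `gate_p`, `test_type`, `t_p`,
#'   `status`, `n_imputed`.
#' @export
run_comparisons <- function(norm, gate_alpha = 0.05, p_threshold = 0.05,
                            fc_cutoff = 2, p_adjust = c("none", "BH")) {
  stopifnot(inherits(norm, "log_matrix"))
  p_adjust <- match.arg(p_adjust)
  if (anyNA(norm$values)) {
    stop("matrix contains missing values: impute before testing")
  }
  design <- norm$design
  ctrl <- attr(design, "control")
  trts <- treatments(design)
  ctrl_cols <- design$run[design$group == ctrl]
  Y <- norm$values[, ctrl_cols, drop = FALSE]
  n2 <- ncol(Y)
  m2 <- rowMeans(Y)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  res <- lapply(trts, function(trt) {
    trt_cols <- design$run[design$group == trt]
    if (length(trt_cols) < 2L || n2 < 2L) {
      stop("group with fewer than 2 runs: ", trt)
    }
    X <- norm$values[, trt_cols, drop = FALSE]
    n1 <- ncol(X)
    m1 <- rowMeans(X)
    v1 <- rowSums((X - m1)^2) / (n1 - 1)
    gate_p <- gate_p_vec(v1, n1, v2, n2)
    welch <- gate_p < gate_alpha
    t_p <- t_p_vec(m1, v1, n1, m2, v2, n2, welch)
    lfc <- m1 - m2
    data.frame(
      accession = norm$proteins$accession,
      name = norm$proteins$name,
      treatment = trt,
      log2fc = lfc,
      fc = 2^lfc,
      gate_p = gate_p,
      test_type = ifelse(welch, "welch_type3", "student_type2"),
      t_p = t_p,
      status = "ns",
      n_imputed = as.integer(rowSums(
        norm$imputed_mask[, c(trt_cols, ctrl_cols), drop = FALSE])),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  res <- do.call(rbind, res)
  if (p_adjust == "BH") {
    res$t_p <- stats::ave(res$t_p, res$treatment,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  }
  call_daps(res, p_threshold = p_threshold, fc_cutoff = fc_cutoff)
}

#' Cross-treatment DAP set intersections
#'
#' Collects, per treatment and direction, the sets of up- and down-regulated
#' accessions, and reports the sizes of every pairwise and higher-order
#' intersection per direction (a Venn-style comparison).
#'
#' @param stats A result table from [run_comparisons()] covering >= 2
#'   treatments.
#' @return An object of class `dap_sets`: a list with `sets` (per direction,
#'   per treatment, sorted accession vectors), `intersections` (a
#'   `data.frame` of direction, treatment combination, size), and
#'   `shared_all` (per direction, accessions shared by all treatments).
#' @export
shared_sets <- function(stats) {
  trts <- unique(stats$treatment)
  if (length(trts) < 2L) stop("need >= 2 treatments for set comparison")
  sets <- lapply(c(up = "up", down = "down"), function(dir) {
    s <- lapply(setNames(trts, trts), function(trt) {
      sort(stats$accession[stats$treatment == trt & stats$status == dir])
    })
    s
  })
  rows <- list()
  for (dir in names(sets)) {
    for (k in 2:length(trts)) {
      for (combo in combn(trts, k, simplify = FALSE)) {
        size <- length(Reduce(intersect, sets[[dir]][combo]))
        rows[[length(rows) + 1L]] <- data.frame(
          direction = dir, treatments = paste(combo, collapse = "&"),
          n_treatments = k, size = size, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    sets = sets,
    intersections = do.call(rbind, rows),
    shared_all = lapply(sets, function(s) Reduce(intersect, s))
  ), class = "dap_sets")
}

#' @export
print.dap_sets <- function(x, ...) {
  for (dir in names(x$sets)) {
    sizes <- vapply(x$sets[[dir]], length, integer(1L))
    cat(dir, ": ", paste(names(sizes), sizes, sep = "=", collapse = ", "),
        "; shared by all = ", length(x$shared_all[[dir]]), "\n", sep = "")
  }
  invisible(x)
}

#' DAP set sizes as a table
#'
#' @param stats A result table from [run_comparisons()].
#' @return `data.frame` with one row per treatment: counts of up, down and
#'   total DAPs.
#' @export
dap_counts <- function(stats) {
  trts <- unique(stats$treatment)
  out <- do.call(rbind, lapply(trts, function(trt) {
    s <- stats$status[stats$treatment == trt]
    data.frame(treatment = trt, up = sum(s == "up"), down = sum(s == "down"),
               total = sum(s != "ns"), stringsAsFactors = FALSE)
  }))
  out
}
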