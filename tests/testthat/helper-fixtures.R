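# Shared fixture builders and independent oracles.

# Small study-shaped design: control + 3 treatments, 3 technical replicates.
make_design <- function(groups = c("control", "T1", "T2", "T3"), reps = 3L) {
  sample_design(
    run = as.vector(vapply(groups, function(g) paste(g, seq_len(reps),
                                                     sep = "_"),
                           character(reps))),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), length(groups)),
    control = groups[1L])
}

# Quant table with given intensity matrix (NA = missing).
make_quant <- function(intensities, peptide_count = NULL,
                       design = make_design()) {
  n <- nrow(intensities)
  if (is.null(peptide_count)) peptide_count <- rep(5L, n)
  quant_table(
    proteins = data.frame(accession = sprintf("P%03d", seq_len(n)),
                          name = sprintf("protein %d", seq_len(n)),
                          peptide_count = peptide_count,
                          stringsAsFactors = FALSE),
    intensities = intensities, design = design)
}

# Random complete log-scale matrix wrapped as log_matrix.
make_logmat <- function(n = 50L, design = make_design(), seed = 1L,
                        na_frac = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n * nrow(design), 25, 2), n, nrow(design))
  if (na_frac > 0) v[runif(length(v)) < na_frac] <- NA_real_
  colnames(v) <- design$run
  rownames(v) <- sprintf("P%03d", seq_len(n))
  log_matrix(values = v,
             proteins = data.frame(accession = rownames(v),
                                   name = rownames(v),
                                   peptide_count = rep(5L, n),
                                   stringsAsFactors = FALSE),
             design = design)
}

# Write a protein-group TSV in the MaxQuant dialect; ints: numeric matrix
# (0 encodes non-detection), runs taken from colnames.
write_pg_tsv <- function(ints, peptides, path,
                         accession = sprintf("P%03d", seq_len(nrow(ints))),
                         scramble_cols = FALSE) {
  df <- data.frame(accession, "x", peptides, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("Majority protein IDs", "Protein names", "Peptides")
  int_df <- as.data.frame(ints, check.names = FALSE)
  names(int_df) <- paste0("LFQ intensity ", colnames(ints))
  if (scramble_cols) int_df <- int_df[, rev(seq_len(ncol(int_df))),
                                      drop = FALSE]
  write.table(cbind(df, int_df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

write_design_tsv <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# --- Independent statistical oracles ---------------------------------------

# Pooled-variance two-sample t (closed textbook form, not the package path).
oracle_student_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tval), n1 + n2 - 2)
}

# Welch t with Welch-Satterthwaite df.
oracle_welch_p <- function(x, y) {
  a <- var(x) / length(x); b <- var(y) / length(y)
  tval <- (mean(x) - mean(y)) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (length(x) - 1) + b^2 / (length(y) - 1))
  2 * pt(-abs(tval), df)
}

# Two-tailed variance-ratio p via numerical integration of the F density
# (upper tail of the larger/smaller ratio, doubled).
oracle_gate_p <- function(x, y) {
  v1 <- var(x); v2 <- var(y)
  if (v1 == v2) return(1)
  if (min(v1, v2) == 0) return(0)
  Fstat <- max(v1, v2) / min(v1, v2)
  df1 <- if (v1 >= v2) length(x) - 1 else length(y) - 1
  df2 <- if (v1 >= v2) length(y) - 1 else length(x) - 1
  # upper tail via the substitution x = exp(t): the integrand
  # df(exp(t)) * exp(t) decays exponentially (rate df2/2), which the
  # quadrature handles even for the heavy df2 = 1 tail at huge F
  g <- function(t) {
    # beyond t ~ 709, exp overflows and the density is 0 anyway
    out <- suppressWarnings(exp(df(exp(t), df1, df2, log = TRUE) + t))
    out[!is.finite(out)] <- 0
    out
  }
  tail <- integrate(g, lower = log(Fstat), upper = Inf,
                    rel.tol = 1e-11, subdivisions = 500L)$value
  2 * min(tail, 1 - tail)
}

# Inverse-CDF upper-truncated normal sampler, coded independently of the
# package, under the same per-column substream policy (seed + column).
oracle_impute_column <- function(n_missing, col_min, col_sd, spread_factor,
                                 seed, col_index) {
  set.seed(seed + col_index)
  u <- runif(n_missing)
  col_min + col_sd * spread_factor *
    qnorm(u * pnorm(0))  # standardization: upper bound == mean
}
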