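test_that("peptide filter keeps proteins with enough peptide evidence", {
  ints <- matrix(1000, 3, 12)
  tb <- make_quant(ints, peptide_count = c(1L, 2L, 3L))
  expect_identical(filter_by_peptides(tb, 2)$proteins$accession,
                   c("P002", "P003"))
  expect_identical(filter_by_peptides(tb, 1)$proteins$accession,
                   tb$proteins$accession)
  expect_error(filter_by_peptides(tb, 0), "configuration error")
})

test_that("quantified-run filter counts observed cells across all runs", {
  ints <- matrix(1000, 3, 12)
  ints[1, 2:12] <- NA   # observed in exactly 1 of 12 runs
  ints[2, 3:12] <- NA   # observed in 2 runs
  tb <- make_quant(ints)
  expect_identical(filter_by_quantified(tb, 2)$proteins$accession,
                   c("P002", "P003"))
  expect_identical(filter_by_quantified(tb, 0)$proteins$accession,
                   tb$proteins$accession)
  expect_error(filter_by_quantified(tb, 13), "configuration error")
})

test_that("log2 transform is exact on powers of two and propagates NA", {
  ints <- matrix(c(1024, rep(NA, 11), rep(2^25.5, 12)), 2, 12, byrow = TRUE)
  m <- log2_transform(make_quant(ints))
  expect_identical(m$values[1, 1], 10)
  expect_true(all(is.na(m$values[1, 2:12])))
  expect_equal(m$values[2, ], setNames(rep(25.5, 12), colnames(m$values)),
               tolerance = 1e-9)
  expect_true("log2_transform" %in% sapply(m$provenance, `[[`, "step"))
})

test_that("median normalization equalizes column medians about their mean", {
  # half the runs have median 10, half median 20 -> all get 15
  design <- make_design()
  v <- cbind(matrix(c(9, 10, 11), 3, 6), matrix(c(19, 20, 21), 3, 6))
  colnames(v) <- design$run
  m <- log_matrix(v, proteins = data.frame(accession = as.character(1:3),
                                           peptide_count = 2L),
                  design = design)
  out <- normalize_median(m)
  expect_equal(unname(apply(out$values, 2, median)), rep(15, 12),
               tolerance = 1e-12)
})

test_that("median normalization postconditions hold on random matrices", {
  m <- make_logmat(n = 50, seed = 11, na_frac = 0.1)
  out <- normalize_median(m)
  meds <- apply(out$values, 2, median, na.rm = TRUE)
  expect_lt(diff(range(meds)), 1e-9)
  expect_equal(mean(meds),
               mean(apply(m$values, 2, median, na.rm = TRUE)),
               tolerance = 1e-9)
  # each column is a pure shift of the original
  for (j in seq_len(ncol(m$values))) {
    d <- out$values[, j] - m$values[, j]
    expect_lt(diff(range(d, na.rm = TRUE)), 1e-12)
  }
  # missing cells untouched
  expect_identical(is.na(out$values), is.na(m$values))
  # idempotence
  twice <- normalize_median(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)
})

test_that("median normalization is shift-equivariant", {
  m <- make_logmat(n = 40, seed = 21)
  shifted <- m
  shifted$values[, 4] <- shifted$values[, 4] + 7.3
  a <- normalize_median(m)
  b <- normalize_median(shifted)
  # the shifted column is recentred; only the global target moves with the
  # mean of medians, a constant offset across the whole matrix
  offset <- 7.3 / ncol(m$values)
  expect_equal(b$values, a$values + offset, tolerance = 1e-9)
})

test_that("width normalization equalizes IQRs and preserves medians", {
  m <- normalize_median(make_logmat(n = 50, seed = 31, na_frac = 0.1))
  out <- normalize_width(m)
  iqrs <- apply(out$values, 2, function(col) {
    q <- quantile(col, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  })
  expect_lt(diff(range(iqrs)), 1e-9)
  meds_before <- apply(m$values, 2, median, na.rm = TRUE)
  meds_after <- apply(out$values, 2, median, na.rm = TRUE)
  expect_equal(meds_after, meds_before, tolerance = 1e-9)
  # independent direct computation of the rescaling on one column
  j <- 5
  w_j <- diff(quantile(m$values[, j], c(0.25, 0.75), na.rm = TRUE))
  w_all <- mean(apply(m$values, 2, function(col)
    diff(quantile(col, c(0.25, 0.75), na.rm = TRUE))))
  expect_equal(out$values[, j],
               meds_before[j] + (m$values[, j] - meds_before[j]) *
                 (w_all / w_j),
               tolerance = 1e-9)
  # idempotence
  expect_equal(normalize_width(out)$values, out$values, tolerance = 1e-12)
})

test_that("width normalization is scale-equivariant and order-checked", {
  m <- normalize_median(make_logmat(n = 40, seed = 41))
  scaled <- m
  med5 <- median(scaled$values[, 5])
  scaled$values[, 5] <- med5 + (scaled$values[, 5] - med5) * 3.7
  a <- normalize_width(m)
  b <- normalize_width(scaled)
  # scaling one column's deviations changes the target width by a known
  # factor; after removing it, results coincide
  w <- apply(m$values, 2, function(col)
    diff(quantile(col, c(0.25, 0.75), names = FALSE)))
  ratio <- mean(replace(w, 5, w[5] * 3.7)) / mean(w)
  meds <- apply(m$values, 2, median)
  undone <- sweep(sweep(b$values, 2, meds) / ratio, 2, meds, `+`)
  expect_equal(undone, a$values, tolerance = 1e-9)
  expect_error(normalize_width(make_logmat(n = 10)), "ordering error")
})

test_that("identical columns pass width normalization unchanged", {
  v <- matrix(rep(c(21, 23, 25, 27, 29), 12), 5, 12)
  colnames(v) <- make_design()$run
  m <- normalize_median(log_matrix(
    v, proteins = data.frame(accession = sprintf("P%d", 1:5),
                             peptide_count = 2L),
    design = make_design()))
  out <- normalize_width(m)
  expect_equal(out$values, m$values, tolerance = 1e-12)
})

test_that("probabilistic-minimum imputation fills exactly the missing cells", {
  m <- normalize_width(normalize_median(
    make_logmat(n = 60, seed = 51, na_frac = 0.08)))
  miss <- is.na(m$values)
  out <- impute_probabilistic_minimum(m, seed = 99)
  expect_false(anyNA(out$values))
  expect_identical(out$imputed_mask, miss)
  # observed cells never altered
  expect_identical(out$values[!miss], m$values[!miss])
  # truncation contract: imputed values never exceed the column observed min
  for (j in which(colSums(miss) > 0)) {
    expect_true(all(out$values[miss[, j], j] <=
                      min(m$values[, j], na.rm = TRUE)))
  }
  # reproducible from seed; different seed differs
  again <- impute_probabilistic_minimum(m, seed = 99)
  expect_identical(again$values, out$values)
  other <- impute_probabilistic_minimum(m, seed = 100)
  expect_false(identical(other$values, out$values))
  # a complete matrix passes through untouched
  complete <- impute_probabilistic_minimum(make_logmat(n = 10), seed = 1)
  expect_false(any(complete$imputed_mask))
})

test_that("imputed draws match an independently coded truncated-normal
           sampler under the same substream policy", {
  m <- normalize_width(normalize_median(
    make_logmat(n = 60, seed = 61, na_frac = 0.1)))
  miss <- is.na(m$values)
  out <- impute_probabilistic_minimum(m, seed = 7, spread_factor = 0.25)
  for (j in which(colSums(miss) > 0)) {
    obs <- m$values[!miss[, j], j]
    expected <- oracle_impute_column(sum(miss[, j]), min(obs), sd(obs),
                                     spread_factor = 0.25, seed = 7,
                                     col_index = j)
    expect_equal(unname(out$values[miss[, j], j]), expected,
                 tolerance = 1e-12)
  }
})

test_that("downshifted-normal alternative imputes below the distribution
           body and caller RNG state is preserved", {
  m <- normalize_width(normalize_median(
    make_logmat(n = 80, seed = 71, na_frac = 0.1)))
  set.seed(12345)
  before <- .Random.seed
  out <- impute_probabilistic_minimum(m, seed = 7,
                                      method = "downshifted_normal")
  expect_identical(.Random.seed, before)
  imputed <- out$values[out$imputed_mask]
  expect_lt(mean(imputed), mean(m$values, na.rm = TRUE))
  expect_error(impute_probabilistic_minimum(m, seed = 1, spread_factor = 0),
               "configuration error")
})

test_that("imputation refuses a run with no observed values", {
  m <- make_logmat(n = 5, seed = 81)
  m$values[, 3] <- NA_real_
  expect_error(impute_probabilistic_minimum(m, seed = 1), "entirely missing")
})

test_that("full preprocessing chain removes run biases: recovered group
           effects are nearly unbiased when censoring is off", {
  # dap_fraction 0 so that only the run biases differ between groups and
  # the chain is exercised purely as a normalization
  cfg <- sim_config(n_proteins = 200, dap_fraction = 0,
                    censor_quantile = 0, single_peptide_fraction = 0,
                    seed = 17)
  sim <- simulate_lfq(cfg)
  norm <- normalize_width(normalize_median(log2_transform(sim$table)))
  # no censoring -> nothing to impute
  expect_false(anyNA(norm$values))
  stats <- run_comparisons(norm)
  err <- stats$log2fc -
    sim$truth$true_log2fc[cbind(match(stats$accession,
                                      rownames(sim$truth$true_log2fc)),
                                match(stats$treatment,
                                      colnames(sim$truth$true_log2fc)))]
  expect_lt(abs(mean(err)), 0.1)
})
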