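#' Read and write protein-group quantification tables
#'
#' `read_protein_groups()` parses a tab-separated protein-group table in the
#' MaxQuant `proteinGroups.txt` dialect into a [quant_table] object. Intensity
#' cells equal to `0` or blank are stored as missing (`NA`): an LFQ intensity
#' of zero encodes a non-detection, not a measured abundance, and no
#' downstream stage ever sees a raw zero.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param design A sample design as returned by [read_design()] or
#'   [sample_design()]. Run identifiers in the design select and order the
#'   intensity columns; the matrix column order always follows the design,
#'   not the file.
#' @param column_map Named list mapping semantic roles to column headers.
#'   Recognised roles: `accession` (default `"Majority protein IDs"`),
#'   `name` (default `"Protein names"`, optional), `peptides`
#'   (default `"Peptides"`), and `intensity_prefix` (default
#'   `"LFQ intensity "`), the prefix prepended to each run identifier to
#'   obtain its intensity column header.
#' @param drop_contaminants Drop rows whose accession starts with `CON__` or
#'   `REV__` (MaxQuant contaminant/decoy markers). Default `TRUE`.
#' @return A [quant_table].
#' @seealso [quant_table()], [read_design()], [write_results()]
#' @export
read_protein_groups <- function(path, design, column_map = list(),
                                drop_contaminants = TRUE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- modifyList(list(accession = "Majority protein IDs",
                          name = "Protein names",
                          peptides = "Peptides",
                          intensity_prefix = "LFQ intensity "), column_map)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  for (role in c("accession", "peptides")) {
    if (!cmap[[role]] %in% names(raw)) {
      stop("schema error: required column for role '", role,
           "' not found (expected header '", cmap[[role]], "')")
    }
  }
  int_cols <- paste0(cmap$intensity_prefix, design$run)
  absent <- setdiff(int_cols, names(raw))
  if (length(absent) > 0L) {
    stop("schema error: intensity column(s) missing for run(s): ",
         paste(sub(cmap$intensity_prefix, "", absent, fixed = TRUE),
               collapse = ", "))
  }
  acc <- as.character(raw[[cmap$accession]])
  if (anyNA(acc) || any(!nzchar(acc))) stop("empty accession in table")
  if (drop_contaminants) {
    keep <- !grepl("^(CON__|REV__)", acc)
    raw <- raw[keep, , drop = FALSE]
    acc <- acc[keep]
  }
  if (anyDuplicated(acc)) {
    stop("duplicate accessions: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  nm <- if (cmap$name %in% names(raw)) as.character(raw[[cmap$name]]) else
    rep(NA_character_, length(acc))
  pep <- raw[[cmap$peptides]]
  if (!is.numeric(pep) || anyNA(pep) || any(pep < 0) || any(pep != floor(pep))) {
    stop("parse error: peptide counts must be non-negative integers")
  }
  mat <- matrix(NA_real_, nrow = length(acc), ncol = length(int_cols),
                dimnames = list(acc, design$run))
  for (j in seq_along(int_cols)) {
    col <- raw[[int_cols[j]]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L) {
        stop("parse error: non-numeric intensity at row ", bad[1L],
             ", column '", int_cols[j], "': '", col[bad[1L]], "'")
      }
      col <- num
    }
    mat[, j] <- col
  }
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensity encountered")
  mat[!is.na(mat) & mat == 0] <- NA_real_   # zero LFQ = non-detection
  quant_table(
    proteins = data.frame(accession = acc, name = nm,
                          peptide_count = as.integer(pep),
                          stringsAsFactors = FALSE),
    intensities = mat, design = design
  )
}

#' Construct a protein-group quantification table
#'
#' The central container of the pipeline: protein metadata, a
#' proteins-by-runs intensity matrix (`NA` marks a missing, i.e.
#' non-detected, value), and the sample design that maps runs to groups.
#'
#' @param proteins `data.frame` with columns `accession` (unique, non-empty),
#'   `name` (may be `NA`) and `peptide_count` (non-negative integer).
#' @param intensities Numeric matrix, proteins in rows and runs in columns;
#'   values are raw LFQ intensities (positive) or `NA`.
#' @param design A [sample_design()].
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(proteins, intensities, design) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "peptide_count") %in% names(proteins)),
            is.matrix(intensities), is.numeric(intensities))
  if (!"name" %in% names(proteins)) proteins$name <- NA_character_
  if (anyDuplicated(proteins$accession) ||
      any(!nzchar(proteins$accession)) || anyNA(proteins$accession)) {
    stop("accessions must be unique and non-empty")
  }
  if (any(proteins$peptide_count < 0)) stop("peptide_count must be >= 0")
  if (nrow(intensities) != nrow(proteins)) {
    stop("intensity matrix rows (", nrow(intensities),
         ") do not match protein list (", nrow(proteins), ")")
  }
  design <- validate_design(design)
  if (ncol(intensities) != nrow(design)) {
    stop("intensity matrix columns (", ncol(intensities),
         ") do not match design runs (", nrow(design), ")")
  }
  if (!is.null(colnames(intensities))) {
    missing_runs <- setdiff(design$run, colnames(intensities))
    if (length(missing_runs) > 0L) {
      stop("consistency error: design run(s) absent from table: ",
           paste(missing_runs, collapse = ", "))
    }
    intensities <- intensities[, design$run, drop = FALSE]
  } else {
    colnames(intensities) <- design$run
  }
  rownames(intensities) <- proteins$accession
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop("present intensities must be positive (zeros are stored as NA)")
  }
  structure(list(proteins = proteins, intensities = intensities,
                 design = design),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  n_missing <- sum(is.na(x$intensities))
  cat("quant_table: ", nrow(x$proteins), " proteins x ",
      nrow(x$design), " runs (",
      length(unique(x$design$group)), " groups; control = '",
      attr(x$design, "control"), "'); ",
      round(100 * n_missing / length(x$intensities), 1),
      "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)

#' Construct and validate a sample design
#'
#' Maps each mass-spectrometry run to a group (one control plus one or more
#' treatments) and a technical replicate index. Every group must have at
#' least two runs; the study design this package emulates has exactly three
#' technical replicates per pooled sample.
#'
#' @param run Character vector of unique run identifiers, in matrix column
#'   order.
#' @param group Character vector, same length: group label per run.
#' @param replicate Integer vector, same length: replicate index within group.
#' @param control Label of the control group (must occur in `group`).
#' @return A `data.frame` of class `sample_design` with attribute `control`.
#' @export
sample_design <- function(run, group, replicate = NULL, control = "control") {
  if (is.null(replicate)) replicate <- stats::ave(seq_along(run), group,
                                                  FUN = seq_along)
  d <- data.frame(run = as.character(run), group = as.character(group),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  attr(d, "control") <- control
  class(d) <- c("sample_design", "data.frame")
  validate_design(d)
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("run", "group", "replicate") %in% names(design)))
  control <- attr(design, "control")
  if (is.null(control)) stop("configuration error: no control group designated")
  if (anyDuplicated(design$run)) stop("duplicate run identifiers in design")
  if (!control %in% design$group) {
    stop("configuration error: control group '", control,
         "' not present in design")
  }
  sizes <- table(design$group)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    stop("invariant violation: group(s) with fewer than 2 runs: ",
         paste(small, collapse = ", "))
  }
  if (length(sizes) < 2L) stop("design needs a control and >=1 treatment group")
  design
}

#' Read a sample design file
#'
#' Tab-separated file with columns `run`, `group`, `replicate` and one row
#' per run.
#'
#' @inheritParams sample_design
#' @param path Path to the TSV file.
#' @return A validated [sample_design()].
#' @export
read_design <- function(path, control = "control") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("run", "group", "replicate"), names(d))
  if (length(need) > 0L) {
    stop("schema error: design file lacks column(s): ",
         paste(need, collapse = ", "))
  }
  sample_design(d$run, d$group, d$replicate, control = control)
}

#' Treatment group labels of a design
#'
#' @param design A [sample_design()].
#' @return Character vector of non-control group labels, in order of first
#'   appearance.
#' @export
treatments <- function(design) {
  setdiff(unique(design$group), attr(design, "control"))
}

#' Write and re-read differential-abundance result tables
#'
#' `write_results()` writes one row per protein x treatment comparison as
#' UTF-8 TSV with `.` decimal separator and empty cells for `NA`; values
#' round-trip through `read_results()` without loss at better than 10
#' significant digits.
#'
#' @param stats A result table from [run_comparisons()].
#' @param path Output path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the result `data.frame`.
#' @export
write_results <- function(stats, path) {
  stopifnot(is.data.frame(stats))
  out <- stats
  num <- vapply(out, is.numeric, logical(1L)) & names(out) != "n_imputed"
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(c("log2fc", "fc", "gate_p", "t_p"), names(d))) {
    d[[col]] <- as.numeric(d[[col]])
  }
  if ("n_imputed" %in% names(d)) d$n_imputed <- as.integer(d$n_imputed)
  d
}
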