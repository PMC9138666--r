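#' Read a protein annotation table
#'
#' Tab-separated file with columns `accession`, `category` and optionally
#' `display_name`. Accessions absent from the map fall in category
#' `"unannotated"` when summarised.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `accession`, `category`,
#'   `display_name`.
#' @export
read_annotation <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("accession", "category"), names(a))
  if (length(need) > 0L) {
    stop("schema error: annotation lacks column(s): ",
         paste(need, collapse = ", "))
  }
  if (!"display_name" %in% names(a)) a$display_name <- NA_character_
  if (anyDuplicated(a$accession)) {
    stop("annotation maps an accession to more than one category: ",
         paste(unique(a$accession[duplicated(a$accession)]), collapse = ", "))
  }
  a[c("accession", "category", "display_name")]
}

#' Volcano plot of one treatment-vs-control comparison
#'
#' Scatter of effect size against significance: `x = log2(FC)` and
#' `y = -log2(p)` (base-2 significance axis, so the p < 0.05 line sits at
#' `-log2(0.05) = 4.3219`). Threshold lines are drawn at
#' `y = -log2(p_threshold)` and `x = +/- log2(fc_cutoff)`; points are
#' coloured blue (decreased: FC below `1/fc_cutoff` with significant
#' t-test), red (increased), or black (neither) with strict inequalities,
#' mirroring the status column of [call_daps()]. p-values of exactly zero
#' are clamped to `y_max`, marked by an annotation.
#'
#' @param stats A result table from [run_comparisons()], one treatment's
#'   rows (or pass `treatment` to select).
#' @param treatment Optional treatment label to filter `stats` by.
#' @param p_threshold,fc_cutoff Thresholds drawn on the plot (defaults 0.05
#'   and 2); should match those used in calling.
#' @param y_max Clamp for `-log2(p)` when `p == 0` (default 52.9, i.e.
#'   p = 1e-16 on the base-2 axis).
#' @param path Optional output stem; when given the figure is written via
#'   [save_figure()] and the plotted table as `<stem>.tsv`.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
volcano <- function(stats, treatment = NULL, p_threshold = 0.05,
                    fc_cutoff = 2, y_max = -log2(1e-16), path = NULL) {
  if (!is.null(treatment)) stats <- stats[stats$treatment == treatment, ]
  if (nrow(stats) == 0L) stop("no rows to plot")
  sig <- stats$t_p < p_threshold
  lfc_cut <- log2(fc_cutoff)
  df <- data.frame(
    accession = stats$accession,
    log2fc = stats$log2fc,
    neg_log2_p = ifelse(stats$t_p == 0, y_max, pmin(-log2(stats$t_p), y_max)),
    clamped = stats$t_p == 0,
    class = factor(ifelse(sig & stats$log2fc > lfc_cut, "increased",
                          ifelse(sig & stats$log2fc < -lfc_cut, "decreased",
                                 "not significant")),
                   levels = c("decreased", "increased", "not significant")),
    stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log2fc, y = neg_log2_p,
                                        colour = class)) +
    ggplot2::geom_hline(yintercept = -log2(p_threshold), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 1.6, alpha = 0.85) +
    ggplot2::scale_colour_manual(
      values = c(decreased = "#2166ac", increased = "#b2182b",
                 `not significant` = "black"), drop = FALSE) +
    ggplot2::labs(x = expression(log[2] ~ "(FC)"),
                  y = expression(-log[2] ~ "(p)"),
                  colour = NULL,
                  title = if (!is.null(treatment))
                    paste("treatment", treatment, "vs control") else NULL) +
    ggplot2::theme_classic()
  if (any(df$clamped)) {
    p <- p + ggplot2::annotate("text", x = min(df$log2fc), y = y_max,
                               hjust = 0, vjust = 1, size = 3,
                               label = paste0("p = 0 clamped to y = ",
                                              signif(y_max, 4)))
  }
  if (!is.null(path)) {
    save_figure(p, path)
    write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(p))
  }
  p
}

#' Significance line position on the -log2(p) axis
#'
#' @param p_threshold p-value threshold.
#' @return `-log2(p_threshold)`; 4.3219 for the conventional 0.05.
#' @export
volcano_significance_line <- function(p_threshold = 0.05) -log2(p_threshold)

#' Heat map of relative abundance for an annotation category
#'
#' Rows are the proteins of one category (labelled by display name, falling
#' back to the protein name and then the accession), columns are treatments
#' plus control. The cell value is the per-group mean of normalized log2
#' abundances, centred per row, so colour encodes relative abundance across
#' groups; DAP cells are marked with an asterisk. Cell values are invariant
#' to replicate column order. Row order is deterministic: alphabetical by
#' accession within the category.
#'
#' @param norm A normalized [log_matrix()].
#' @param annotation Annotation `data.frame` as from [read_annotation()].
#' @param category Category label to plot.
#' @param stats Result table from [run_comparisons()], used for the DAP
#'   asterisks.
#' @param path Optional output stem, as in [volcano()].
#' @return The ggplot object; the long-format cell table is attached as
#'   attribute `"table"`.
#' @export
heatmap_abundance <- function(norm, annotation, category, stats,
                              path = NULL) {
  stopifnot(inherits(norm, "log_matrix"))
  acc <- sort(intersect(annotation$accession[annotation$category == category],
                        norm$proteins$accession))
  if (length(acc) == 0L) {
    stop("no proteins in category '", category, "'")
  }
  design <- norm$design
  groups <- unique(design$group)
  grp_mean <- vapply(groups, function(g) {
    cols <- design$run[design$group == g]
    rowMeans(norm$values[acc, cols, drop = FALSE])
  }, numeric(length(acc)))
  if (is.null(dim(grp_mean))) grp_mean <- matrix(grp_mean, nrow = 1L,
                                                 dimnames = list(acc, groups))
  centred <- grp_mean - rowMeans(grp_mean)
  idx <- match(acc, norm$proteins$accession)
  disp <- annotation$display_name[match(acc, annotation$accession)]
  disp <- ifelse(!is.na(disp) & nzchar(disp), disp,
                 ifelse(!is.na(norm$proteins$name[idx]) &
                          nzchar(norm$proteins$name[idx]),
                        norm$proteins$name[idx], acc))
  long <- expand.grid(accession = acc, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- centred[cbind(match(long$accession, acc),
                              match(long$group, groups))]
  long$label <- disp[match(long$accession, acc)]
  long$dap <- vapply(seq_len(nrow(long)), function(i) {
    hit <- stats$accession == long$accession[i] &
      stats$treatment == long$group[i] & stats$status != "ns"
    any(hit)
  }, logical(1L))
  long$group <- factor(long$group, levels = groups)
  long$label <- factor(long$label, levels = rev(disp[order(acc)]))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = group, y = label,
                                          fill = value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(dap, "*", "")),
                       size = 5, vjust = 0.75) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "relative\nabundance",
                  title = category) +
    ggplot2::theme_minimal()
  attr(p, "table") <- long
  if (!is.null(path)) {
    save_figure(p, path)
    write.table(long, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(p))
  }
  p
}

#' Per-category DAP counts by treatment and direction
#'
#' @param stats A result table from [run_comparisons()].
#' @param annotation Annotation `data.frame` as from [read_annotation()];
#'   accessions not in the map are counted under `"unannotated"`.
#' @return `data.frame` with columns `category`, `treatment`, `up`, `down`,
#'   `total`; totals over categories equal the per-treatment DAP counts.
#' @export
category_summary <- function(stats, annotation) {
  cat_of <- annotation$category[match(stats$accession, annotation$accession)]
  cat_of[is.na(cat_of)] <- "unannotated"
  agg <- stats
  agg$category <- cat_of
  out <- do.call(rbind, lapply(split(agg, list(agg$category, agg$treatment),
                                     drop = TRUE), function(s) {
    data.frame(category = s$category[1L], treatment = s$treatment[1L],
               up = sum(s$status == "up"), down = sum(s$status == "down"),
               total = sum(s$status != "ns"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$category, out$treatment), ]
}

#' Save a ggplot as PNG (and SVG where supported)
#'
#' Writes `<stem>.png` always and `<stem>.svg` when the graphics device is
#' available, so every figure has a raster and an editable vector form.
#'
#' @param plot A ggplot object.
#' @param stem Output path without extension.
#' @param width,height Size in inches.
#' @return Character vector of files written, invisibly.
#' @export
save_figure <- function(plot, stem, width = 6, height = 5) {
  files <- character()
  png_file <- paste0(stem, ".png")
  png(png_file, width = width, height = height, units = "in", res = 150)
  print(plot)
  dev.off()
  files <- png_file
  if (isTRUE(capabilities("cairo"))) {
    svg_file <- paste0(stem, ".svg")
    svg(svg_file, width = width, height = height)
    print(plot)
    dev.off()
    files <- c(files, svg_file)
  }
  invisible(files)
}
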