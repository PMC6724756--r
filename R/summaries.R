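#' Region-level expression and co-expression summary
#'
#' Computes, from positivity flags alone, the region statistics the
#' workflow reports: percent of all DAPI-defined cells positive per probe,
#' conditional co-expression percentages (for every ordered channel pair
#' `(A|B)`, the percent of B-positive cells that are also A-positive), and
#' the co-expression class counts (one class per subset of channels,
#' including "none").
#'
#' Denominator discipline: `percent_positive` always uses all cells of the
#' region; the conditional percentage `(A|B)` uses B-positive cells and is
#' reported as `NA` (missing, not 0) when no cell is B-positive.
#'
#' @param cell_table A [build_cell_table()] result.
#' @param region Region name to summarize, or `NULL` for all cells pooled.
#'   An unknown region is an error.
#' @return A list of class `region_summary` with `region`, `n_cells`,
#'   `percent_positive` (named vector), `conditional` (matrix, entry
#'   `[A, B]` = % of B-positive cells that are A-positive), and
#'   `class_counts` (named vector over channel subsets; names join channel
#'   names with `+`, the empty subset is `"none"`).
#' @export
summarize_region <- function(cell_table, region = NULL) {
  flags <- .positivity_flags(cell_table, region)
  channels <- colnames(flags)
  n <- nrow(flags)
  pct <- 100 * colMeans(flags)
  k <- length(channels)
  cond <- matrix(NA_real_, k, k, dimnames = list(channels, channels))
  for (b in seq_len(k)) {
    nb <- sum(flags[, b])
    if (nb > 0) for (a in seq_len(k)) if (a != b)
      cond[a, b] <- 100 * sum(flags[, a] & flags[, b]) / nb
  }
  cls <- .class_labels(channels)
  counts <- integer(length(cls$labels))
  names(counts) <- cls$labels
  if (n > 0) {
    code <- as.integer(flags %*% 2L^(seq_len(k) - 1L))
    tabs <- tabulate(code + 1L, nbins = 2L^k)
    counts[] <- tabs[cls$order]
  }
  structure(list(region = region, n_cells = n, percent_positive = pct,
                 conditional = cond, class_counts = counts),
            class = "region_summary")
}

# positivity flag matrix (cells x channels) for a region
.positivity_flags <- function(cell_table, region = NULL) {
  if (!inherits(cell_table, "cell_table"))
    stop("cell_table must come from build_cell_table()", call. = FALSE)
  channels <- attr(cell_table, "channels")
  rows <- cell_table
  if (!is.null(region)) {
    known <- unique(cell_table$region[!is.na(cell_table$region)])
    if (!region %in% known) stop("unknown region: ", region, call. = FALSE)
    rows <- cell_table[!is.na(cell_table$region) & cell_table$region == region, ]
  }
  m <- vapply(channels, function(ch) as.logical(rows[[paste0("positive_", ch)]]),
              logical(nrow(rows)))
  matrix(m, nrow = nrow(rows), ncol = length(channels),
         dimnames = list(NULL, channels))
}

# subset labels in canonical order: by size then channel order; "none" first
.class_labels <- function(channels) {
  k <- length(channels)
  codes <- 0:(2^k - 1)
  size <- vapply(codes, function(x) sum(bitwAnd(x, 2L^(0:(k - 1))) > 0), 0L)
  ord <- order(size, codes)
  labels <- vapply(codes[ord], function(x) {
    on <- channels[bitwAnd(x, 2L^(seq_len(k) - 1L)) > 0]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }, "")
  list(labels = labels, order = codes[ord] + 1L)
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region summary%s: %d cells\n",
              if (is.null(x$region)) "" else paste0(" [", x$region, "]"),
              x$n_cells))
  cat("  % positive:",
      paste(sprintf("%s %.1f%%", names(x$percent_positive), x$percent_positive),
            collapse = ", "), "\n")
  nz <- x$class_counts[x$class_counts > 0]
  if (length(nz))
    cat("  classes:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Percent-positive table by region and channel
#'
#' The heatmap quantity: for every region and channel, the percent of all
#' DAPI-defined cells called positive. Regions where the applicability rule
#' fails for a channel (mean foci per cell below `min_mean_foci`, or the
#' region marked not separable) are explicitly not quantified and carry
#' `NA` in the percent matrix with the reason recorded, mirroring the
#' exclusion of too-sparse or too-dense regions rather than reporting a
#' misleading number.
#'
#' @param cell_table A [build_cell_table()] result with region membership.
#' @param regions Regions to tabulate (default: all regions present).
#' @param min_mean_foci Applicability threshold in mean dots per cell
#'   (default 4); `NULL` disables the rule.
#' @param separable Optional named logical vector (per region) of
#'   separability verdicts; regions absent from it are assumed separable.
#' @return A list of class `heatmap_table`: `percent` (region x channel
#'   matrix, `NA` where not quantified), `quantified` (logical matrix) and
#'   `reason` (character matrix).
#' @export
heatmap_table <- function(cell_table, regions = NULL, min_mean_foci = 4,
                          separable = NULL) {
  if (!inherits(cell_table, "cell_table"))
    stop("cell_table must come from build_cell_table()", call. = FALSE)
  if (is.null(regions)) {
    regions <- unique(cell_table$region[!is.na(cell_table$region)])
    if (length(regions) == 0)
      stop("cell table has no region membership", call. = FALSE)
  }
  channels <- attr(cell_table, "channels")
  pct <- matrix(NA_real_, length(regions), length(channels),
                dimnames = list(regions, channels))
  quant <- matrix(TRUE, length(regions), length(channels),
                  dimnames = list(regions, channels))
  reason <- matrix("ok", length(regions), length(channels),
                   dimnames = list(regions, channels))
  for (rg in regions) {
    smry <- summarize_region(cell_table, rg)
    for (ch in channels) {
      sep <- if (!is.null(separable) && rg %in% names(separable))
        separable[[rg]] else TRUE
      if (!is.null(min_mean_foci)) {
        ap <- applicability_check(cell_table, ch, rg,
                                  min_mean_foci = min_mean_foci,
                                  separable = sep)
        quant[rg, ch] <- ap$quantifiable
        reason[rg, ch] <- ap$reason
      }
      if (quant[rg, ch]) pct[rg, ch] <- smry$percent_positive[[ch]]
    }
  }
  structure(list(percent = pct, quantified = quant, reason = reason),
            class = "heatmap_table")
}

#' @export
print.heatmap_table <- function(x, ...) {
  cat("Percent of cells positive by region (n.q. = not quantified):\n")
  disp <- matrix(sprintf("%.1f", x$percent), nrow(x$percent),
                 dimnames = dimnames(x$percent))
  disp[!x$quantified] <- "n.q."
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Label each cell with its co-expression class
#'
#' Assigns every cell the subset of channels it is positive for, the
#' classification used to colour multiplex composites (single positives,
#' pairwise co-expression, triple expression, or none). The assay carries
#' at most three probe channels, so tables with more channels are rejected.
#'
#' @param cell_table A [build_cell_table()] result with 1-3 channels.
#' @return A factor of length `nrow(cell_table)` whose levels are all
#'   channel subsets in canonical order (`"none"`, singles, pairs joined
#'   with `+`, the full triple).
#' @export
classify_cells <- function(cell_table) {
  flags <- .positivity_flags(cell_table)
  channels <- colnames(flags)
  if (length(channels) > 3)
    stop("at most 3 probe channels are supported by the assay", call. = FALSE)
  cls <- .class_labels(channels)
  code <- as.integer(flags %*% 2L^(seq_along(channels) - 1L))
  lab <- vapply(code, function(x) {
    on <- channels[bitwAnd(x, 2L^(seq_along(channels) - 1L)) > 0]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }, "")
  factor(lab, levels = cls$labels)
}
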