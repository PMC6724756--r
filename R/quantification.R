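#' Assign detected foci to cell territories
#'
#' Each focus is attributed to the cell territory that owns its pixel
#' (territories are disjoint, so ownership is unambiguous); foci landing on
#' background pixels are counted as strays and belong to no cell. The
#' conservation identity `sum(counts) + strays == nrow(foci)` holds by
#' construction.
#'
#' @param foci A `focus_set` (or data frame with `row`, `col`).
#' @param cells Integer cell label matrix (e.g. from [dilate_labels()]).
#' @return List with `counts` (integer vector indexed by cell id 1..n) and
#'   `strays` (number of background foci).
#' @export
assign_foci <- function(foci, cells) {
  .check_label_map(cells)
  n <- .n_labels(cells)
  if (nrow(foci) > 0) {
    if (any(foci$row < 1 | foci$row > nrow(cells) |
            foci$col < 1 | foci$col > ncol(cells)))
      stop("focus coordinates fall outside the label map", call. = FALSE)
    lab <- cells[cbind(foci$row, foci$col)]
  } else lab <- integer(0)
  list(counts = tabulate(lab[lab > 0], nbins = n),
       strays = sum(lab == 0))
}

#' Call per-cell positivity from focus counts
#'
#' A cell is positive for a probe when it contains at least `threshold`
#' foci; the workflow's rule is three or more.
#'
#' @param counts Non-negative integer focus counts.
#' @param threshold Minimum count for a positive call (default 3).
#' @return Logical vector, `TRUE` where `counts >= threshold`.
#' @examples
#' call_positive(c(0, 2, 3, 7))  # FALSE FALSE TRUE TRUE
#' @export
call_positive <- function(counts, threshold = 3L) {
  if (length(threshold) != 1L || threshold < 1 || threshold != round(threshold))
    stop("threshold must be a positive integer", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  counts >= threshold
}

#' Build the per-cell quantification table
#'
#' One row per cell: nucleus centroid and area, region membership (the
#' region containing the centroid pixel), border contact, and per-channel
#' focus counts and positivity flags. This is the central tabular product of
#' the workflow from which all summaries derive.
#'
#' @param nuclei Nucleus label matrix from [segment_nuclei()].
#' @param cells Matching cell label matrix from [dilate_labels()] (same
#'   label set).
#' @param focus_sets Named list of `focus_set` objects, one per probe
#'   channel.
#' @param regions Optional named list of logical/0-1 mask matrices (same
#'   geometry) delimiting anatomical areas; masks must not overlap. A cell
#'   whose centroid lies outside every mask gets region `NA`.
#' @param threshold Positivity threshold applied to every channel
#'   (default 3).
#' @return A data frame of class `cell_table` with columns `cell_id`,
#'   `row`, `col` (centroid, 1-based), `nucleus_area`, `region`, `border`
#'   and, per channel `X`, `count_X` and `positive_X`. Attributes:
#'   `channels`, `threshold`, `strays` (named per-channel stray counts).
#'   Rows are ordered by `cell_id`.
#' @export
build_cell_table <- function(nuclei, cells, focus_sets, regions = NULL,
                             threshold = 3L) {
  .check_label_map(nuclei, "nucleus label map")
  .check_label_map(cells, "cell label map")
  if (!all(dim(nuclei) == dim(cells)))
    stop("nucleus and cell label maps must share geometry", call. = FALSE)
  n <- .n_labels(nuclei)
  if (!identical(sort(unique(as.integer(cells[cells > 0]))), seq_len(n)))
    stop("cell label set must match the nucleus label set", call. = FALSE)
  if (is.null(names(focus_sets)) || anyDuplicated(names(focus_sets)))
    stop("focus_sets must be a uniquely named list", call. = FALSE)
  channels <- names(focus_sets)

  if (!is.null(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("regions must be a uniquely named list of masks", call. = FALSE)
    for (nm in names(regions)) {
      m <- regions[[nm]]
      if (!all(dim(m) == dim(nuclei)))
        stop("region mask '", nm, "' does not match the image geometry",
             call. = FALSE)
    }
    nms <- names(regions)
    if (length(nms) > 1) {
      for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
        if (any(regions[[i]] > 0 & regions[[j]] > 0))
          stop(sprintf("region masks overlap: '%s' and '%s'", nms[i], nms[j]),
               call. = FALSE)
      }
    }
  }

  # centroids, areas, border contact from the nucleus map
  cent_r <- cent_c <- area <- numeric(n)
  border <- logical(n)
  if (n > 0) {
    pos <- which(nuclei > 0, arr.ind = TRUE)
    lab <- nuclei[pos]
    cent_r <- tapply(pos[, 1], factor(lab, levels = seq_len(n)), mean)
    cent_c <- tapply(pos[, 2], factor(lab, levels = seq_len(n)), mean)
    area <- as.numeric(tabulate(lab, nbins = n))
    on_border <- pos[, 1] == 1 | pos[, 1] == nrow(nuclei) |
      pos[, 2] == 1 | pos[, 2] == ncol(nuclei)
    border[sort(unique(lab[on_border]))] <- TRUE
  }

  region <- rep(NA_character_, n)
  if (!is.null(regions) && n > 0) {
    pr <- pmin(nrow(nuclei), pmax(1, floor(cent_r + 0.5)))
    pc <- pmin(ncol(nuclei), pmax(1, floor(cent_c + 0.5)))
    for (nm in names(regions)) {
      hit <- regions[[nm]][cbind(pr, pc)] > 0
      region[hit] <- nm
    }
  }

  tab <- data.frame(cell_id = seq_len(n), row = as.numeric(cent_r),
                    col = as.numeric(cent_c), nucleus_area = area,
                    region = region, border = border)
  strays <- integer(0)
  for (ch in channels) {
    a <- assign_foci(focus_sets[[ch]], cells)
    tab[[paste0("count_", ch)]] <- a$counts
    tab[[paste0("positive_", ch)]] <- call_positive(a$counts, threshold)
    strays[ch] <- a$strays
  }
  rownames(tab) <- NULL
  attr(tab, "channels") <- channels
  attr(tab, "threshold") <- as.integer(threshold)
  attr(tab, "strays") <- strays
  class(tab) <- c("cell_table", class(tab))
  tab
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("Cell table: %d cells, channels: %s (positivity >= %d foci)\n",
              nrow(x), paste(attr(x, "channels"), collapse = ", "),
              attr(x, "threshold")))
  print.data.frame(utils::head(x, 10), digits = 4, ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Decide whether per-cell quantification applies to a region
#'
#' The workflow's applicability rule: quantitative analysis is not applied
#' where the channel's expression is below 4 dots per DAPI-defined cell
#' (mean focus count over *all* cells of the region) or where cell bodies
#' could not be separated. The failed criterion is named in the verdict.
#'
#' @param cell_table A [build_cell_table()] result.
#' @param channel Channel to assess (must exist in the table).
#' @param region Restrict to this region (default: all cells).
#' @param min_mean_foci Minimum mean foci per cell (default 4).
#' @param separable Separability verdict for the region, e.g.
#'   `separability_check(...)$separable` (default `TRUE`).
#' @return List of class `applicability_check` with `channel`, `region`,
#'   `n_cells`, `mean_foci`, `quantifiable` and `reason` (`"ok"`,
#'   `"below 4 dots per cell"` with the configured minimum, or
#'   `"cell bodies not separable"`).
#' @export
applicability_check <- function(cell_table, channel, region = NULL,
                                min_mean_foci = 4, separable = TRUE) {
  if (!inherits(cell_table, "cell_table"))
    stop("cell_table must come from build_cell_table()", call. = FALSE)
  if (!channel %in% attr(cell_table, "channels"))
    stop("unknown channel: ", channel, call. = FALSE)
  rows <- if (is.null(region)) cell_table else
    cell_table[!is.na(cell_table$region) & cell_table$region == region, ]
  if (nrow(rows) == 0)
    stop("no cells in region ", region %||% "<all>", call. = FALSE)
  mean_foci <- mean(rows[[paste0("count_", channel)]])
  if (!isTRUE(separable)) {
    quant <- FALSE; reason <- "cell bodies not separable"
  } else if (mean_foci < min_mean_foci) {
    quant <- FALSE
    reason <- sprintf("below %g dots per cell", min_mean_foci)
  } else {
    quant <- TRUE; reason <- "ok"
  }
  structure(list(channel = channel, region = region, n_cells = nrow(rows),
                 mean_foci = mean_foci, min_mean_foci = min_mean_foci,
                 quantifiable = quant, reason = reason),
            class = "applicability_check")
}

#' @export
print.applicability_check <- function(x, ...) {
  cat(sprintf("Applicability [%s%s]: %s (%.2f foci/cell over %d cells; %s)\n",
              x$channel, if (is.null(x$region)) "" else paste0(" in ", x$region),
              if (x$quantifiable) "quantifiable" else "NOT quantifiable",
              x$mean_foci, x$n_cells, x$reason))
  invisible(x)
}
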