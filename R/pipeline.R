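#' Configuration for an end-to-end quantification run
#'
#' Collects every parameter of the workflow so a run is fully reproducible
#' from its configuration: the image stack and channel mapping, per-channel
#' detection tolerances, segmentation settings, the dilation radius and the
#' positivity threshold, plus optional named region masks.
#'
#' @param image Path to a multi-page TIFF, or a named list of channel
#'   matrices (as returned by [read_image_stack()] or
#'   `simulate_image()$images`).
#' @param channels Character vector of channel names in page order (ignored
#'   with a named list input, where names are taken from the list).
#' @param dapi Name of the nuclear channel; must match exactly one channel.
#' @param detection Named list, one entry per probe channel:
#'   `list(tolerance =, sigma = 1, exclude_border = 0)`. Tolerance is
#'   mandatory and sample-specific. Probe channels are all non-DAPI
#'   channels with a detection entry.
#' @param segmentation List of [segment_nuclei()] settings
#'   (`min_area`, `smoothing_sigma`, `seed_tolerance`, `min_bimodality`).
#' @param dilation_radius Cell-territory expansion in pixels (default 3).
#' @param positivity_threshold Foci needed for a positive call (default 3).
#' @param min_mean_foci Applicability threshold in dots per cell
#'   (default 4).
#' @param regions Optional named list: mask matrices, or paths to
#'   single-page mask TIFFs (non-zero = inside).
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @return A validated list of class `run_config`.
#' @seealso [run_pipeline()], [read_run_config()]
#' @export
run_config <- function(image, channels = NULL, dapi = "DAPI",
                       detection = list(), segmentation = list(),
                       dilation_radius = 3, positivity_threshold = 3L,
                       min_mean_foci = 4, regions = NULL,
                       output_dir = NULL) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("image not found: ", image, call. = FALSE)
    if (is.null(channels)) stop("channels must be given for a TIFF path",
                                call. = FALSE)
  } else if (is.list(image)) {
    if (is.null(names(image)) || anyDuplicated(names(image)))
      stop("in-memory image must be a uniquely named list of matrices",
           call. = FALSE)
    channels <- names(image)
  } else stop("image must be a path or a named list of matrices", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel names must be unique", call. = FALSE)
  if (sum(channels == dapi) != 1L)
    stop("exactly one channel must be designated as DAPI ('", dapi,
         "' not found)", call. = FALSE)
  probes <- names(detection)
  if (length(probes) == 0)
    stop("detection settings must name at least one probe channel",
         call. = FALSE)
  if (!all(probes %in% setdiff(channels, dapi)))
    stop("detection names must be non-DAPI channels", call. = FALSE)
  for (ch in probes) {
    d <- detection[[ch]]
    if (is.null(d$tolerance) || d$tolerance <= 0)
      stop("a positive detection tolerance is required for channel ", ch,
           call. = FALSE)
    detection[[ch]]$sigma <- d$sigma %||% 1
    detection[[ch]]$exclude_border <- d$exclude_border %||% 0L
  }
  seg <- list(min_area = segmentation$min_area %||% 20,
              smoothing_sigma = segmentation$smoothing_sigma %||% 1,
              seed_tolerance = segmentation$seed_tolerance %||% 1,
              min_bimodality = segmentation$min_bimodality %||% 0.75)
  if (!is.null(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("regions must be uniquely named", call. = FALSE)
    for (nm in names(regions)) {
      rg <- regions[[nm]]
      if (is.character(rg) && !file.exists(rg))
        stop("region mask not found: ", rg, call. = FALSE)
    }
  }
  structure(list(image = image, channels = channels, dapi = dapi,
                 detection = detection, segmentation = seg,
                 dilation_radius = dilation_radius,
                 positivity_threshold = as.integer(positivity_threshold),
                 min_mean_foci = min_mean_foci,
                 regions = regions, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the [run_config()] arguments; relative paths are resolved
#' against the configuration file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) if (is.character(p) && !file.exists(p) &&
                             file.exists(file.path(base, p)))
    file.path(base, p) else p
  cfg$image <- resolve(cfg$image)
  if (!is.null(cfg$regions)) cfg$regions <- lapply(cfg$regions, resolve)
  det <- lapply(cfg$detection, function(d) as.list(d))
  run_config(image = cfg$image, channels = cfg$channels,
             dapi = cfg$dapi %||% "DAPI", detection = det,
             segmentation = as.list(cfg$segmentation),
             dilation_radius = cfg$dilation_radius %||% 3,
             positivity_threshold = cfg$positivity_threshold %||% 3L,
             min_mean_foci = cfg$min_mean_foci %||% 4,
             regions = cfg$regions, output_dir = cfg$output_dir)
}

#' Run the full quantification pipeline
#'
#' Executes the end-to-end workflow on one image stack: segment nuclei from
#' the DAPI channel, expand them into cell territories, detect foci in each
#' probe channel (Gaussian filter + tolerance maxima), count foci per cell,
#' call positivity, and summarize per region. Identical configuration and
#' inputs produce byte-identical outputs. Stage failures are reported with
#' the stage name.
#'
#' When `output_dir` is set, writes: `cells.csv` (the cell table),
#' `foci_<channel>.csv`, `labels_nuclei.tif` and `labels_cells.tif` (16-bit
#' label images), `heatmap.csv`, `summary.json` (region summaries) and
#' `qc.json` (every parameter of the run plus conservation and
#' separability diagnostics).
#'
#' @param config A [run_config()].
#' @return A list of class `rnaquant_run`: `cell_table`, `foci` (named list
#'   of focus sets), `nuclei` and `cells` (label maps), `summaries` (named
#'   list of `region_summary`, plus `"all"` when no regions are given),
#'   `heatmap` (or `NULL` without regions), `separability`, `qc`, and
#'   `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("config must come from run_config()", call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  images <- stage("read", {
    if (is.character(config$image))
      read_image_stack(config$image, config$channels)
    else lapply(config$image, function(m) { .check_image(m); m })
  })
  regions <- stage("read", {
    if (is.null(config$regions)) NULL else
      lapply(config$regions, function(rg) {
        if (is.character(rg)) {
          m <- tiff::readTIFF(rg, as.is = TRUE)
          if (length(dim(m)) != 2L)
            stop("region masks must be single-plane, single-channel")
          matrix(as.numeric(m > 0), nrow(m), ncol(m))
        } else matrix(as.numeric(rg > 0), nrow(rg), ncol(rg))
      })
  })

  seg <- config$segmentation
  nuclei <- stage("segmentation",
    segment_nuclei(images[[config$dapi]], min_area = seg$min_area,
                   smoothing_sigma = seg$smoothing_sigma,
                   seed_tolerance = seg$seed_tolerance,
                   min_bimodality = seg$min_bimodality))
  sep <- stage("segmentation", separability_check(nuclei))
  cells <- stage("dilation", dilate_labels(nuclei, config$dilation_radius))

  foci <- stage("detection", {
    out <- list()
    for (ch in names(config$detection)) {
      d <- config$detection[[ch]]
      out[[ch]] <- detect_foci(images[[ch]], tolerance = d$tolerance,
                               sigma = d$sigma,
                               exclude_border = d$exclude_border,
                               channel = ch)
    }
    out
  })

  cell_table <- stage("quantification",
    build_cell_table(nuclei, cells, foci, regions = regions,
                     threshold = config$positivity_threshold))

  summaries <- stage("summaries", {
    if (is.null(regions)) list(all = summarize_region(cell_table)) else {
      rgs <- unique(cell_table$region[!is.na(cell_table$region)])
      stats::setNames(lapply(rgs, summarize_region, cell_table = cell_table),
                      rgs)
    }
  })
  heat <- stage("summaries", {
    if (is.null(regions)) NULL else {
      sep_by_region <- stats::setNames(
        rep(sep$separable, length(summaries)), names(summaries))
      heatmap_table(cell_table, names(summaries),
                    min_mean_foci = config$min_mean_foci,
                    separable = sep_by_region)
    }
  })

  qc <- list(
    parameters = list(
      channels = config$channels, dapi = config$dapi,
      detection = config$detection, segmentation = seg,
      dilation_radius = config$dilation_radius,
      positivity_threshold = config$positivity_threshold,
      min_mean_foci = config$min_mean_foci),
    n_nuclei = attr(nuclei, "n_nuclei"),
    separability = list(separable = sep$separable,
                        fused_fraction = sep$fused_fraction,
                        area_ceiling = sep$area_ceiling),
    foci = lapply(foci, nrow),
    strays = as.list(attr(cell_table, "strays")),
    conservation_ok = all(vapply(names(foci), function(ch)
      sum(cell_table[[paste0("count_", ch)]]) +
        attr(cell_table, "strays")[[ch]] == nrow(foci[[ch]]), TRUE)))

  paths <- character(0)
  if (!is.null(config$output_dir))
    paths <- .write_run_outputs(config$output_dir, cell_table, foci,
                                nuclei, cells, summaries, heat, qc)

  structure(list(cell_table = cell_table, foci = foci, nuclei = nuclei,
                 cells = cells, summaries = summaries, heatmap = heat,
                 separability = sep, qc = qc, paths = paths),
            class = "rnaquant_run")
}

.write_run_outputs <- function(dir, cell_table, foci, nuclei, cells,
                               summaries, heat, qc) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             qc = file.path(dir, "qc.json"),
             summary = file.path(dir, "summary.json"),
             labels_nuclei = file.path(dir, "labels_nuclei.tif"),
             labels_cells = file.path(dir, "labels_cells.tif"))
  tab <- as.data.frame(cell_table)
  .write_csv(tab, paths[["cells"]])
  for (ch in names(foci)) {
    p <- file.path(dir, paste0("foci_", ch, ".csv"))
    .write_csv(as.data.frame(foci[[ch]]), p)
    paths[paste0("foci_", ch)] <- p
  }
  .write_stack(list(nuclei = matrix(as.numeric(nuclei), nrow(nuclei))),
               paths[["labels_nuclei"]])
  .write_stack(list(cells = matrix(as.numeric(cells), nrow(cells))),
               paths[["labels_cells"]])
  if (!is.null(heat)) {
    paths["heatmap"] <- file.path(dir, "heatmap.csv")
    hm <- as.data.frame(heat$percent)
    hm[!heat$quantified] <- NA
    hm <- cbind(region = rownames(heat$percent), hm)
    .write_csv(hm, paths[["heatmap"]])
  }
  smry <- lapply(summaries, function(s) list(
    region = s$region %||% "all", n_cells = s$n_cells,
    percent_positive = as.list(s$percent_positive),
    conditional = s$conditional, class_counts = as.list(s$class_counts)))
  jsonlite::write_json(smry, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "rowmajor")
  jsonlite::write_json(qc, paths[["qc"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths
}

#' @export
print.rnaquant_run <- function(x, ...) {
  cat(sprintf("RNAscope quantification run: %d cells, channels: %s\n",
              nrow(x$cell_table),
              paste(attr(x$cell_table, "channels"), collapse = ", ")))
  for (ch in names(x$foci))
    cat(sprintf("  %s: %d foci (%d stray), %d positive cells\n", ch,
                nrow(x$foci[[ch]]), attr(x$cell_table, "strays")[[ch]],
                sum(x$cell_table[[paste0("positive_", ch)]])))
  print(x$separability)
  if (!is.null(x$heatmap)) print(x$heatmap)
  if (length(x$paths)) cat("Outputs in:", dirname(x$paths[[1]]), "\n")
  invisible(x)
}

#' @export
summary.rnaquant_run <- function(object, ...) {
  print(object)
  for (s in object$summaries) print(s)
  invisible(object)
}
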