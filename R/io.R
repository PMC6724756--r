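#' Read a multi-page TIFF as named channel images
#'
#' Reads one single-plane image per TIFF page and names the pages with the
#' supplied channel mapping. Integer samples of any bit depth are returned
#' as stored (no rescaling); floating-point samples are returned as-is.
#' Multi-sample (e.g. RGB) or volumetric pages are rejected: the workflow
#' operates on single optical planes only.
#'
#' @param path Path to a TIFF file.
#' @param channel_names Character vector, one name per page, in page order.
#' @return A named list of numeric matrices.
#' @seealso [write_fixture()] writes stacks this function reads back
#'   identically.
#' @export
read_image_stack <- function(path, channel_names) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_names))
    stop(sprintf("%s has %d pages but %d channel names were given",
                 path, length(pages), length(channel_names)), call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique", call. = FALSE)
  out <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) != 2L)
      stop(sprintf("page %d of %s is not a single-plane single-channel image; %s",
                   i, path,
                   "multi-sample or volumetric input must be split upstream"),
           call. = FALSE)
    storage.mode(p) <- "double"
    p
  })
  names(out) <- channel_names
  out
}

# write named integer-valued channel images as one multi-page 16-bit TIFF
.write_stack <- function(images, path, max_intensity = 65535) {
  pages <- lapply(images, function(m) {
    if (any(m < 0) || any(m > max_intensity) || any(m != round(m)))
      stop("images must be integer-valued in [0, max_intensity] for 16-bit storage",
           call. = FALSE)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a simulated scene to disk as a reusable fixture
#'
#' Stores the image stack as a multi-page 16-bit TIFF (one page per channel)
#' with the channel order recorded in a `channels.csv` sidecar, and the
#' ground truth as plain CSV tables (`nuclei.csv`, `counts.csv`,
#' `spots.csv`). All coordinates are 1-based (row, column) pixel indices, as
#' documented in each file's header. The fixture round-trips losslessly
#' through [read_fixture()] and regenerating with the same configuration
#' produces byte-identical CSVs.
#'
#' @param sim A scene from [simulate_image()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(sim, dir) {
  if (!inherits(sim, "rnaquant_sim")) stop("sim must be an rnaquant_sim", call. = FALSE)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create fixture directory: ", dir, call. = FALSE)
  paths <- c(images = file.path(dir, "images.tif"),
             channels = file.path(dir, "channels.csv"),
             nuclei = file.path(dir, "nuclei.csv"),
             counts = file.path(dir, "counts.csv"),
             spots = file.path(dir, "spots.csv"))
  .write_stack(sim$images, paths[["images"]], sim$config$max_intensity)
  .write_csv(data.frame(page = seq_along(sim$images),
                        channel = names(sim$images)), paths[["channels"]])
  .write_csv(sim$ground_truth$nuclei, paths[["nuclei"]])
  .write_csv(sim$ground_truth$counts, paths[["counts"]])
  .write_csv(sim$ground_truth$spots, paths[["spots"]])
  invisible(paths)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A list with `images` (named matrices, exactly the pixel values
#'   written) and `ground_truth` (the three CSV tables).
#' @export
read_fixture <- function(dir) {
  chan <- .read_csv(file.path(dir, "channels.csv"))
  images <- read_image_stack(file.path(dir, "images.tif"), chan$channel)
  gt <- list(
    nuclei = .read_csv(file.path(dir, "nuclei.csv")),
    counts = .read_csv(file.path(dir, "counts.csv")),
    spots = .read_csv(file.path(dir, "spots.csv")))
  list(images = images, ground_truth = gt)
}

# deterministic CSV I/O (fixed na encoding, no row names, no quoting drift)
.write_csv <- function(df, path) {
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write: ", path, call. = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
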