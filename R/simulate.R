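#' Per-channel specification for the tissue simulator
#'
#' Describes one probe channel of a simulated scene: the per-cell transcript
#' count law and the rendered appearance of each punctum.
#'
#' Two count laws are supported. `"zip"` is a zero-inflated Poisson: a cell
#' is a structural zero ("negative" cell, no transcript cluster) with
#' probability `pi`, otherwise its count is Poisson with mean `lambda`.
#' `"fixed"` plants exactly `k` puncta in every cell, which is convenient
#' for constructing scenes with exactly known per-cell means.
#'
#' @param name Channel name (e.g. `"HCN4"`).
#' @param law `"zip"` or `"fixed"`.
#' @param pi Zero-inflation probability in \[0,1\] (ZIP law).
#' @param lambda Poisson mean, >= 0 (ZIP law).
#' @param k Exact per-cell count (fixed law).
#' @param amplitude Peak intensity of a rendered punctum above background.
#' @param sigma Punctum Gaussian width in pixels. The default (1.5) is a
#'   diffraction-limited spot at typical high-NA confocal sampling.
#' @param stray_rate Expected number of extracellular (stray) puncta per
#'   image for this channel (Poisson-distributed; default 0).
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(name, law = c("zip", "fixed"), pi = 0.2, lambda = 5,
                         k = 3L, amplitude = 120, sigma = 1.5,
                         stray_rate = 0) {
  law <- match.arg(law)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("channel name must be a non-empty string", call. = FALSE)
  if (law == "zip") {
    if (pi < 0 || pi > 1) stop("pi must be in [0, 1]", call. = FALSE)
    if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  } else {
    if (k < 0 || k != round(k)) stop("k must be a non-negative integer", call. = FALSE)
  }
  if (amplitude <= 0 || sigma <= 0 || stray_rate < 0)
    stop("amplitude and sigma must be positive, stray_rate non-negative",
         call. = FALSE)
  structure(list(name = name, law = law, pi = pi, lambda = lambda,
                 k = as.integer(k), amplitude = amplitude, sigma = sigma,
                 stray_rate = stray_rate),
            class = "channel_spec")
}

#' Configuration for a simulated multiplex FISH scene
#'
#' Defines a synthetic single-plane tissue image: DAPI-stained nuclei of
#' configurable density (allowing touching nuclei and too-dense-to-separate
#' regimes), diffraction-limited puncta planted per cell in each probe
#' channel, diffuse background, additive Gaussian noise (clipped at zero)
#' and optional uniform bright patches emulating optical aberrations.
#' Identical configurations (including `seed`) produce bit-identical
#' scenes.
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei to place (may be 0).
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius law (normal,
#'   truncated below at 3 px), in pixels.
#' @param min_center_spacing Minimum distance between nucleus centers, in
#'   pixels. Values below twice the radius force touching nuclei; values far
#'   below the diameter create regimes that watershed cannot separate. The
#'   default keeps nuclei comfortably apart.
#' @param channels List of [channel_spec()] objects (the probe channels; the
#'   DAPI channel is always generated in addition).
#' @param background_level Diffuse background intensity added to every
#'   channel.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param dapi_amplitude Peak intensity of a nucleus in the DAPI channel.
#' @param aberration_patches List of uniform patches, each
#'   `list(row, col, height, width, intensity)` (1-based corner), added to
#'   every probe channel.
#' @param min_spot_spacing Minimum distance between puncta planted in the
#'   same cell, in pixels; keeps planted spots optically resolvable so that
#'   ground-truth counts are recoverable (overlapping puncta are a known
#'   real-data feature the simulator does not model).
#' @param max_intensity Intensity ceiling; rendered images are rounded to
#'   integers and clipped to `[0, max_intensity]` (16-bit by default).
#' @param seed Integer RNG seed; part of the scene identity.
#' @return A validated list of class `simulation_config`.
#' @seealso [simulate_image()]
#' @export
simulation_config <- function(width = 448, height = 448, n_nuclei = 40,
                              nucleus_radius_mean = 16, nucleus_radius_sd = 1,
                              min_center_spacing = 2 * (nucleus_radius_mean + 2) + 2,
                              channels = list(channel_spec("probe1")),
                              background_level = 20, noise_sd = 8,
                              dapi_amplitude = 150,
                              aberration_patches = list(),
                              min_spot_spacing = 8,
                              max_intensity = 65535, seed = 1L) {
  stopifnot(width >= 8, height >= 8, n_nuclei >= 0,
            nucleus_radius_mean > 0, nucleus_radius_sd >= 0,
            min_center_spacing > 0, background_level >= 0, noise_sd >= 0,
            dapi_amplitude > 0, min_spot_spacing >= 0, max_intensity > 0)
  if (!is.list(channels) || !all(vapply(channels, inherits, TRUE, "channel_spec")))
    stop("channels must be a list of channel_spec objects", call. = FALSE)
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("channel names must be unique", call. = FALSE)
  if ("DAPI" %in% nm) stop("'DAPI' is reserved for the nuclear channel", call. = FALSE)
  for (p in aberration_patches)
    if (!all(c("row", "col", "height", "width", "intensity") %in% names(p)))
      stop("each aberration patch needs row, col, height, width, intensity",
           call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 min_center_spacing = min_center_spacing,
                 channels = channels, background_level = background_level,
                 noise_sd = noise_sd, dapi_amplitude = dapi_amplitude,
                 aberration_patches = aberration_patches,
                 min_spot_spacing = min_spot_spacing,
                 max_intensity = max_intensity, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-channel tissue scene with known ground truth
#'
#' Renders the scene described by a [simulation_config()]: one DAPI channel
#' containing a smoothly shaded disk per nucleus, and one image per probe
#' channel containing the planted puncta (2D Gaussian kernels at integer
#' pixel positions inside the owning nucleus), plus background, noise and
#' aberration patches. Every planted object is recorded in the returned
#' ground truth, which is the oracle for segmentation, detection and
#' counting tests.
#'
#' Nucleus centers are placed by rejection sampling under the
#' `min_center_spacing` constraint; an over-dense request that cannot be
#' satisfied raises an error. Puncta within one cell are planted at least
#' `min_spot_spacing` apart; if a cell is too small to hold its drawn count
#' at that spacing, the ground truth records the number actually planted
#' (counts are always counts of planted spots).
#'
#' @param config A [simulation_config()].
#' @return A list of class `rnaquant_sim` with elements:
#'   \describe{
#'     \item{images}{named list of integer-valued matrices, `DAPI` first.}
#'     \item{ground_truth}{list with data frames `nuclei`
#'       (`cell_id, row, col, radius`), `counts` (`cell_id, channel, count`,
#'       all cell/channel pairs) and `spots`
#'       (`channel, row, col, cell_id`; `cell_id` is `NA` for strays).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_image(simulation_config(n_nuclei = 5, seed = 7))
#' names(sim$images)
#' head(sim$ground_truth$counts)
#' @export
simulate_image <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config", call. = FALSE)
  .with_seed(config$seed, .simulate_scene(config))
}

.simulate_scene <- function(cf) {
  H <- cf$height; W <- cf$width
  margin <- cf$nucleus_radius_mean + 4

  # --- nuclei placement (rejection sampling) ---
  n <- cf$n_nuclei
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  if (n > 0) {
    max_attempts <- 200L * n
    attempts <- 0L
    while (nrow(centers) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not place %d nuclei with spacing %.1f in a %dx%d image (over-dense request)",
          n, cf$min_center_spacing, H, W), call. = FALSE)
      r <- max(3, rnorm(1, cf$nucleus_radius_mean, cf$nucleus_radius_sd))
      lo <- margin; hi_r <- H - margin; hi_c <- W - margin
      if (hi_r <= lo || hi_c <= lo)
        stop("image too small for the requested nucleus size", call. = FALSE)
      cand <- c(runif(1, lo, hi_r), runif(1, lo, hi_c))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= cf$min_center_spacing)) {
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
      }
    }
  }
  nuclei <- data.frame(cell_id = seq_len(n),
                       row = if (n) centers[, 1] else numeric(0),
                       col = if (n) centers[, 2] else numeric(0),
                       radius = radii)

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  # --- DAPI channel: shaded disks ---
  dapi <- matrix(0, H, W)
  disk_pixels <- vector("list", n)   # linear indices inside each nucleus
  for (i in seq_len(n)) {
    r0 <- nuclei$row[i]; c0 <- nuclei$col[i]; rad <- nuclei$radius[i]
    ri <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    dd <- outer((ri - r0)^2, (ci - c0)^2, `+`)
    inside <- dd <= rad^2
    # flat core with soft rim: bright, realistic-enough DAPI disk
    shade <- (1 - (dd / rad^2)^2)
    block <- dapi[ri, ci]
    block[inside] <- pmax(block[inside], cf$dapi_amplitude * shade[inside])
    dapi[ri, ci] <- block
    idx <- which(inside, arr.ind = TRUE)
    disk_pixels[[i]] <- cbind(ri[idx[, 1]], ci[idx[, 2]])
  }

  # --- probe channels ---
  ch_names <- vapply(cf$channels, `[[`, "", "name")
  images <- list()
  counts <- list(); spots <- list()
  in_any_dilated <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    r0 <- nuclei$row[i]; c0 <- nuclei$col[i]; rad <- nuclei$radius[i] + 3
    ri <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    dd <- outer((ri - r0)^2, (ci - c0)^2, `+`)
    idx <- which(dd <= rad^2, arr.ind = TRUE)
    in_any_dilated[cbind(ri[idx[, 1]], ci[idx[, 2]])] <- TRUE
  }

  for (sp in cf$channels) {
    img <- matrix(0, H, W)
    k_drawn <- .draw_counts(sp, n)
    ch_spots <- list()
    planted <- integer(n)
    for (i in seq_len(n)) {
      if (k_drawn[i] == 0L) next
      pos <- .place_spots(disk_pixels[[i]], k_drawn[i], cf$min_spot_spacing)
      planted[i] <- nrow(pos)
      if (planted[i] > 0) {
        img <- .render_spots(img, pos, sp$amplitude, sp$sigma)
        ch_spots[[length(ch_spots) + 1L]] <-
          data.frame(channel = sp$name, row = pos[, 1], col = pos[, 2],
                     cell_id = i)
      }
    }
    # stray (extracellular) puncta
    n_stray <- if (sp$stray_rate > 0) rpois(1, sp$stray_rate) else 0L
    if (n_stray > 0) {
      bg <- which(!in_any_dilated, arr.ind = TRUE)
      interior <- bg[bg[, 1] > 4 & bg[, 1] < H - 4 & bg[, 2] > 4 & bg[, 2] < W - 4, ,
                     drop = FALSE]
      if (nrow(interior) > 0) {
        take <- interior[sample.int(nrow(interior), min(n_stray, nrow(interior))), ,
                         drop = FALSE]
        img <- .render_spots(img, take, sp$amplitude, sp$sigma)
        ch_spots[[length(ch_spots) + 1L]] <-
          data.frame(channel = sp$name, row = take[, 1], col = take[, 2],
                     cell_id = NA_integer_)
      }
    }
    counts[[sp$name]] <- data.frame(cell_id = seq_len(n),
                                    channel = rep(sp$name, n),
                                    count = planted)
    spots[[sp$name]] <- if (length(ch_spots)) do.call(rbind, ch_spots) else
      data.frame(channel = character(0), row = numeric(0), col = numeric(0),
                 cell_id = integer(0))
    images[[sp$name]] <- img
  }

  # --- background, aberrations, noise, quantization ---
  finish <- function(img, with_patches) {
    img <- img + cf$background_level
    if (with_patches) for (p in cf$aberration_patches) {
      ri <- p$row:min(H, p$row + p$height - 1L)
      ci <- p$col:min(W, p$col + p$width - 1L)
      img[ri, ci] <- img[ri, ci] + p$intensity
    }
    if (cf$noise_sd > 0) img <- img + rnorm(length(img), 0, cf$noise_sd)
    matrix(pmin(cf$max_intensity, pmax(0, round(img))), H, W)
  }
  out_images <- c(list(DAPI = finish(dapi, FALSE)),
                  lapply(images, finish, with_patches = TRUE))

  gt_counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(cell_id = integer(0), channel = character(0), count = integer(0))
  gt_spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(channel = character(0), row = numeric(0), col = numeric(0),
               cell_id = integer(0))
  rownames(gt_counts) <- rownames(gt_spots) <- NULL

  structure(list(images = out_images,
                 ground_truth = list(nuclei = nuclei, counts = gt_counts,
                                     spots = gt_spots),
                 config = cf),
            class = "rnaquant_sim")
}

.draw_counts <- function(sp, n) {
  if (n == 0L) return(integer(0))
  if (sp$law == "fixed") return(rep(sp$k, n))
  k <- rpois(n, sp$lambda)
  k[runif(n) < sp$pi] <- 0L
  k
}

# pick k pixels from the candidate set, pairwise >= min_sep apart where
# possible; if the cell is too small to hold k spots at that spacing, the
# remainder is placed without the spacing constraint (distinct pixels), so
# the planted count always equals the drawn count
.place_spots <- function(pix, k, min_sep) {
  chosen <- matrix(integer(0), 0, 2)
  avail <- pix
  while (nrow(chosen) < k && nrow(avail) > 0) {
    j <- sample.int(nrow(avail), 1)
    p <- avail[j, , drop = FALSE]
    chosen <- rbind(chosen, p)
    if (min_sep > 0) {
      d2 <- (avail[, 1] - p[1])^2 + (avail[, 2] - p[2])^2
      avail <- avail[d2 >= min_sep^2, , drop = FALSE]
    } else avail <- avail[-j, , drop = FALSE]
  }
  if (nrow(chosen) < k) {
    taken <- paste(chosen[, 1], chosen[, 2])
    rest <- pix[!(paste(pix[, 1], pix[, 2]) %in% taken), , drop = FALSE]
    extra <- min(k - nrow(chosen), nrow(rest))
    if (extra > 0)
      chosen <- rbind(chosen, rest[sample.int(nrow(rest), extra), , drop = FALSE])
  }
  chosen
}

.render_spots <- function(img, pos, amplitude, sigma) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * sigma)
  for (s in seq_len(nrow(pos))) {
    r0 <- pos[s, 1]; c0 <- pos[s, 2]
    ri <- max(1L, r0 - r):min(H, r0 + r)
    ci <- max(1L, c0 - r):min(W, c0 + r)
    kern <- amplitude * exp(-outer((ri - r0)^2, (ci - c0)^2, `+`) / (2 * sigma^2))
    img[ri, ci] <- img[ri, ci] + kern
  }
  img
}

#' @export
print.rnaquant_sim <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("Simulated scene: %dx%d px, %d nuclei, channels: %s\n",
              x$config$height, x$config$width, nrow(gt$nuclei),
              paste(names(x$images), collapse = ", ")))
  cat(sprintf("  planted spots: %d (%d stray)\n", nrow(gt$spots),
              sum(is.na(gt$spots$cell_id))))
  invisible(x)
}

#' Closed-form tail probability of the zero-inflated Poisson count law
#'
#' `P(K >= k)` for the simulator's ZIP law: with probability `pi` the count
#' is a structural zero, otherwise Poisson(`lambda`). Used as the analytic
#' reference for positive-fraction checks.
#'
#' @param k Threshold count (the positivity rule uses `k = 3`).
#' @param pi Zero-inflation probability.
#' @param lambda Poisson mean.
#' @return `P(K >= k)` as a number.
#' @export
zip_tail <- function(k, pi, lambda) {
  if (k <= 0) return(1)
  (1 - pi) * stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Match detected foci against ground-truth spot positions
#'
#' Greedy nearest-pair matching within a radius: candidate
#' (detected, truth) pairs closer than `radius` are matched in order of
#' increasing distance, each point used at most once. Recall is
#' `matches / n_truth`, precision `matches / n_detected`.
#'
#' @param detected Data frame with `row`, `col` (e.g. a `focus_set`).
#' @param truth Data frame with `row`, `col` (e.g. `ground_truth$spots`).
#' @param radius Maximum match distance in pixels (default 2).
#' @return List with `n_detected`, `n_truth`, `n_matched`, `recall`,
#'   `precision`, and the matched index pairs.
#' @export
match_spots <- function(detected, truth, radius = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(n_detected = nd, n_truth = nt, n_matched = 0L,
                recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0,
                pairs = matrix(integer(0), 0, 2)))
  }
  d2 <- outer(detected$row, truth$row, `-`)^2 + outer(detected$col, truth$col, `-`)^2
  cand <- which(d2 <= radius^2, arr.ind = TRUE)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_d[a] && !used_t[b]) {
      used_d[a] <- used_t[b] <- TRUE
      pairs <- rbind(pairs, c(a, b))
    }
  }
  m <- nrow(pairs)
  list(n_detected = nd, n_truth = nt, n_matched = m,
       recall = m / nt, precision = m / nd, pairs = pairs)
}
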