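# Independent reference implementations used to cross-check the package.
# These are deliberately naive (exhaustive loops, per-maximum flood search)
# and share no code with the implementations they test.

# --- prominence maxima by per-maximum flood search --------------------------
# A regional-maximum plateau of value v is accepted iff a breadth-first
# flood from it over pixels with value > v - tolerance never reaches a pixel
# with value > v, and additionally v - min(img) >= tolerance.
oracle_find_maxima <- function(img, tolerance, exclude_border = 0) {
  nr <- nrow(img); nc <- ncol(img)
  vmin <- min(img)
  seen <- matrix(FALSE, nr, nc)
  out <- NULL
  neighbours <- function(i, j) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    cbind(ii[ok], jj[ok])
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seen[i, j]) next
    v <- img[i, j]
    # plateau BFS over equal-valued pixels
    plat <- matrix(c(i, j), 1)
    inplat <- matrix(FALSE, nr, nc); inplat[i, j] <- TRUE
    q <- 1; higher <- FALSE
    while (q <= nrow(plat)) {
      nb <- neighbours(plat[q, 1], plat[q, 2])
      for (t in seq_len(nrow(nb))) {
        a <- nb[t, 1]; b <- nb[t, 2]
        if (img[a, b] > v) higher <- TRUE
        else if (img[a, b] == v && !inplat[a, b]) {
          inplat[a, b] <- TRUE
          plat <- rbind(plat, c(a, b))
        }
      }
      q <- q + 1
    }
    seen[inplat] <- TRUE
    if (higher) next                       # not a regional maximum
    if (v - vmin < tolerance) next         # no sufficient relief anywhere
    # flood over pixels with value > v - tolerance
    flooded <- inplat
    fq <- plat; q <- 1; reached_higher <- FALSE
    while (q <= nrow(fq) && !reached_higher) {
      nb <- neighbours(fq[q, 1], fq[q, 2])
      for (t in seq_len(nrow(nb))) {
        a <- nb[t, 1]; b <- nb[t, 2]
        if (!flooded[a, b] && img[a, b] > v - tolerance) {
          if (img[a, b] > v) { reached_higher <- TRUE; break }
          flooded[a, b] <- TRUE
          fq <- rbind(fq, c(a, b))
        }
      }
      q <- q + 1
    }
    if (reached_higher) next
    cr <- floor(mean(plat[, 1]) + 0.5)
    cc <- floor(mean(plat[, 2]) + 0.5)
    if (exclude_border > 0 &&
        (cr <= exclude_border || cr > nr - exclude_border ||
         cc <= exclude_border || cc > nc - exclude_border)) next
    out <- rbind(out, data.frame(row = cr, col = cc, value = v))
  }
  if (is.null(out)) out <- data.frame(row = integer(0), col = integer(0),
                                      value = numeric(0))
  out[order(out$row, out$col), , drop = FALSE]
}

# --- exhaustive nearest-label assignment ------------------------------------
oracle_dilate <- function(labels, radius) {
  out <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  pos <- which(labels > 0, arr.ind = TRUE)
  if (nrow(pos) == 0 || radius == 0) return(out)
  labs <- labels[pos]
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    if (labels[i, j] > 0) next
    d2 <- (pos[, 1] - i)^2 + (pos[, 2] - j)^2
    m <- min(d2)
    if (m <= radius^2) out[i, j] <- min(labs[d2 == m])
  }
  out
}

# --- nested-loop region summary over a flag table ---------------------------
# flags: logical matrix (cells x channels)
oracle_summary <- function(flags) {
  channels <- colnames(flags)
  n <- nrow(flags)
  pct <- sapply(channels, function(ch) {
    pos <- 0
    for (i in seq_len(n)) if (flags[i, ch]) pos <- pos + 1
    100 * pos / n
  })
  k <- length(channels)
  cond <- matrix(NA_real_, k, k, dimnames = list(channels, channels))
  for (a in channels) for (b in channels) {
    if (a == b) next
    nb <- nab <- 0
    for (i in seq_len(n)) {
      if (flags[i, b]) {
        nb <- nb + 1
        if (flags[i, a]) nab <- nab + 1
      }
    }
    if (nb > 0) cond[a, b] <- 100 * nab / nb
  }
  # class counts: every subset, exact membership
  subsets <- list(integer(0))
  for (ch in seq_len(k))
    subsets <- c(subsets, lapply(subsets, c, ch))
  labels <- vapply(subsets, function(s)
    if (length(s) == 0) "none" else paste(channels[sort(s)], collapse = "+"), "")
  counts <- integer(length(subsets)); names(counts) <- labels
  for (i in seq_len(n)) {
    on <- which(flags[i, ])
    lab <- if (length(on) == 0) "none" else paste(channels[on], collapse = "+")
    counts[lab] <- counts[lab] + 1L
  }
  list(percent_positive = pct, conditional = cond, class_counts = counts)
}

# --- helpers ----------------------------------------------------------------

# build a cell_table directly from a flag/count matrix (bypasses images)
make_cell_table <- function(counts, threshold = 3L, region = NULL) {
  n <- nrow(counts)
  lab <- matrix(0L, 8, max(8, n))
  # one pixel per cell keeps label maps valid
  for (i in seq_len(n)) lab[1 + (i - 1) %% 8, 1 + (i - 1) %/% 8] <- i
  fs <- lapply(colnames(counts), function(ch) {
    rows <- integer(0); cols <- integer(0)
    for (i in seq_len(n)) {
      k <- counts[i, ch]
      rows <- c(rows, rep(1 + (i - 1) %% 8, k))
      cols <- c(cols, rep(1 + (i - 1) %/% 8, k))
    }
    structure(data.frame(row = rows, col = cols,
                         value = rep(1, length(rows))),
              class = c("focus_set", "data.frame"), channel = ch)
  })
  names(fs) <- colnames(counts)
  regions <- NULL
  if (!is.null(region)) {
    m <- matrix(1, 8, max(8, n))
    regions <- stats::setNames(list(m), region)
  }
  build_cell_table(lab, lab, fs, regions = regions, threshold = threshold)
}

# map ground-truth nuclei to segmented labels via their centers
gt_label_map <- function(nucleus_labels, gt_nuclei) {
  nucleus_labels[cbind(round(gt_nuclei$row), round(gt_nuclei$col))]
}
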