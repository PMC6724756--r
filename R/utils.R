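# internal validators shared across modules

.check_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(what, " must be non-empty", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (any(img < 0))
    stop(what, " contains negative intensities", call. = FALSE)
  invisible(img)
}

.check_label_map <- function(labels, what = "label map") {
  if (!is.matrix(labels) || !is.numeric(labels))
    stop(what, " must be an integer matrix", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop(what, " must contain non-negative integer labels", call. = FALSE)
  invisible(labels)
}

.n_labels <- function(labels) {
  if (all(labels == 0)) 0L else as.integer(max(labels))
}

# relabel positive labels to 1..n preserving ascending order of old ids
.relabel <- function(labels) {
  old <- sort(unique(labels[labels > 0]))
  if (length(old) == 0L) {
    out <- matrix(0L, nrow(labels), ncol(labels))
    return(out)
  }
  lut <- integer(max(old))
  lut[old] <- seq_along(old)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- lut[labels[pos]]
  out
}

# run an expression with a temporarily-seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
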