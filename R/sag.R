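#' Average current-clamp sweeps pointwise
#'
#' Repeated hyperpolarizing steps are averaged sample-by-sample before the
#' sag measurement (typically 5-10 sweeps).
#'
#' @param sweeps Numeric matrix, one column per sweep (equal length,
#'   uniform sampling), or a numeric vector for a single sweep.
#' @return Numeric vector: the pointwise mean trace.
#' @export
average_sweeps <- function(sweeps) {
  if (is.vector(sweeps) && is.numeric(sweeps)) sweeps <- matrix(sweeps, ncol = 1)
  if (!is.matrix(sweeps) || !is.numeric(sweeps) || ncol(sweeps) < 1L ||
      nrow(sweeps) < 1L)
    stop("sweeps must be a non-empty numeric matrix (samples x sweeps)",
         call. = FALSE)
  if (!all(is.finite(sweeps)))
    stop("sweeps contain non-finite samples", call. = FALSE)
  rowMeans(sweeps)
}

#' Sag amplitude of an averaged hyperpolarizing response
#'
#' The Ih-mediated sag is the difference between the most hyperpolarized
#' point within the first second after stimulus onset and the final steady
#' state of the averaged trace:
#' `sag = V_steady - V_min`, where `V_min` is the trace minimum over
#' `[onset, onset + 1 s]` and `V_steady` is the mean over the last
#' `steady_window` seconds of the stimulus epoch. A trace that relaxes
#' upward after the trough gives a positive sag; a flat trace gives exactly
#' zero. Adding a constant offset to the trace leaves the sag unchanged.
#'
#' @param avg Averaged voltage trace (mV), e.g. from [average_sweeps()].
#' @param dt Sampling interval in seconds.
#' @param stimulus_onset Stimulus onset time (s), measured from the first
#'   sample at time 0.
#' @param stimulus_duration Stimulus length in seconds (the protocol uses a
#'   5 s step).
#' @param steady_window Length (s) of the terminal window averaged for the
#'   steady state (default 0.5 s).
#' @return A list of class `sag_measurement` with `sag` (mV), `v_min`,
#'   `t_min` (s), `v_steady`, and the windows used.
#' @examples
#' t <- seq(0, 6, by = 1e-3)
#' v <- -50 - ifelse(t >= 0.5 & t < 5.5, 20 - 7 * (1 - exp(-(t - 0.5) / 0.3)), 0)
#' compute_sag(v, dt = 1e-3, stimulus_onset = 0.5, stimulus_duration = 5)$sag
#' @export
compute_sag <- function(avg, dt, stimulus_onset, stimulus_duration = 5,
                        steady_window = 0.5) {
  if (!is.numeric(avg) || length(avg) < 2L || !all(is.finite(avg)))
    stop("avg must be a finite numeric trace", call. = FALSE)
  stopifnot(dt > 0, stimulus_duration > 0, steady_window > 0,
            steady_window <= stimulus_duration, stimulus_onset >= 0)
  if (stimulus_duration < 1)
    stop("stimulus must last at least 1 s to define the trough window",
         call. = FALSE)
  t_end <- (length(avg) - 1) * dt
  if (stimulus_onset + stimulus_duration > t_end + 1e-9)
    stop("stimulus window extends beyond the trace", call. = FALSE)
  tm <- (seq_along(avg) - 1) * dt
  eps <- dt * 1e-6
  min_win <- tm >= stimulus_onset - eps & tm <= stimulus_onset + 1 + eps
  steady_win <- tm >= stimulus_onset + stimulus_duration - steady_window - eps &
    tm <= stimulus_onset + stimulus_duration + eps
  v_min <- min(avg[min_win])
  t_min <- tm[min_win][which.min(avg[min_win])]
  v_steady <- mean(avg[steady_win])
  structure(list(sag = v_steady - v_min, v_min = v_min, t_min = t_min,
                 v_steady = v_steady, stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 steady_window = steady_window),
            class = "sag_measurement")
}

#' @export
print.sag_measurement <- function(x, ...) {
  cat(sprintf("Sag: %.3f mV (trough %.3f mV at %.3f s; steady state %.3f mV over final %.2g s)\n",
              x$sag, x$v_min, x$t_min, x$v_steady, x$steady_window))
  invisible(x)
}

#' Read current-clamp sweeps from a delimited text file
#'
#' Expects a CSV/TSV matrix with a time column (seconds) followed by one
#' column per sweep (mV). The sampling interval must be uniform.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param time_col Name or index of the time column (default 1).
#' @return List with `time` (s), `sweeps` (matrix, samples x sweeps) and
#'   `dt` (s).
#' @export
read_sweeps <- function(path, time_col = 1L) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  tm <- df[[time_col]]
  sw <- as.matrix(df[, setdiff(seq_along(df), if (is.numeric(time_col))
    time_col else match(time_col, names(df))), drop = FALSE])
  dts <- diff(tm)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9 * max(1, abs(dts[1]))))
    stop("time column must be uniformly sampled", call. = FALSE)
  list(time = tm, sweeps = sw, dt = dts[1])
}
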