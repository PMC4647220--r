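#' Multi-trial MEG sensor epochs
#'
#' Container for epoched sensor data with a vertical EOG channel. Epochs
#' run from 200 ms before stimulus onset to 800 ms after, sampled at
#' 600 Hz (600 samples), in SI units (tesla; EOG in volts).
#'
#' @param data Numeric array, trials x sensors x samples (tesla).
#' @param eog Numeric matrix, trials x samples (volts).
#' @param srate Sampling rate, Hz.
#' @param t0 Epoch start relative to stimulus onset, seconds.
#' @return Object of class `trial_set`.
#' @export
trial_set <- function(data, eog, srate = 600, t0 = -0.2) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_samples <- dim(data)[3]
  if (n_samples != round(1.0 * srate))
    stop("epoch must span exactly 1 s (samples = srate)")
  if (dim(data)[1] < 1) stop("need at least one trial")
  if (!is.matrix(eog) || nrow(eog) != dim(data)[1] || ncol(eog) != n_samples)
    stop("eog must be a trials x samples matrix matching `data`")
  structure(list(data = data, eog = eog, srate = srate, t0 = t0,
                 n_trials = dim(data)[1]),
            class = "trial_set")
}

# Sample times of an epoch (seconds, relative to stimulus onset).
sample_times <- function(ts) ts$t0 + (seq_len(dim(ts$data)[3]) - 1) / ts$srate

#' Reject trials with ocular artifacts
#'
#' Drops every trial whose EOG amplitude exceeds the threshold at any
#' sample (default 150 uV).
#'
#' @param trials A `trial_set`.
#' @param threshold Rejection threshold in volts (default `150e-6`).
#' @return The pruned `trial_set`; the number of removed trials is stored
#'   in attribute `n_removed`.
#' @export
reject_artifact_trials <- function(trials, threshold = 150e-6) {
  stopifnot(inherits(trials, "trial_set"))
  peak <- apply(abs(trials$eog), 1, max)
  keep <- peak <= threshold
  if (!any(keep))
    stop(sprintf("all %d trials exceed the %.0f uV EOG threshold",
                 trials$n_trials, threshold * 1e6))
  out <- trial_set(trials$data[keep, , , drop = FALSE],
                   trials$eog[keep, , drop = FALSE],
                   srate = trials$srate, t0 = trials$t0)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Persist a trial set as an array container with a JSON sidecar
#'
#' Writes `<base>.dat` (raw little-endian doubles: the data array in R
#' column order followed by the EOG matrix) and `<base>.json` describing
#' dimensions, sampling and optional sensor geometry.
#'
#' @param ts A `trial_set`.
#' @param base Output path prefix.
#' @param head Optional `head_model` stored in the sidecar.
#' @return `base`, invisibly.
#' @export
write_trial_set <- function(ts, base, head = NULL) {
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ts$data), con, size = 8, endian = "little")
  writeBin(as.numeric(ts$eog), con, size = 8, endian = "little")
  side <- list(dims = dim(ts$data), srate = ts$srate, t0 = ts$t0)
  if (!is.null(head))
    side$sensors <- list(positions = head$sensor_positions,
                         orientations = head$sensor_orientations)
  jsonlite::write_json(side, paste0(base, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(base)
}

#' Read a trial set written by [write_trial_set()]
#' @param base Path prefix used at write time.
#' @return A `trial_set`.
#' @export
read_trial_set <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  dat <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  eog <- readBin(con, "double", n = d[1] * d[3], size = 8, endian = "little")
  trial_set(array(dat, dim = d), matrix(eog, d[1], d[3]),
            srate = side$srate, t0 = side$t0)
}
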