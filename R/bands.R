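#' Oscillatory band definitions
#'
#' Frequency bands used for peak extraction and for group-level
#' stimulation maps. `peak_range` is the search range for per-subject
#' peaks (alpha 7-14, beta 15-30, gamma 40-100 Hz); `test_range` is the
#' narrower range used by the group stimulation test (alpha 8-13, beta
#' 15-25, gamma 60-90, theta 4-7 Hz). `sign` is -1 for alpha/beta (the
#' stimulus suppresses them) and +1 for gamma (the stimulus enhances it).
#' Theta has no peak-extraction default (no reliable modulation) and only
#' a test range.
#'
#' @param name One of `"alpha"`, `"beta"`, `"gamma"`, `"theta"`.
#' @return Object of class `band_definition` with fields `name`,
#'   `peak_range`, `test_range`, `sign`.
#' @export
band_definition <- function(name = c("alpha", "beta", "gamma", "theta")) {
  name <- match.arg(name)
  bd <- switch(name,
    alpha = list(peak_range = c(7, 14), test_range = c(8, 13), sign = -1),
    beta  = list(peak_range = c(15, 30), test_range = c(15, 25), sign = -1),
    gamma = list(peak_range = c(40, 100), test_range = c(60, 90), sign = +1),
    theta = list(peak_range = NULL, test_range = c(4, 7), sign = -1))
  structure(c(list(name = name), bd), class = "band_definition")
}

#' Per-subject band peak frequency, timing and amplitude
#'
#' The peak is the largest modulation of the V1-averaged response within
#' the band's peak range and the 0-600 ms window: the maximum for gamma,
#' the deepest suppression (most negative value) for alpha/beta. The
#' peak frequency and timing are the grid coordinates of that extremum
#' and the peak amplitude is the signed response value there. Ties are
#' broken towards the lower frequency and earlier time (and reported via
#' a message).
#'
#' @param response A `response_array` (or a freq x time matrix from
#'   [v1_response()]).
#' @param band A `band_definition` (must have a `peak_range`).
#' @param t_window Search window in seconds (default `c(0, 0.6)`).
#' @return Object of class `band_peaks`: `peak_freq` (Hz), `peak_time`
#'   (ms), `peak_amp` (signed, normalised units), `band`.
#' @export
extract_band_peaks <- function(response, band, t_window = c(0, 0.6)) {
  stopifnot(inherits(band, "band_definition"))
  if (is.null(band$peak_range))
    stop(sprintf("band '%s' has no peak-extraction range", band$name))
  resp <- if (inherits(response, "response_array")) v1_response(response)
          else response
  freqs <- as.numeric(attr(resp, "fgrid"))
  times <- as.numeric(attr(resp, "tgrid"))
  fi <- which(freqs >= band$peak_range[1] - 1e-9 &
                freqs <= band$peak_range[2] + 1e-9)
  ti <- which(times >= t_window[1] - 1e-9 & times <= t_window[2] + 1e-9)
  if (length(fi) == 0 || length(ti) == 0)
    stop("band peak range does not intersect the analysis grids")
  sub <- resp[fi, ti, drop = FALSE]
  if (all(sub == 0)) stop("no modulation: response is identically zero in the band")
  signed <- band$sign * sub
  best <- max(signed)
  hits <- which(signed == best, arr.ind = TRUE)
  if (nrow(hits) > 1) {
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    message(sprintf("peak tie in %s band: %d bins; taking lowest frequency, earliest time",
                    band$name, nrow(hits)))
  }
  f_at <- fi[hits[1, 1]]
  t_at <- ti[hits[1, 2]]
  structure(list(peak_freq = freqs[f_at],
                 peak_time = 1000 * times[t_at],
                 peak_amp = resp[f_at, t_at],
                 band = band$name),
            class = "band_peaks")
}
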