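#' Frequency grid for time-frequency analysis
#'
#' Builds the analysis frequency grid: 4-15 Hz sampled at 0.25 Hz,
#' 15-30 Hz at 0.5 Hz and 36-104 Hz at 2 Hz. The three-range layout can be
#' overridden by supplying a list of `c(from, to, by)` triplets.
#'
#' @param ranges List of numeric triplets `c(from, to, by)` in Hz. The
#'   default reproduces the three-range layout above (the second range
#'   starts at 15.5 Hz so that 15 Hz is not duplicated).
#' @return An object of class `freq_grid`: a strictly increasing numeric
#'   vector of bin centre frequencies in Hz.
#' @export
freq_grid <- function(ranges = list(c(4, 15, 0.25),
                                    c(15.5, 30, 0.5),
                                    c(36, 104, 2))) {
  bins <- unlist(lapply(ranges, function(r) seq(r[1], r[2], by = r[3])))
  if (any(diff(bins) <= 0)) stop("frequency bins must be strictly increasing")
  if (any(bins <= 0)) stop("frequencies must be positive")
  structure(bins, class = "freq_grid", ranges = ranges)
}

#' Gamma-band-only frequency grid (36-104 Hz at 2 Hz)
#' @return A `freq_grid` covering only the high-frequency range.
#' @export
gamma_freq_grid <- function() freq_grid(list(c(36, 104, 2)))

#' Time grid for time-frequency analysis
#'
#' Uniform grid of analysis instants from 200 ms before stimulus onset to
#' 800 ms after, in 17 ms steps. Time 0 is stimulus onset.
#'
#' @param t0,t1 Window limits in seconds.
#' @param step Spacing in seconds (default 0.017).
#' @return Object of class `time_grid`: numeric vector of instants (s).
#' @export
time_grid <- function(t0 = -0.2, t1 = 0.8, step = 0.017) {
  stopifnot(step > 0, t1 > t0)
  instants <- t0 + step * seq(0L, floor((t1 - t0) / step + 1e-9))
  structure(instants, class = "time_grid", step = step)
}

# Baseline bins: instants in [-Inf, 0), i.e. strictly pre-stimulus.
baseline_bins <- function(tgrid) which(unclass(tgrid) < 0)

# Post-stimulus analysis bins within [0, t_max] (default 600 ms).
post_bins <- function(tgrid, t_max = 0.6) {
  which(unclass(tgrid) >= 0 & unclass(tgrid) <= t_max + 1e-9)
}
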