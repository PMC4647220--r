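#' Persist a response array as an array container with a JSON sidecar
#'
#' Writes `<base>.dat` (raw little-endian doubles in R column order,
#' points x freq x time) and `<base>.json` holding the axis grids, the
#' modulation mode and the V1 point indices.
#'
#' @param response A `response_array` from [normalize_and_modulate()].
#' @param base Output path prefix.
#' @return `base`, invisibly.
#' @export
write_response_array <- function(response, base) {
  stopifnot(inherits(response, "response_array"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(response), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(dims = dim(response),
         freq_hz = as.numeric(attr(response, "fgrid")),
         time_s = as.numeric(attr(response, "tgrid")),
         mode = attr(response, "mode"),
         v1_indices = attr(response, "v1_indices")),
    paste0(base, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(base)
}

#' Read a response array written by [write_response_array()]
#' @param base Path prefix used at write time.
#' @return A `response_array`.
#' @export
read_response_array <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  structure(array(vals, dim = d), class = "response_array",
            fgrid = structure(side$freq_hz, class = "freq_grid"),
            tgrid = structure(side$time_s, class = "time_grid"),
            mode = side$mode, v1_indices = side$v1_indices)
}
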