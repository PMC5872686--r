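#' Monthly ambient UVR climatology
#'
#' A latitude-by-calendar-month grid of ambient erythemal ultraviolet
#' radiation (kJ/m^2 per month).  Real satellite-derived grids can be read
#' with \code{\link{read_climatology}}; \code{\link{default_climatology}}
#' supplies a synthetic grid for simulation work.
#'
#' @param latitudes numeric vector of band latitudes (degrees, positive
#'   north), strictly increasing.
#' @param values numeric matrix, one row per latitude band and 12 columns
#'   (January..December), all values >= 0.
#' @return an object of class \code{uvr_climatology}.
#' @examples
#' clim <- uvr_climatology(c(30, 40), rbind(rep(100, 12), rep(60, 12)))
#' ambient_monthly(clim, 35, 6)
#' @export
uvr_climatology <- function(latitudes, values) {
  latitudes <- as.numeric(latitudes)
  values <- as.matrix(values)
  if (any(is.na(latitudes)) || is.unsorted(latitudes, strictly = TRUE))
    stop("latitudes must be strictly increasing")
  if (nrow(values) != length(latitudes) || ncol(values) != 12L)
    stop("values must be a length(latitudes) x 12 matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("climatology values must be finite and >= 0")
  dimnames(values) <- list(NULL, month.abb)
  structure(list(latitudes = latitudes, values = values),
            class = "uvr_climatology")
}

#' @export
print.uvr_climatology <- function(x, ...) {
  cat(sprintf("UVR climatology: %d latitude bands (%g to %g deg N)\n",
              length(x$latitudes), min(x$latitudes), max(x$latitudes)))
  cat(sprintf("monthly range %.1f to %.1f kJ/m^2\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Synthetic default climatology
#'
#' A smooth stand-in grid (labelled synthetic; it is not a satellite
#' product): each band follows an annual sinusoid peaking in June, with both
#' the mean level and the seasonal amplitude decreasing with latitude.
#' Values are on a realistic ambient erythemal scale for the mid-latitude
#' northern hemisphere (roughly 30-160 kJ/m^2 per month near 33 deg N).
#'
#' @param latitudes band latitudes; default every 2 degrees from 24 to 50 N.
#' @return a \code{\link{uvr_climatology}}.
#' @export
default_climatology <- function(latitudes = seq(24, 50, by = 2)) {
  base <- 100 - 3 * (latitudes - 32)     # mean monthly level, kJ/m^2
  amp <- pmax(10, 60 - 2 * (latitudes - 32))
  m <- 1:12
  vals <- outer(seq_along(latitudes), m, function(i, mm)
    base[i] + amp[i] * cos(2 * pi * (mm - 6) / 12))
  vals[vals < 0] <- 0
  uvr_climatology(latitudes, vals)
}

#' Ambient monthly UVR at a latitude
#'
#' Linear interpolation between adjacent climatology bands; a latitude equal
#' to a band returns the stored value exactly; latitudes outside the grid
#' (by at most 5 degrees) are clamped to the nearest band.
#'
#' @param clim a \code{\link{uvr_climatology}}.
#' @param latitude degrees north; vectorised.
#' @param month calendar month 1..12; vectorised (recycled with latitude).
#' @return ambient UVR, kJ/m^2 for that month.
#' @export
ambient_monthly <- function(clim, latitude, month) {
  stopifnot(inherits(clim, "uvr_climatology"))
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  lats <- clim$latitudes
  lo <- min(lats) - 5
  hi <- max(lats) + 5
  if (any(latitude < lo | latitude > hi))
    stop(sprintf("latitude outside supported range [%g, %g]", lo, hi))
  n <- max(length(latitude), length(month))
  .ambient_interp(clim, rep_len(latitude, n), rep_len(month, n))
}

# interpolation core without argument checks (grid-range latitudes clamped)
.ambient_interp <- function(clim, latitude, month) {
  lats <- clim$latitudes
  latitude <- pmin(pmax(latitude, lats[1L]), lats[length(lats)])
  i <- findInterval(latitude, lats, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lats) - 1L)
  w <- (latitude - lats[i]) / (lats[i + 1L] - lats[i])
  v_lo <- clim$values[cbind(i, month)]
  v_hi <- clim$values[cbind(i + 1L, month)]
  (1 - w) * v_lo + w * v_hi
}

#' Read / write a climatology file
#'
#' Delimited text, header row, one row per latitude band: a \code{latitude}
#' column followed by 12 monthly columns (January..December), kJ/m^2.
#'
#' @param file path to a CSV file.
#' @return \code{read_climatology}: a \code{\link{uvr_climatology}}.
#' @export
read_climatology <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  if (ncol(d) != 13L)
    stop("climatology file must have a latitude column plus 12 monthly columns")
  o <- order(d[[1L]])
  uvr_climatology(d[[1L]][o], as.matrix(d[o, -1L, drop = FALSE]))
}

#' @param clim a \code{\link{uvr_climatology}} to write.
#' @rdname read_climatology
#' @export
write_climatology <- function(clim, file) {
  stopifnot(inherits(clim, "uvr_climatology"))
  d <- data.frame(latitude = clim$latitudes, clim$values, check.names = FALSE)
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}
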