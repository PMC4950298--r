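#' North--south distance between two latitudes
#'
#' The invasion analysed here advances along a north--south axis, so
#' transition-zone bounds are taken as pure latitudinal separations at
#' 111.2 km per degree. For the general great-circle alternative see
#' [geodesic_distance()].
#'
#' @param lat_a,lat_b Latitudes in decimal degrees.
#' @param km_per_degree Kilometres per degree of latitude (default 111.2).
#' @return Distance in km (vectorized).
#' @examples
#' latitudinal_distance(53.67, 51.34)  # about 260 km
#' @export
latitudinal_distance <- function(lat_a, lat_b, km_per_degree = 111.2) {
  if (any(!is.finite(lat_a)) || any(!is.finite(lat_b)))
    stop("latitudes must be finite numbers", call. = FALSE)
  abs(lat_a - lat_b) * km_per_degree
}

#' Great-circle distance between two coordinates
#'
#' Haversine distance on a spherical Earth; provided as the alternative to
#' the default north--south metric of [latitudinal_distance()].
#'
#' @param lat_a,lon_a,lat_b,lon_b Coordinates in decimal degrees.
#' @param radius_km Earth radius in km (default 6371).
#' @return Distance in km.
#' @export
geodesic_distance <- function(lat_a, lon_a, lat_b, lon_b,
                              radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat_b - lat_a) * to_rad
  dlon <- (lon_b - lon_a) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat_a * to_rad) * cos(lat_b * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Dispersal lower bound from the travelling-wave width relation
#'
#' For a bistable CI invasion wave with a Gaussian dispersal kernel,
#' perfect maternal transmission and no fecundity cost, the width of the
#' transition zone (5% to 95% infection frequency) is
#' `delta_x = 3 sigma / sqrt(l_ci)`. Inverting gives a lower bound on the
#' dispersal standard deviation from an observed (lower-bound) zone width:
#' `sigma = delta_x * sqrt(l_ci) / 3`.
#'
#' @param delta_x Transition-zone width in km (> 0).
#' @param l_ci CI level in (0, 1\].
#' @param form `"sqrt"` (default): the square-root wave-width relation
#'   above; `"literal"`: `sigma = delta_x * l_ci / 3`, without the radical.
#' @param round_km Round the bound to the nearest integer km for reporting
#'   (default `FALSE`).
#' @return Dispersal standard deviation bound in km.
#' @examples
#' sigma_lower_bound(130, 0.98, round_km = TRUE)  # 43
#' sigma_lower_bound(85, 0.98, round_km = TRUE)   # 28
#' @export
sigma_lower_bound <- function(delta_x, l_ci, form = c("sqrt", "literal"),
                              round_km = FALSE) {
  form <- match.arg(form)
  if (any(delta_x <= 0)) stop("'delta_x' must be positive", call. = FALSE)
  if (any(l_ci <= 0 | l_ci > 1))
    stop("'l_ci' must be in (0, 1]", call. = FALSE)
  sigma <- switch(form,
    sqrt    = delta_x * sqrt(l_ci) / 3,
    literal = delta_x * l_ci / 3
  )
  if (round_km) round(sigma) else sigma
}

#' Width of the transition zone on a spatial frequency profile
#'
#' Measures the distance over which the invading strain's frequency rises
#' from `lo` (default 5%) to `hi` (default 95%) along a transect. Noisy
#' empirical profiles are first monotonized by isotonic (pool-adjacent-
#' violators) regression -- sampling noise otherwise creates multiple
#' threshold crossings -- and the crossing positions are obtained by linear
#' interpolation between adjacent sites. Transects falling in either
#' direction are handled: the orientation with the better isotonic fit is
#' used, and the result is invariant under reversing the transect.
#'
#' @param position Strictly increasing site positions (km).
#' @param frequency Infection frequencies in \[0, 1\], one per position.
#' @param lo,hi Frequency thresholds defining the zone (defaults 0.05,
#'   0.95).
#' @param monotonize Apply isotonic smoothing before locating crossings
#'   (default `TRUE`).
#' @return Zone width in km, or `NA_real_` if either threshold is never
#'   crossed.
#' @examples
#' x <- seq(0, 100, by = 5)
#' p <- plogis((x - 50) / 8)
#' transition_zone_width(x, p)
#' @export
transition_zone_width <- function(position, frequency,
                                  lo = 0.05, hi = 0.95,
                                  monotonize = TRUE) {
  if (length(position) < 2L)
    stop("at least two sites are required", call. = FALSE)
  if (length(position) != length(frequency))
    stop("'position' and 'frequency' must have the same length",
         call. = FALSE)
  if (any(diff(position) <= 0))
    stop("'position' must be strictly increasing", call. = FALSE)
  if (any(frequency < 0 | frequency > 1, na.rm = TRUE))
    stop("'frequency' must be in [0, 1]", call. = FALSE)
  if (!(lo < hi)) stop("'lo' must be below 'hi'", call. = FALSE)

  f <- frequency
  if (monotonize) {
    up <- stats::isoreg(position, frequency)$yf
    dn <- rev(stats::isoreg(position, rev(frequency))$yf)
    f <- if (sum((up - frequency)^2) <= sum((dn - frequency)^2)) up else dn
  }
  # analyse in increasing orientation
  if (f[length(f)] < f[1L]) f <- rev(f)

  cross <- function(th) {
    if (f[1L] > th || f[length(f)] < th) return(NA_real_)
    i <- which(f >= th)[1L]
    if (i == 1L) return(position[1L])
    if (f[i] == f[i - 1L]) return(position[i])
    position[i - 1L] + (th - f[i - 1L]) / (f[i] - f[i - 1L]) *
      (position[i] - position[i - 1L])
  }
  x_lo <- cross(lo)
  x_hi <- cross(hi)
  if (is.na(x_lo) || is.na(x_hi)) return(NA_real_)
  x_hi - x_lo
}

#' Read a population-site table
#'
#' Reads a TSV/CSV table of survey sites with columns `site`, `lat`,
#' `lon`, `period`, `n`, `n_double` and derives the doubly infected
#' frequency.
#'
#' @param path Path to a tab- or comma-separated file with a header row
#'   (the delimiter is sniffed from the header line).
#' @return A data frame with the input columns plus `freq_double`
#'   (`NA` where `n` is 0).
#' @export
read_site_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("site", "lat", "lon", "period", "n", "n_double")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("site table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tab$n_double > tab$n | tab$n_double < 0))
    stop("'n_double' must be between 0 and 'n'", call. = FALSE)
  tab$freq_double <- ifelse(tab$n > 0, tab$n_double / tab$n, NA_real_)
  tab
}
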