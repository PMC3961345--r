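#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0 km, the geodesic
#' convention used by every distance-resolved statistic in this package.
#' Inputs are recycled to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#'   Latitudes must lie in \[-90, 90\], longitudes in \[-180, 180\].
#' @return Numeric vector of distances in kilometres.
#' @examples
#' great_circle_distance(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  validate_coords(c(lat1, lat2), c(lon1, lon2))
  cpp_haversine(lat1, lon1, lat2, lon2)
}

validate_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("coordinates out of range: lat must be in [-90, 90], ",
         "lon in [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Specify a jump-length distribution
#'
#' The travel stage draws displacement lengths from one of three laws: a
#' truncated power law (the default, exponent magnitude 1.55 following the
#' empirical displacement literature), a normal law truncated below at
#' `d_min`, or a uniform law on `[d_min, d_max]`.
#'
#' @param family One of `"powerlaw"`, `"normal"`, `"uniform"`.
#' @param exponent Magnitude of the power-law exponent (density
#'   proportional to `r^-exponent` on `[d_min, d_max]`).
#' @param d_min,d_max Lower/upper truncation in km; `d_min > 0`.
#' @param mean,sd Normal-family location and scale in km.
#' @return A `jump_spec` object.
#' @export
jump_spec <- function(family = c("powerlaw", "normal", "uniform"),
                      exponent = 1.55, d_min = 1, d_max = 20000,
                      mean = 100, sd = 50) {
  family <- match.arg(family)
  stopifnot(d_min > 0, d_max > d_min)
  if (family == "powerlaw") stopifnot(is.finite(exponent), exponent > 0)
  if (family == "normal") stopifnot(sd > 0)
  structure(list(family = family, exponent = exponent,
                 d_min = d_min, d_max = d_max, mean = mean, sd = sd),
            class = "jump_spec")
}

#' @export
print.jump_spec <- function(x, ...) {
  cat("<jump_spec>", x$family, "")
  if (x$family == "powerlaw")
    cat(sprintf("exponent -%.3g on [%g, %g] km\n", x$exponent, x$d_min, x$d_max))
  else if (x$family == "normal")
    cat(sprintf("mean %g sd %g km, truncated at %g km\n", x$mean, x$sd, x$d_min))
  else
    cat(sprintf("on [%g, %g] km\n", x$d_min, x$d_max))
  invisible(x)
}

#' Draw jump lengths
#'
#' Power-law lengths are drawn by the inverse CDF of the truncated law;
#' normal lengths are resampled until they exceed `d_min`; uniform lengths
#' are drawn on `[d_min, d_max]`. Uses R's global RNG.
#'
#' @param spec A [jump_spec()].
#' @param n Number of draws.
#' @return Numeric vector of lengths in km.
#' @export
sample_jump_length <- function(spec, n = 1) {
  stopifnot(inherits(spec, "jump_spec"))
  switch(spec$family,
    powerlaw = qtrunc_powerlaw(stats::runif(n), spec$exponent,
                               spec$d_min, spec$d_max),
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      while (any(bad <- x < spec$d_min))
        x[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
      x
    },
    uniform = stats::runif(n, spec$d_min, spec$d_max)
  )
}

#' Truncated power-law distribution functions
#'
#' CDF and quantile function of the law with density proportional to
#' `r^-alpha` on `[d_min, d_max]` (`alpha != 1`).
#'
#' @param q,p Quantiles / probabilities.
#' @param alpha Exponent magnitude.
#' @param d_min,d_max Truncation bounds in km.
#' @return Numeric vector.
#' @export
ptrunc_powerlaw <- function(q, alpha, d_min, d_max) {
  a <- 1 - alpha
  q <- pmin(pmax(q, d_min), d_max)
  (q^a - d_min^a) / (d_max^a - d_min^a)
}

#' @rdname ptrunc_powerlaw
#' @export
qtrunc_powerlaw <- function(p, alpha, d_min, d_max) {
  a <- 1 - alpha
  (d_min^a + p * (d_max^a - d_min^a))^(1 / a)
}

#' Fit a truncated power law by maximum likelihood
#'
#' Estimates the exponent magnitude of a power law truncated to
#' `[d_min, d_max]` by numerical maximisation of the log-likelihood.
#'
#' @param x Positive observations within the truncation bounds.
#' @param d_min,d_max Known truncation bounds; default to the data range.
#' @return A list with elements `alpha` (exponent magnitude), `logLik`,
#'   and `n`.
#' @export
fit_truncated_powerlaw <- function(x, d_min = min(x), d_max = max(x)) {
  stopifnot(length(x) > 1, all(x > 0))
  slx <- sum(log(x))
  n <- length(x)
  nll <- function(alpha) {
    a <- 1 - alpha
    norm <- (d_max^a - d_min^a) / a
    alpha * slx + n * log(norm)
  }
  opt <- stats::optimize(nll, interval = c(0.05, 8))
  list(alpha = opt$minimum, logLik = -opt$objective, n = n)
}

#' Sample landing points at a given distance in a populated direction
#'
#' Given an origin and a target distance `r`, candidate cells are the
#' populated raster cells whose centre lies in the annulus
#' `[r - w/2, r + w/2]` around the origin, with annulus width
#' `w = max(cell diagonal at the origin latitude, annulus_factor * r)`.
#' A cell is drawn with probability proportional to its population and the
#' landing point is jittered uniformly inside it. When the annulus holds no
#' population, `fallback = "closest"` lands in the populated cell whose
#' centre distance is nearest to `r`; `fallback = "none"` returns `NA`.
#'
#' @param grid A [population_grid].
#' @param origin_lat,origin_lon Origin coordinates (degrees); must lie
#'   inside the grid extent.
#' @param r Vector of target distances in km (all > 0).
#' @param annulus_factor Relative annulus width (default 0.05).
#' @param fallback `"closest"` (default) or `"none"`.
#' @return A tibble with columns `lat`, `lon`, `in_annulus`.
#' @export
sample_jump_target <- function(grid, origin_lat, origin_lon, r,
                               annulus_factor = 0.05,
                               fallback = c("closest", "none")) {
  stopifnot(inherits(grid, "population_grid"), all(r > 0))
  fallback <- match.arg(fallback)
  ext <- grid_extent(grid)
  if (origin_lat < ext$lat_min || origin_lat > ext$lat_max ||
      origin_lon < ext$lon_min || origin_lon > ext$lon_max)
    stop("origin lies outside the grid extent", call. = FALSE)
  res <- cpp_jump_targets(grid$counts, grid$xllcorner, grid$yllcorner,
                          grid$cellsize, origin_lat, origin_lon,
                          as.numeric(r), annulus_factor,
                          fallback == "closest")
  tibble::tibble(lat = res$lat, lon = res$lon, in_annulus = res$ok)
}
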