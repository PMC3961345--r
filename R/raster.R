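#' Population grids
#'
#' A `population_grid` is a georeferenced matrix of non-negative cell
#' population counts used for initial agent placement and for weighting the
#' direction of random jumps. Row 1 of the count matrix is the
#' northernmost row (raster convention); `xllcorner`/`yllcorner` give the
#' lower-left corner, `cellsize` the cell side in decimal degrees.
#'
#' @param counts Numeric matrix of non-negative counts (row 1 = north).
#' @param xllcorner,yllcorner Lower-left corner in decimal degrees.
#' @param cellsize Cell side in decimal degrees.
#' @param nodata_value Marker used when writing missing cells.
#' @return A `population_grid` object.
#' @name population_grid
#' @export
population_grid <- function(counts, xllcorner, yllcorner, cellsize,
                            nodata_value = -9999) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("population counts must be finite and non-negative", call. = FALSE)
  if (sum(counts) <= 0)
    stop("grid has zero total population", call. = FALSE)
  structure(list(counts = counts,
                 nrows = nrow(counts), ncols = ncol(counts),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf(
    "<population_grid> %d x %d cells of %g deg, corner (%g, %g), total %g\n",
    x$nrows, x$ncols, x$cellsize, x$yllcorner, x$xllcorner, sum(x$counts)))
  invisible(x)
}

grid_extent <- function(grid) {
  list(lat_min = grid$yllcorner,
       lat_max = grid$yllcorner + grid$nrows * grid$cellsize,
       lon_min = grid$xllcorner,
       lon_max = grid$xllcorner + grid$ncols * grid$cellsize)
}

#' Cell centres of a population grid
#'
#' @param grid A [population_grid].
#' @return Tibble with `row`, `col`, `lat`, `lon`, `count` for every cell.
#' @export
grid_cell_centers <- function(grid) {
  rows <- seq_len(grid$nrows)
  cols <- seq_len(grid$ncols)
  tibble::tibble(
    row = rep(rows, times = grid$ncols),
    col = rep(cols, each = grid$nrows),
    lat = grid$yllcorner + (grid$nrows - rep(rows, times = grid$ncols) + 0.5) *
      grid$cellsize,
    lon = grid$xllcorner + (rep(cols, each = grid$nrows) - 0.5) *
      grid$cellsize,
    count = as.vector(grid$counts))
}

#' Read an ESRI ASCII population raster
#'
#' Parses the ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header
#' followed by row-major values (first row = north). NODATA cells are
#' mapped to zero population; header fields are preserved on the returned
#' object so that write-then-read round-trips exactly.
#'
#' @param path File path.
#' @return A [population_grid].
#' @export
read_population_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed raster header line: ", lines[i], call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("raster header is missing fields: ",
         paste(setdiff(req, names(hdr)), collapse = ", "), call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- suppressWarnings(as.numeric(
    unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  if (anyNA(vals))
    stop("non-numeric raster values", call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("raster value count (%d) does not match header (%d x %d)",
                 length(vals), nr, nc), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- 0
  if (any(m < 0))
    stop("raster contains negative population counts", call. = FALSE)
  if (sum(m) <= 0)
    stop("raster has zero total population", call. = FALSE)
  population_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII population raster
#'
#' @param grid A [population_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_raster <- function(grid, path) {
  stopifnot(inherits(grid, "population_grid"))
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata_value))
  rows <- apply(grid$counts, 1, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Synthesise a Gaussian-cities population grid
#'
#' Builds a heterogeneous population landscape as a mixture of isotropic
#' Gaussian cities, mimicking a country with a few dominant urban centres.
#' City centres are drawn uniformly inside the central 60% of the extent
#' unless given. Counts are discretised so the total matches
#' `total_population` exactly (largest-remainder rounding).
#'
#' @param lat_range,lon_range Numeric length-2 extents in degrees.
#' @param cellsize Cell side in degrees.
#' @param n_cities Number of cities (>= 1).
#' @param city_weights Positive relative weights, recycled to `n_cities`.
#' @param city_sd_km Gaussian spread of each city in km (recycled).
#' @param total_population Total population count.
#' @param city_centers Optional matrix/data frame of city centres
#'   (columns `lat`, `lon`); overrides random placement.
#' @param seed Optional integer seed (local to this call).
#' @return A [population_grid].
#' @export
synth_population_grid <- function(lat_range, lon_range, cellsize = 0.2,
                                  n_cities = 3, city_weights = 1,
                                  city_sd_km = 50, total_population = 1e5,
                                  city_centers = NULL, seed = NULL) {
  stopifnot(n_cities >= 1, all(city_weights > 0), total_population >= 1)
  if (diff(range(lat_range)) < cellsize || diff(range(lon_range)) < cellsize)
    stop("extent is smaller than one cell", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  nr <- max(1L, floor(diff(range(lat_range)) / cellsize))
  nc <- max(1L, floor(diff(range(lon_range)) / cellsize))
  w <- rep_len(city_weights, n_cities)
  sdk <- rep_len(city_sd_km, n_cities)
  if (is.null(city_centers)) {
    pad_lat <- 0.2 * diff(range(lat_range))
    pad_lon <- 0.2 * diff(range(lon_range))
    city_centers <- cbind(
      lat = stats::runif(n_cities, min(lat_range) + pad_lat,
                         max(lat_range) - pad_lat),
      lon = stats::runif(n_cities, min(lon_range) + pad_lon,
                         max(lon_range) - pad_lon))
  } else {
    city_centers <- as.matrix(as.data.frame(city_centers)[, c("lat", "lon")])
    stopifnot(nrow(city_centers) == n_cities)
  }
  xll <- min(lon_range); yll <- min(lat_range)
  # cell centres (row 1 = north)
  lat_c <- yll + (nr - seq_len(nr) + 0.5) * cellsize
  lon_c <- xll + (seq_len(nc) - 0.5) * cellsize
  dens <- matrix(0, nr, nc)
  for (k in seq_len(n_cities)) {
    d <- outer(lat_c, lon_c, function(la, lo)
      cpp_haversine(la, lo, rep(city_centers[k, "lat"], length(la)),
                    rep(city_centers[k, "lon"], length(la))))
    dens <- dens + w[k] * exp(-d^2 / (2 * sdk[k]^2))
  }
  if (sum(dens) <= 0) stop("degenerate city placement", call. = FALSE)
  target <- dens / sum(dens) * total_population
  counts <- floor(target)
  rem <- as.integer(round(total_population - sum(counts)))
  if (rem > 0) {
    frac_order <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[frac_order] <- counts[frac_order] + 1
  }
  population_grid(counts, xll, yll, cellsize)
}

#' Sample initial agent positions from a population grid
#'
#' Cells are chosen with probability proportional to their population and
#' each position is jittered uniformly inside its cell, avoiding the
#' artificial zero distances that cell-centre placement would create.
#'
#' @param grid A [population_grid].
#' @param n Number of agents.
#' @param seed Optional integer seed (local to this call).
#' @return Tibble with columns `id`, `lat`, `lon`.
#' @export
sample_initial_positions <- function(grid, n, seed = NULL) {
  stopifnot(inherits(grid, "population_grid"), n >= 0)
  if (sum(grid$counts) <= 0)
    stop("grid has zero total population", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (n == 0)
    return(tibble::tibble(id = integer(), lat = numeric(), lon = numeric()))
  idx <- sample.int(length(grid$counts), n, replace = TRUE,
                    prob = as.vector(grid$counts))
  row <- (idx - 1L) %% grid$nrows + 1L
  col <- (idx - 1L) %/% grid$nrows + 1L
  lat <- grid$yllcorner + (grid$nrows - row) * grid$cellsize +
    stats::runif(n) * grid$cellsize
  lon <- grid$xllcorner + (col - 1L) * grid$cellsize +
    stats::runif(n) * grid$cellsize
  tibble::tibble(id = seq_len(n), lat = lat, lon = lon)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
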