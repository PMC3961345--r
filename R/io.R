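#' Read and write directed edge lists
#'
#' Tab-separated `src<TAB>dst`, one directed edge per line, with a single
#' `#`-prefixed header line. Self-loops and duplicate lines are rejected
#' with their line numbers. Write-then-read reproduces the edge set.
#'
#' @param path File path.
#' @return Tibble `src`, `dst`.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines))
    return(tibble::tibble(src = integer(), dst = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad))
    stop("malformed edge line(s): ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  src <- vapply(parts, `[`, character(1), 1)
  dst <- vapply(parts, `[`, character(1), 2)
  loops <- src == dst
  if (any(loops))
    stop("self-loop(s) at line(s): ",
         paste(lineno[loops], collapse = ", "), call. = FALSE)
  dup <- duplicated(paste(src, dst))
  if (any(dup))
    stop("duplicate edge(s) at line(s): ",
         paste(lineno[dup], collapse = ", "), call. = FALSE)
  si <- suppressWarnings(as.integer(src))
  di <- suppressWarnings(as.integer(dst))
  if (!anyNA(si) && !anyNA(di)) tibble::tibble(src = si, dst = di)
  else tibble::tibble(src = src, dst = dst)
}

#' @rdname read_edgelist
#' @param x A [geonet] or a tibble with `src`, `dst`.
#' @param comment Optional text appended to the header line (e.g. seed and
#'   config hash).
#' @export
write_edgelist <- function(x, path, comment = NULL) {
  edges <- if (inherits(x, "geonet")) x$edges else tibble::as_tibble(x)
  hdr <- paste0("# src\tdst",
                if (!is.null(comment)) paste0("\t", comment) else "")
  writeLines(c(hdr, paste(edges$src, edges$dst, sep = "\t")), path)
  invisible(path)
}

#' Read and write agent location tables
#'
#' Tab-separated `id<TAB>lat<TAB>lon` with a single `#`-prefixed header
#' line; coordinates printed at 6 decimals.
#'
#' @param path File path.
#' @return Tibble `id`, `lat`, `lon`.
#' @export
read_positions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(tibble::tibble(id = integer(), lat = numeric(), lon = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("malformed location line(s)", call. = FALSE)
  id <- vapply(parts, `[`, character(1), 1)
  ii <- suppressWarnings(as.integer(id))
  tibble::tibble(
    id = if (anyNA(ii)) id else ii,
    lat = as.numeric(vapply(parts, `[`, character(1), 2)),
    lon = as.numeric(vapply(parts, `[`, character(1), 3)))
}

#' @rdname read_positions
#' @param positions Tibble `id`, `lat`, `lon`.
#' @param comment Optional text appended to the header line.
#' @export
write_positions <- function(positions, path, comment = NULL) {
  hdr <- paste0("# id\tlat\tlon",
                if (!is.null(comment)) paste0("\t", comment) else "")
  writeLines(c(hdr, sprintf("%s\t%.6f\t%.6f", positions$id,
                            positions$lat, positions$lon)), path)
  invisible(path)
}

#' Write a metric curve as CSV
#'
#' Columns `bin_low`, `bin_high`, `value`, `n`, preceded by a single
#' `#`-prefixed comment line.
#'
#' @param curve A `metric_curve` or disparity histogram tibble.
#' @param path Output path.
#' @param comment Optional comment text.
#' @export
write_curve <- function(curve, path, comment = NULL) {
  hdr <- paste0("# bin_low,bin_high,value,n",
                if (!is.null(comment)) paste0(",", comment) else "")
  body <- sprintf("%.8g,%.8g,%.8g,%g", curve$bin_low, curve$bin_high,
                  ifelse(is.na(curve$value), NA, curve$value), curve$n)
  writeLines(c(hdr, "bin_low,bin_high,value,n", body), path)
  invisible(path)
}

#' Load check-in records and keep each user's last known position
#'
#' Parses tab-separated check-in files (user id, ISO 8601 timestamp,
#' latitude, longitude, location id — the dialect of the public
#' location-based social network dumps). For each user the most recent
#' record is kept; equal timestamps break ties by last occurrence in the
#' file. Malformed rows (wrong field count, unparseable timestamp or
#' coordinates out of range) are skipped and tallied in the `n_skipped`
#' attribute.
#'
#' @param path File path.
#' @return Tibble `id`, `lat`, `lon` (one row per user) with attribute
#'   `n_skipped`.
#' @export
load_checkins <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok_len <- lengths(parts) >= 5
  user <- rep(NA_character_, length(parts))
  ts <- rep(NA_real_, length(parts))
  lat <- rep(NA_real_, length(parts))
  lon <- rep(NA_real_, length(parts))
  if (any(ok_len)) {
    user[ok_len] <- vapply(parts[ok_len], `[`, character(1), 1)
    tss <- vapply(parts[ok_len], `[`, character(1), 2)
    tt <- as.POSIXct(tss, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    alt <- is.na(tt)
    if (any(alt))
      tt[alt] <- as.POSIXct(tss[alt], format = "%Y-%m-%d %H:%M:%OS",
                            tz = "UTC")
    ts[ok_len] <- as.numeric(tt)
    lat[ok_len] <- suppressWarnings(
      as.numeric(vapply(parts[ok_len], `[`, character(1), 3)))
    lon[ok_len] <- suppressWarnings(
      as.numeric(vapply(parts[ok_len], `[`, character(1), 4)))
  }
  valid <- !is.na(user) & !is.na(ts) & !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  n_skipped <- sum(!valid)
  if (!any(valid))
    stop("no valid check-in rows in ", path, call. = FALSE)
  df <- tibble::tibble(id = user[valid], ts = ts[valid],
                       lat = lat[valid], lon = lon[valid],
                       ord = seq_len(sum(valid)))
  last <- df |>
    dplyr::arrange(.data$id, .data$ts, .data$ord) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ord) |>
    dplyr::select("id", "lat", "lon")
  ii <- suppressWarnings(as.integer(last$id))
  if (!anyNA(ii)) last$id <- ii
  attr(last, "n_skipped") <- n_skipped
  if (n_skipped > 0)
    message(n_skipped, " malformed check-in row(s) skipped")
  last
}

# ---- run configuration -----------------------------------------------------

config_keys <- c("p_v", "p", "p_c", "delta_km", "jump", "L_target",
                 "max_sweeps", "visit_mode", "neighbor_gate",
                 "annulus_factor", "seed")
jump_keys <- c("family", "exponent", "d_min", "d_max", "mean", "sd")

#' Read and write run configuration files
#'
#' YAML configurations mirror [model_params()] field-for-field, plus a
#' `seed`. Unknown keys are rejected; write-then-read round-trips
#' losslessly.
#'
#' @param path File path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$jump)) {
    ju <- setdiff(names(cfg$jump), jump_keys)
    if (length(ju))
      stop("unknown jump key(s): ", paste(ju, collapse = ", "),
           call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @param config Named list (subset of the [model_params()] fields plus
#'   `seed`).
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build model parameters from a configuration list
#'
#' @param config List as returned by [read_run_config()].
#' @return A [model_params()].
#' @export
config_to_params <- function(config) {
  jump <- if (is.null(config$jump)) jump_spec()
          else do.call(jump_spec, config$jump)
  args <- config[setdiff(names(config), c("jump", "seed"))]
  args$jump <- jump
  do.call(model_params, args)
}

#' Hash a configuration for output provenance
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the deparsed configuration,
#' printed as 8 hex digits; embedded in the header line of every file the
#' CLI writes so that outputs are traceable to their settings.
#'
#' @param config Any R object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# ---- fixtures --------------------------------------------------------------

#' Deterministic synthetic fixtures with known ground truth
#'
#' Generates the test worlds used throughout the package: Gaussian-cities
#' worlds, networks with a planted link-probability slope, planted per-bin
#' reciprocity, planted triangles at separated distance scales, and
#' travel-and-friend reference networks with known generating parameters.
#'
#' @param kind One of `"gaussian_world"`, `"planted_p1_slope"`,
#'   `"planted_reciprocity"`, `"planted_triangles"`, `"tf_reference"`.
#' @param params Named list overriding the kind's defaults (see Details).
#' @param seed Integer seed; outputs are deterministic given `(kind,
#'   params, seed)`.
#' @return List with `grid` ([population_grid] or `NULL`), `positions`,
#'   `net` ([geonet] or `NULL`) and `truth` (the planted parameters).
#' @details
#' `gaussian_world`: `n` agents (default 500) on a 3-city landscape.
#' `planted_p1_slope`: spatial-model network with kernel slope
#' `slope` (default 1) on a uniform landscape.
#' `planted_reciprocity`: node pairs at two distance scales with exact
#' per-scale reciprocated fractions (defaults 0.8 near, 0.2 far).
#' `planted_triangles`: closed triangles at a short scale plus open triads
#' at a long scale.
#' `tf_reference`: a travel-and-friend run at known `(p_v, p_c)`.
#' @export
make_fixture <- function(kind, params = list(), seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  p <- params
  gauss_world <- function(n) {
    grid <- synth_population_grid(
      lat_range = c(40, 50), lon_range = c(0, 12), cellsize = 0.2,
      n_cities = 3, city_weights = c(3, 2, 1), city_sd_km = 40,
      total_population = 1e5)
    list(grid = grid, positions = sample_initial_positions(grid, n))
  }
  switch(kind,
    gaussian_world = {
      n <- p$n %||% 500
      w <- gauss_world(n)
      list(grid = w$grid, positions = w$positions, net = NULL,
           truth = list(n = n, n_cities = 3))
    },
    planted_p1_slope = {
      n <- p$n %||% 1000
      slope <- p$slope %||% 1
      L <- p$L_target %||% (4 * n)
      grid <- population_grid(matrix(1, 40, 40), 0, 40, 0.25)
      positions <- sample_initial_positions(grid, n)
      net <- run_s_model(positions,
                         s_model_params(alpha = slope, d0 = 1,
                                        L_target = L))
      list(grid = grid, positions = positions, net = net,
           truth = list(slope = slope, L_target = L))
    },
    planted_reciprocity = {
      n_pairs <- p$n_pairs %||% 50
      r_near <- p$r_near %||% 0.8
      r_far <- p$r_far %||% 0.2
      d_near <- p$d_near %||% 5
      d_far <- p$d_far %||% 500
      km_per_deg <- pi * 6371 / 180
      build <- function(offset_lat, d_km, n_pairs) {
        lat <- offset_lat + (seq_len(n_pairs) - 1) * 0.5
        tibble::tibble(lat1 = lat, lon1 = 0, lat2 = lat,
                       lon2 = d_km / (km_per_deg * cos(lat * pi / 180)))
      }
      near <- build(0, d_near, n_pairs)
      far <- build(40, d_far, n_pairs)
      nodes <- tibble::tibble(
        id = seq_len(4 * n_pairs),
        lat = c(near$lat1, near$lat2, far$lat1, far$lat2),
        lon = c(near$lon1, near$lon2, far$lon1, far$lon2))
      a_near <- seq_len(n_pairs); b_near <- n_pairs + a_near
      a_far <- 2 * n_pairs + a_near; b_far <- 3 * n_pairs + a_near
      rec_near <- seq_len(round(r_near * n_pairs))
      rec_far <- seq_len(round(r_far * n_pairs))
      edges <- tibble::tibble(
        src = c(a_near, b_near[rec_near], a_far, b_far[rec_far]),
        dst = c(b_near, a_near[rec_near], b_far, a_far[rec_far]))
      list(grid = NULL, positions = nodes, net = geonet(nodes, edges),
           truth = list(r_near = length(rec_near) / n_pairs,
                        r_far = length(rec_far) / n_pairs,
                        d_near = d_near, d_far = d_far))
    },
    planted_triangles = {
      n_tri <- p$n_triangles %||% 4
      n_open <- p$n_open %||% 6
      d_short <- p$d_short %||% 10
      d_long <- p$d_long %||% 1000
      km_per_deg <- pi * 6371 / 180
      nodes <- list(); edges <- list(); nid <- 0
      for (t in seq_len(n_tri)) {
        base_lat <- (t - 1) * 3
        dlon <- d_short / (km_per_deg * cos(base_lat * pi / 180))
        ids <- nid + 1:3; nid <- nid + 3
        nodes[[length(nodes) + 1]] <- tibble::tibble(
          id = ids, lat = c(base_lat, base_lat, base_lat + d_short /
                              km_per_deg * sqrt(3) / 2),
          lon = c(0, dlon, dlon / 2))
        edges[[length(edges) + 1]] <- tibble::tibble(
          src = ids[c(1, 2, 3)], dst = ids[c(2, 3, 1)])
      }
      for (t in seq_len(n_open)) {
        base_lat <- 30 + (t - 1) * 3
        dlon <- d_long / (km_per_deg * cos(base_lat * pi / 180))
        ids <- nid + 1:3; nid <- nid + 3
        nodes[[length(nodes) + 1]] <- tibble::tibble(
          id = ids, lat = rep(base_lat, 3), lon = c(0, dlon, 2 * dlon))
        edges[[length(edges) + 1]] <- tibble::tibble(
          src = ids[c(2, 2)], dst = ids[c(1, 3)])
      }
      nodes <- dplyr::bind_rows(nodes); edges <- dplyr::bind_rows(edges)
      list(grid = NULL, positions = nodes, net = geonet(nodes, edges),
           truth = list(n_triangles = n_tri, n_open = n_open,
                        d_short = d_short, d_long = d_long))
    },
    tf_reference = {
      n <- p$n %||% 300
      p_v <- p$p_v %||% 0.3
      p_c <- p$p_c %||% 0.05
      L <- p$L_target %||% (3 * n)
      w <- gauss_world(n)
      pars <- model_params(p_v = p_v, p_c = p_c, L_target = L,
                           jump = p$jump %||% jump_spec(d_max = 2000))
      sim <- run_tf(pars, w$grid, w$positions)
      list(grid = w$grid, positions = w$positions, net = sim$net,
           truth = list(p_v = p_v, p_c = p_c, L_target = L, sim = sim))
    },
    stop("unknown fixture kind: ", kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
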