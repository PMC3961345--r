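# Shared worlds and tiny networks built in code; everything deterministic.

small_world <- function(n = 200, seed = 7) {
  grid <- synth_population_grid(
    lat_range = c(40, 50), lon_range = c(0, 12), cellsize = 0.2,
    n_cities = 3, city_weights = c(3, 2, 1), city_sd_km = 40,
    total_population = 1e5, seed = seed)
  list(grid = grid,
       positions = sample_initial_positions(grid, n, seed = seed + 1))
}

continental_world <- function(n = 500, seed = 7) {
  grid <- synth_population_grid(
    lat_range = c(25, 50), lon_range = c(-125, -70), cellsize = 0.5,
    n_cities = 6, city_weights = c(4, 3, 2, 2, 1, 1), city_sd_km = 60,
    total_population = 1e5, seed = seed)
  list(grid = grid,
       positions = sample_initial_positions(grid, n, seed = 2))
}

# nodes on the equator at given km offsets (1 deg lon ~ 111.195 km there)
line_nodes <- function(offsets_km) {
  tibble::tibble(id = seq_along(offsets_km), lat = 0,
                 lon = offsets_km / (pi * 6371 / 180))
}

net_from <- function(nodes, src, dst) {
  geonet(nodes, tibble::tibble(src = src, dst = dst))
}

# Erdos-Renyi-ish directed network on jittered positions, for oracle tests
random_geonet <- function(n, n_edges, seed = 1, extent_km = 500) {
  set.seed(seed)
  nodes <- tibble::tibble(
    id = seq_len(n),
    lat = runif(n, 0, extent_km / 111.195),
    lon = runif(n, 0, extent_km / 111.195))
  pairs <- expand.grid(src = seq_len(n), dst = seq_len(n))
  pairs <- pairs[pairs$src != pairs$dst, ]
  pick <- sample.int(nrow(pairs), n_edges)
  geonet(nodes, tibble::as_tibble(pairs[pick, ]))
}
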