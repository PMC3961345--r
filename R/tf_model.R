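#' Travel-and-friend model parameters
#'
#' The coupled dynamics have four behavioural parameters plus a jump-length
#' law: at each activation the chosen agent first moves (visiting a
#' uniformly chosen friend with probability `p_v`, otherwise jumping a
#' sampled distance in a population-weighted direction) and then forms ties
#' (one Bernoulli(`p`) draw gates directed links to every agent inside the
#' `delta_km` x `delta_km` box around it, and independently a
#' Bernoulli(`p_c`) draw gates one directed link to a uniformly chosen
#' agent anywhere). The run stops once `L_target` directed links exist.
#'
#' @param p_v Probability of a friend visit in the travel stage.
#' @param p Probability gating the neighbourhood-linking action
#'   (default 0.1, the calibrated face-to-face linking rate).
#' @param p_c Probability of one global random link per activation.
#' @param delta_km Side of the encounter box in km (default 5).
#' @param jump A [jump_spec()]; default truncated power law with exponent
#'   magnitude 1.55 on \[1, 20000\] km.
#' @param L_target Directed-link count at which the run stops.
#' @param max_sweeps Safety cap on sweeps (a sweep = N activations).
#' @param visit_mode `"out"` (visit someone you follow, default) or
#'   `"union"` (any neighbour in the symmetrized network).
#' @param neighbor_gate `"box"` (one Bernoulli(p) gates the whole box,
#'   default) or `"per_neighbor"` (an independent Bernoulli(p) per
#'   box-mate).
#' @param annulus_factor Relative annulus width for jump-target sampling.
#' @return A `model_params` object.
#' @export
model_params <- function(p_v = 0.3, p = 0.1, p_c = 0.05, delta_km = 5,
                         jump = jump_spec(), L_target = 1000,
                         max_sweeps = 5000,
                         visit_mode = c("out", "union"),
                         neighbor_gate = c("box", "per_neighbor"),
                         annulus_factor = 0.05) {
  stopifnot(p_v >= 0, p_v <= 1, p >= 0, p <= 1, p_c >= 0, p_c <= 1,
            delta_km > 0, L_target >= 1, max_sweeps >= 1,
            inherits(jump, "jump_spec"))
  structure(list(p_v = p_v, p = p, p_c = p_c, delta_km = delta_km,
                 jump = jump, L_target = as.integer(L_target),
                 max_sweeps = as.integer(max_sweeps),
                 visit_mode = match.arg(visit_mode),
                 neighbor_gate = match.arg(neighbor_gate),
                 annulus_factor = annulus_factor),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> p_v=%g p=%g p_c=%g delta=%g km L_target=%d jump=%s\n",
    x$p_v, x$p, x$p_c, x$delta_km, x$L_target, x$jump$family))
  invisible(x)
}

jump_family_code <- function(spec)
  match(spec$family, c("powerlaw", "normal", "uniform")) - 1L

# agents within the delta x delta tangent-plane box centred on (lat0, lon0)
box_mates <- function(positions, agent_idx, delta_km) {
  lat0 <- positions$lat[agent_idx]
  lon0 <- positions$lon[agent_idx]
  km_per_deg <- pi * 6371 / 180
  dlat <- abs(positions$lat - lat0) * km_per_deg
  dlon <- abs(positions$lon - lon0) * km_per_deg * cos(lat0 * pi / 180)
  which(dlat <= delta_km / 2 & dlon <= delta_km / 2 &
          seq_len(nrow(positions)) != agent_idx)
}

#' Travel stage for a single agent
#'
#' With probability `p_v` (and a non-empty friend set) the agent moves to
#' the current location of a uniformly chosen friend; otherwise it jumps a
#' sampled distance towards a population-weighted direction. Agents with no
#' friends always take the random jump. Uses R's global RNG.
#'
#' @param agent_id Node id of the focal agent.
#' @param positions Tibble `id`, `lat`, `lon` of current agent locations.
#' @param edges Tibble `src`, `dst` of current directed edges.
#' @param params A [model_params()].
#' @param grid A [population_grid].
#' @return Tibble with one row: `id`, `lat`, `lon`, `visited`.
#' @export
travel_stage <- function(agent_id, positions, edges, params, grid) {
  i <- match(agent_id, positions$id)
  stopifnot(!is.na(i))
  friends <- if (params$visit_mode == "out") {
    unique(edges$dst[edges$src == agent_id])
  } else {
    unique(c(edges$dst[edges$src == agent_id],
             edges$src[edges$dst == agent_id]))
  }
  if (length(friends) > 0 && stats::runif(1) < params$p_v) {
    f <- friends[sample.int(length(friends), 1)]
    j <- match(f, positions$id)
    return(tibble::tibble(id = agent_id, lat = positions$lat[j],
                          lon = positions$lon[j], visited = TRUE))
  }
  for (try in 1:10) {
    r <- sample_jump_length(params$jump, 1)
    tgt <- sample_jump_target(grid, positions$lat[i], positions$lon[i], r,
                              params$annulus_factor, fallback = "none")
    if (tgt$in_annulus[1])
      return(tibble::tibble(id = agent_id, lat = tgt$lat[1],
                            lon = tgt$lon[1], visited = FALSE))
  }
  tgt <- sample_jump_target(grid, positions$lat[i], positions$lon[i], r,
                            params$annulus_factor, fallback = "closest")
  tibble::tibble(id = agent_id, lat = tgt$lat[1], lon = tgt$lon[1],
                 visited = FALSE)
}

#' Friendship stage for a single agent
#'
#' One Bernoulli(`p`) draw gates the creation of directed links from the
#' agent to every other agent inside its `delta_km` box (existing links and
#' self excluded; or an independent Bernoulli(p) per box-mate under the
#' `"per_neighbor"` gate). Independently, one Bernoulli(`p_c`) draw gates a
#' directed link to a uniformly chosen non-self agent (redrawn while the
#' edge already exists, up to 50 tries). Both actions can fire in the same
#' activation. Uses R's global RNG.
#'
#' @inheritParams travel_stage
#' @return Tibble of created edges (`src`, `dst`); zero rows if none.
#' @export
friendship_stage <- function(agent_id, positions, edges, params) {
  i <- match(agent_id, positions$id)
  stopifnot(!is.na(i))
  new_src <- integer(); new_dst <- integer()
  has_edge <- function(a, b)
    any(edges$src == a & edges$dst == b) ||
      (length(new_src) && any(new_src == a & new_dst == b))
  if (params$neighbor_gate == "box") {
    if (stats::runif(1) < params$p) {
      for (j in box_mates(positions, i, params$delta_km)) {
        b <- positions$id[j]
        if (!has_edge(agent_id, b)) {
          new_src <- c(new_src, agent_id); new_dst <- c(new_dst, b)
        }
      }
    }
  } else {
    for (j in box_mates(positions, i, params$delta_km)) {
      if (stats::runif(1) < params$p) {
        b <- positions$id[j]
        if (!has_edge(agent_id, b)) {
          new_src <- c(new_src, agent_id); new_dst <- c(new_dst, b)
        }
      }
    }
  }
  if (stats::runif(1) < params$p_c && nrow(positions) > 1) {
    for (try in 1:50) {
      b <- positions$id[sample.int(nrow(positions), 1)]
      if (b != agent_id && !has_edge(agent_id, b)) {
        new_src <- c(new_src, agent_id); new_dst <- c(new_dst, b)
        break
      }
    }
  }
  tibble::tibble(src = new_src, dst = new_dst)
}

#' Run the travel-and-friend simulation
#'
#' Iterates single-agent activations (uniform with replacement; one sweep =
#' N activations) of the travel and friendship stages until the directed
#' link count reaches `params$L_target` (the last batch of links is
#' truncated so the count is met exactly) or `max_sweeps` is exhausted, in
#' which case the partial result is flagged. Runs are deterministic given
#' `seed`.
#'
#' @param params A [model_params()].
#' @param grid A [population_grid].
#' @param positions Tibble `id`, `lat`, `lon` of initial agent locations
#'   (at least 2 agents; `L_target < N(N-1)`).
#' @param seed Optional integer seed (local to this call).
#' @param log_creation Record distance and mechanism of each created edge.
#' @return A `tf_sim` object: `net` (final [geonet]), `series` (per-sweep
#'   link and unique-location counts), `n_sweeps`, `n_activations`,
#'   `hit_max_steps`, `seed`, `params`, and optionally `creation_log`.
#' @export
run_tf <- function(params, grid, positions, seed = NULL,
                   log_creation = FALSE) {
  stopifnot(inherits(params, "model_params"),
            inherits(grid, "population_grid"))
  positions <- tibble::as_tibble(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 agents", call. = FALSE)
  if (params$L_target >= n * (n - 1))
    stop("L_target must be below N(N-1)", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  res <- cpp_run_tf(
    positions$lat, positions$lon,
    grid$counts, grid$xllcorner, grid$yllcorner, grid$cellsize,
    params$p_v, params$p, params$p_c, params$delta_km,
    jump_family_code(params$jump), params$jump$exponent,
    params$jump$d_min, params$jump$d_max,
    params$jump$mean, params$jump$sd, params$annulus_factor,
    params$L_target, params$max_sweeps,
    params$visit_mode == "union",
    params$neighbor_gate == "per_neighbor",
    log_creation)
  nodes <- tibble::tibble(id = positions$id, lat = res$lat, lon = res$lon)
  edges <- tibble::tibble(src = positions$id[res$src + 1L],
                          dst = positions$id[res$dst + 1L])
  out <- structure(list(
    net = geonet(nodes, edges),
    series = tibble::tibble(
      sweep = seq_along(res$links_per_sweep),
      links = res$links_per_sweep,
      unique_locations = n + res$jumps_per_sweep),
    n_sweeps = res$n_sweeps,
    n_activations = res$n_activations,
    hit_max_steps = res$hit_max_steps,
    seed = seed, params = params), class = "tf_sim")
  if (log_creation)
    out$creation_log <- tibble::tibble(
      src = edges$src, dst = edges$dst,
      distance_km = res$creation_dist,
      mechanism = c("neighborhood", "random")[res$creation_mech])
  if (res$hit_max_steps)
    warning("max_sweeps reached before L_target; partial result returned",
            call. = FALSE)
  out
}

#' @export
print.tf_sim <- function(x, ...) {
  cat(sprintf(
    "<tf_sim> %d nodes, %d/%d links in %d sweeps (%s)\n",
    n_nodes(x$net), n_edges(x$net), x$params$L_target, x$n_sweeps,
    if (x$hit_max_steps) "max steps hit" else "target reached"))
  invisible(x)
}

#' @method tidy tf_sim
#' @export
tidy.tf_sim <- function(x, ...) x$series

#' @method glance tf_sim
#' @export
glance.tf_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_sweeps = x$n_sweeps,
                   n_activations = x$n_activations,
                   hit_max_steps = x$hit_max_steps),
    glance.geonet(x$net))
}

#' Run a travel-and-friend variant with a substituted jump law
#'
#' Identical to [run_tf()] but with the jump-length law replaced, used to
#' contrast the default heavy-tailed displacements with normal or uniform
#' travel distances.
#'
#' @inheritParams run_tf
#' @param jump A [jump_spec()] replacing `params$jump`.
#' @return A `tf_sim` object.
#' @export
run_tf_variant <- function(params, jump, grid, positions, seed = NULL,
                           log_creation = FALSE) {
  stopifnot(inherits(jump, "jump_spec"))
  params$jump <- jump
  run_tf(params, grid, positions, seed = seed, log_creation = log_creation)
}
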