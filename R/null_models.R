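#' Spatial (S) model parameters
#'
#' The geography-only null model: directed links are placed at random with
#' a probability that decays as a power of the distance between the users,
#' with no network-structure mechanism (no triadic closure, no deliberate
#' reciprocity).
#'
#' @param alpha Power-law decay exponent of the link kernel (>= 0).
#' @param d0 Lower distance cutoff in km (pairs closer than `d0` weigh as
#'   if at `d0`).
#' @param L_target Number of directed links to place.
#' @return An `s_model_params` object.
#' @export
s_model_params <- function(alpha = 0.7, d0 = 1, L_target = 1000) {
  stopifnot(alpha >= 0, d0 > 0, L_target >= 1)
  structure(list(alpha = alpha, d0 = d0, L_target = as.integer(L_target)),
            class = "s_model_params")
}

#' Run the spatial null model
#'
#' Samples exactly `L_target` distinct directed edges without replacement,
#' weighting each ordered pair `(i, j)` by
#' `max(d_ij, d0)^(-alpha)`. Agent positions are left untouched.
#'
#' @param positions Tibble `id`, `lat`, `lon` (>= 2 rows).
#' @param sparams An [s_model_params()].
#' @param seed Optional integer seed (local to this call).
#' @return A [geonet].
#' @export
run_s_model <- function(positions, sparams, seed = NULL) {
  stopifnot(inherits(sparams, "s_model_params"))
  positions <- tibble::as_tibble(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 positions", call. = FALSE)
  if (sparams$L_target > n * (n - 1))
    stop("L_target exceeds the number of possible directed edges",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  # unordered pair weights; each unordered pair stands for 2 directed edges
  iu <- rep(seq_len(n - 1), times = (n - 1):1)
  ju <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  d <- cpp_haversine(positions$lat[iu], positions$lon[iu],
                     positions$lat[ju], positions$lon[ju])
  w <- pmax(d, sparams$d0)^(-sparams$alpha)
  # directed sampling: duplicate each unordered pair in both orientations.
  # Weighted sampling without replacement via the exponential race: the
  # L_target smallest Exp(w) arrival times form an exact weighted sample.
  wdir <- c(w, w)
  src <- c(iu, ju); dst <- c(ju, iu)
  keys <- stats::rexp(length(wdir)) / wdir
  pick <- order(keys)[seq_len(sparams$L_target)]
  geonet(positions,
         tibble::tibble(src = positions$id[src[pick]],
                        dst = positions$id[dst[pick]]))
}

#' Linking (L) model parameters
#'
#' The structure-only null model: the coupled model without geography. Per
#' sweep each agent visits a uniformly chosen out-neighbour with
#' probability `p_v` (abstract co-presence at the host) or idles, and with
#' probability `p_c` adds one random directed link. At sweep end every
#' unordered pair of a host's visitors creates each missing directed link
#' between them with probability `p_enc`, and each visitor's link to the
#' host is reciprocated with probability `q` if missing.
#'
#' @param p_v Visit probability per agent per sweep.
#' @param p_c Random-link probability per agent per sweep.
#' @param p_enc Probability a co-visiting pair creates a missing directed
#'   link (per direction).
#' @param q Probability the host reciprocates a visitor's link.
#' @param sweeps Number of sweeps to simulate.
#' @return An `l_model_params` object.
#' @export
l_model_params <- function(p_v = 0.5, p_c = 0.05, p_enc = 1, q = 1,
                           sweeps = 200) {
  stopifnot(p_v >= 0, p_v <= 1, p_c >= 0, p_c <= 1,
            p_enc >= 0, p_enc <= 1, q >= 0, q <= 1, sweeps >= 1)
  structure(list(p_v = p_v, p_c = p_c, p_enc = p_enc, q = q,
                 sweeps = as.integer(sweeps)),
            class = "l_model_params")
}

#' Run the linking null model
#'
#' Simulates the visit-driven triadic-closure process on `n_agents` agents
#' starting from an empty network, recording the global clustering
#' coefficient, reciprocity and link count after every sweep. Positions are
#' never used; to measure geo-social statistics of an L-model network,
#' attach externally supplied positions via the `positions` argument.
#'
#' @param n_agents Number of agents (>= 3).
#' @param lparams An [l_model_params()].
#' @param seed Optional integer seed (local to this call).
#' @param positions Optional tibble `id`, `lat`, `lon` of length
#'   `n_agents`; defaults to dummy coordinates at the origin cell.
#' @param log_events Record the mechanism (random / closure /
#'   reciprocation) of every created edge.
#' @return An `l_sim` object: `net` ([geonet]), `series` (per-sweep tibble
#'   `sweep`, `C`, `R`, `links`), `degree` (final union degrees),
#'   `params`, `seed`, and optionally `events`.
#' @export
run_l_model <- function(n_agents, lparams, seed = NULL, positions = NULL,
                        log_events = FALSE) {
  stopifnot(inherits(lparams, "l_model_params"), n_agents >= 3)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  res <- cpp_run_l_model(n_agents, lparams$p_v, lparams$p_c, lparams$p_enc,
                         lparams$q, lparams$sweeps, log_events)
  if (is.null(positions)) {
    positions <- tibble::tibble(id = seq_len(n_agents),
                                lat = rep(0, n_agents),
                                lon = rep(0, n_agents))
  } else {
    positions <- tibble::as_tibble(positions)
    stopifnot(nrow(positions) == n_agents)
  }
  edges <- tibble::tibble(src = positions$id[res$src + 1L],
                          dst = positions$id[res$dst + 1L])
  out <- structure(list(
    net = geonet(positions, edges),
    series = tibble::tibble(sweep = seq_along(res$C), C = res$C, R = res$R,
                            links = res$L),
    degree = res$degree,
    n_triads = res$n_triads, n_triangles = res$n_triangles,
    params = lparams, seed = seed), class = "l_sim")
  if (log_events)
    out$events <- tibble::tibble(
      src = edges$src, dst = edges$dst,
      mechanism = c("random", "closure", "reciprocation")[res$mech + 1L])
  out
}

#' @export
print.l_sim <- function(x, ...) {
  last <- nrow(x$series)
  cat(sprintf(
    "<l_sim> %d agents, %d sweeps, %d links, C=%.3f R=%.3f\n",
    n_nodes(x$net), last, x$series$links[last], x$series$C[last],
    x$series$R[last]))
  invisible(x)
}

#' @method tidy l_sim
#' @export
tidy.l_sim <- function(x, ...) x$series

#' @method glance l_sim
#' @export
glance.l_sim <- function(x, ...) {
  last <- nrow(x$series)
  tibble::tibble(n_agents = n_nodes(x$net), sweeps = last,
                 links = x$series$links[last],
                 C = x$series$C[last], R = x$series$R[last])
}
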