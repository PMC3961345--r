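#' Mean-field parameters for the linking model
#'
#' Deterministic difference equations for the expected evolution of the
#' linking model: degree counts `N_k` (undirected-union degree; in- and
#' out-degree are not distinguished), triads and closed triads,
#' reciprocated / non-reciprocated directed link counts, and the
#' zero-out-degree correction. One integration step corresponds to one
#' model sweep.
#'
#' @param n Number of agents.
#' @param p_v,p_c,p_enc,q As in [l_model_params()].
#' @param k_max Degree cutoff for the master equation (>= 10). Degree mass
#'   leaking past `k_max` must stay below `1e-6 * n` or the integrator
#'   aborts asking for a larger cutoff.
#' @param sweeps Number of steps.
#' @param M Lower-bound estimate of the number of triangles closed by one
#'   closing link (default 1: at least the triangle through the host).
#' @return A `meanfield_params` object.
#' @export
meanfield_params <- function(n, p_v = 0.5, p_c = 0.05, p_enc = 1, q = 1,
                             k_max = 150, sweeps = 200, M = 1) {
  stopifnot(n >= 3, p_v >= 0, p_v <= 1, p_c >= 0, p_c <= 1,
            p_enc >= 0, p_enc <= 1, q >= 0, q <= 1,
            k_max >= 10, sweeps >= 1, M >= 1)
  structure(list(n = n, p_v = p_v, p_c = p_c, p_enc = p_enc, q = q,
                 k_max = as.integer(k_max), sweeps = as.integer(sweeps),
                 M = M),
            class = "meanfield_params")
}

#' Mean-field state
#'
#' @param N_k Expected node counts by union degree, `k = 0, 1, ...`
#'   (position 1 is degree 0).
#' @param T_closed Expected closed-triad count.
#' @param L_r,L_nr Reciprocated / non-reciprocated directed link counts.
#' @param N_0out Expected number of nodes with zero out-degree but non-zero
#'   in-degree (they cannot visit, so they dampen the encounter rate until
#'   their link is reciprocated).
#' @return A `meanfield_state` object.
#' @export
meanfield_state <- function(N_k, T_closed = 0, L_r = 0, L_nr = 0,
                            N_0out = 0) {
  stopifnot(all(N_k >= 0), T_closed >= 0, L_r >= 0, L_nr >= 0, N_0out >= 0)
  structure(list(N_k = as.numeric(N_k), T_closed = T_closed,
                 L_r = L_r, L_nr = L_nr, N_0out = N_0out),
            class = "meanfield_state")
}

# number of triads implied by a degree-count vector
triads_from_Nk <- function(N_k) {
  k <- seq_along(N_k) - 1
  sum(N_k * k * (k - 1) / 2)
}

#' Expected encounters per host
#'
#' The expected number of co-visitor pairs at a host per sweep. A neighbour
#' of degree `k'` visits the host with probability `p_v / k'`; averaging
#' over the edge-biased neighbour degree distribution gives a per-edge
#' visit rate `phi = p_v * (N_act - N_0out) / sum_k k N_k`, and a host of
#' degree `k` then receives `Binomial(k, phi)` visitors, hence
#' `choose(k, 2) * phi^2` expected encounter pairs. The returned `S`
#' averages over the active (degree > 0) hosts. `S` is zero when no node
#' has friends or when `p_v = 0`, and is non-decreasing in `p_v`.
#'
#' @param state A [meanfield_state()].
#' @param params A [meanfield_params()].
#' @return The scalar `S`.
#' @export
expected_encounters <- function(state, params) {
  stopifnot(inherits(state, "meanfield_state"),
            inherits(params, "meanfield_params"))
  k <- seq_along(state$N_k) - 1
  N_act <- sum(state$N_k[k >= 1])
  K <- sum(k * state$N_k)
  if (N_act <= 0 || K <= 0 || params$p_v == 0) return(0)
  phi <- params$p_v * max(N_act - state$N_0out, 0) / K
  sum(state$N_k * k * (k - 1) / 2 * phi^2) / N_act
}

#' Integrate the linking-model mean-field equations
#'
#' Forward-Euler integration with a step of one model sweep, from an empty
#' network by default. Per step the integrator computes the per-edge visit
#' rate and the expected encounters `S`, grows the closed-triad count by
#' `3 * M * p_u * (1 - C) * N_act * S` (closure is visit-driven only; `p_u
#' = 1 - (1 - p_enc)^2` is the chance an encounter creates the union link,
#' and the `1 - C` factor discounts co-visitor pairs that are already
#' connected), evolves the reciprocated / non-reciprocated directed link
#' counts (random links enter non-reciprocated; encounters create mutual
#' pairs with probability `p_enc^2`; visits along a non-reciprocated link
#' convert it with probability `q`), advances the degree master equation
#' with per-step promotion probabilities `g_0 = 1 - (1 - p_c)^2` and `g_k =
#' g_0 + 2 p_u (1 - C) N_act S / N_act` for `k >= 1`, and applies the
#' zero-out-degree correction.
#'
#' @param params A [meanfield_params()].
#' @param initial_state Optional [meanfield_state()]; default: all `n`
#'   nodes at degree 0, no links.
#' @return A `meanfield_fit`: `series` tibble (`step`, `C`, `R`, `links`),
#'   `degree_p` (final `P(k)` over `0:k_max`), `state` (final), `params`,
#'   `leak` (degree mass lost past `k_max`).
#' @export
meanfield_integrate <- function(params, initial_state = NULL) {
  stopifnot(inherits(params, "meanfield_params"))
  kmx <- params$k_max
  if (is.null(initial_state)) {
    N_k <- c(params$n, numeric(kmx))
    st <- meanfield_state(N_k)
  } else {
    st <- initial_state
    stopifnot(inherits(st, "meanfield_state"))
    if (length(st$N_k) < kmx + 1)
      st$N_k <- c(st$N_k, numeric(kmx + 1 - length(st$N_k)))
  }
  n <- params$n
  p_u <- 1 - (1 - params$p_enc)^2
  C_t <- numeric(params$sweeps)
  R_t <- numeric(params$sweeps)
  L_t <- numeric(params$sweeps)
  leak <- 0
  k <- 0:kmx
  for (s in seq_len(params$sweeps)) {
    N_k <- st$N_k
    N_act <- sum(N_k[-1])
    K <- sum(k * N_k)
    T_tot <- triads_from_Nk(N_k)
    C_now <- if (T_tot > 0) min(st$T_closed / T_tot, 1) else 0
    S <- expected_encounters(st, params)
    E <- S * N_act                       # encounter pairs per sweep
    sat <- max(1 - C_now, 0)             # co-visitors already linked
    new_union <- p_u * E * sat           # closing links per sweep

    # Closed triads: visit-driven growth only. Each closing link closes
    # the host triangle (M) plus the expected common neighbours of the
    # pair: the uncorrelated-wiring background (sum_k N_k k^2 / N_act^2)
    # and, within the edge-biased host's neighbourhood of expected size
    # <k^2>/<k>, other neighbours linked to both co-visitors, estimated
    # under independence as C^2 per candidate. Visitor triples coinciding
    # at a host in the same sweep (third moment of the binomial visitor
    # count) close one extra triangle per triple.
    club <- if (K > 0) max(sum(N_k * k^2) / K - 2, 0) * C_now^2 else 0
    M_t <- if (N_act > 0)
      params$M + sum(N_k * k^2) / N_act^2 + club else params$M
    phi_e <- if (K > 0) params$p_v * max(N_act - st$N_0out, 0) / K else 0
    E3 <- sum(N_k * k * (k - 1) * (k - 2) / 6) * phi_e^3
    st$T_closed <- st$T_closed + 3 * (M_t * new_union + p_u^3 * E3 * sat)

    # directed links
    conv <- if (st$L_r + st$L_nr > 0) {
      V <- params$p_v * max(N_act - st$N_0out, 0)
      min(params$q * V * st$L_nr / (st$L_r + st$L_nr), st$L_nr)
    } else 0
    st$L_r <- st$L_r + 2 * params$p_enc^2 * E * sat + 2 * conv
    st$L_nr <- st$L_nr + n * params$p_c +
      2 * params$p_enc * (1 - params$p_enc) * E * sat - conv

    # degree master equation
    g0 <- 1 - (1 - params$p_c)^2
    g_enc <- if (N_act > 0) 2 * new_union / N_act else 0
    g <- pmin(c(g0, rep(g0 + g_enc, kmx)), 1)
    up <- g * N_k
    N_new <- N_k - up
    N_new[-1] <- N_new[-1] + up[-(kmx + 1)]
    leak <- leak + up[kmx + 1]
    if (leak > 1e-6 * n)
      stop("degree mass leaking past k_max; increase k_max", call. = FALSE)
    st$N_k <- N_new

    # zero-out-degree correction
    N0 <- N_k[1]
    phi <- if (K > 0) params$p_v * max(N_act - st$N_0out, 0) / K else 0
    st$N_0out <- st$N_0out + params$p_c * (1 - params$p_c) * N0 -
      st$N_0out * min(params$p_c + params$q * phi, 1)
    st$N_0out <- min(max(st$N_0out, 0), sum(st$N_k[-1]))

    T_tot <- triads_from_Nk(st$N_k)
    C_t[s] <- if (T_tot > 0) min(st$T_closed / T_tot, 1) else 0
    R_t[s] <- if (st$L_r + st$L_nr > 0) st$L_r / (st$L_r + st$L_nr) else 0
    L_t[s] <- st$L_r + st$L_nr
  }
  structure(list(
    series = tibble::tibble(step = seq_len(params$sweeps), C = C_t,
                            R = R_t, links = L_t),
    degree_p = st$N_k / n,
    state = st, params = params, leak = leak),
    class = "meanfield_fit")
}

#' @export
print.meanfield_fit <- function(x, ...) {
  last <- nrow(x$series)
  cat(sprintf(
    "<meanfield_fit> n=%d, %d steps, C=%.3f R=%.3f\n",
    x$params$n, last, x$series$C[last], x$series$R[last]))
  invisible(x)
}

#' @method tidy meanfield_fit
#' @export
tidy.meanfield_fit <- function(x, ...) x$series

#' @method glance meanfield_fit
#' @export
glance.meanfield_fit <- function(x, ...) {
  last <- nrow(x$series)
  tibble::tibble(n = x$params$n, steps = last,
                 C = x$series$C[last], R = x$series$R[last],
                 leak = x$leak)
}

#' Compare mean-field predictions with linking-model simulation
#'
#' Relative errors of the clustering coefficient and the reciprocity at
#' final time, and the total-variation distance between the final degree
#' distributions. The low random-link regime (`p_c` below
#' `low_pc_threshold`) is flagged `expected_degraded`: when random links
#' are scarce relative to visit-driven links, degree-degree correlations
#' build up and the uncorrelated approximation worsens.
#'
#' @param mf A `meanfield_fit` from [meanfield_integrate()].
#' @param sim An `l_sim` from [run_l_model()] (or a list of them; their
#'   series are averaged). Parameters must match the mean-field parameters.
#' @param low_pc_threshold Regime flag threshold on `p_c`.
#' @return Tibble with `C_mf`, `C_sim`, `rel_err_C`, `R_mf`, `R_sim`,
#'   `rel_err_R`, `tv_degree`, `expected_degraded`.
#' @export
compare_to_simulation <- function(mf, sim, low_pc_threshold = 0.01) {
  stopifnot(inherits(mf, "meanfield_fit"))
  sims <- if (inherits(sim, "l_sim")) list(sim) else sim
  stopifnot(all(vapply(sims, inherits, logical(1), "l_sim")))
  for (s in sims) {
    p <- s$params
    if (n_nodes(s$net) != mf$params$n ||
        !isTRUE(all.equal(
          c(p$p_v, p$p_c, p$p_enc, p$q, as.numeric(p$sweeps)),
          c(mf$params$p_v, mf$params$p_c, mf$params$p_enc, mf$params$q,
            as.numeric(mf$params$sweeps)))))
      stop("simulation and mean-field parameters do not match",
           call. = FALSE)
  }
  lastC <- mean(vapply(sims, function(s) s$series$C[nrow(s$series)],
                       numeric(1)))
  lastR <- mean(vapply(sims, function(s) s$series$R[nrow(s$series)],
                       numeric(1)))
  mC <- mf$series$C[nrow(mf$series)]
  mR <- mf$series$R[nrow(mf$series)]
  kmx <- mf$params$k_max
  deg_p_sim <- rowMeans(vapply(sims, function(s) {
    h <- tabulate(pmin(s$degree, kmx) + 1L, kmx + 1L)
    h / sum(h)
  }, numeric(kmx + 1)))
  tv <- 0.5 * sum(abs(deg_p_sim - mf$degree_p))
  tibble::tibble(
    C_mf = mC, C_sim = lastC,
    rel_err_C = if (lastC > 0) abs(mC - lastC) / lastC else NA_real_,
    R_mf = mR, R_sim = lastR,
    rel_err_R = if (lastR > 0) abs(mR - lastR) / lastR else NA_real_,
    tv_degree = tv,
    expected_degraded = mf$params$p_c < low_pc_threshold)
}
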