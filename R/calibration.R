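#' Compute the calibration property set of a network
#'
#' The eight properties entering the multi-property model-data discrepancy:
#' link probability `P1(d)`, degree distribution `P(k)`, reciprocity
#' `R(d)`, social overlap `J_f(d)`, clustering `C(d)`, triangle-disparity
#' distribution `P(D)`, the number of connected nodes `N_c`, and the mean
#' local clustering coefficient. When `binnings` is `NULL` (reference
#' side), data-driven binnings are derived and attached; pass the reference
#' object's `binnings` to evaluate a model network on the same bins, which
#' fixes the number of comparison terms per property.
#'
#' @param net A [geonet].
#' @param binnings Optional binnings from a reference property set.
#' @param pair_budget Pair budget for [link_probability_curve()].
#' @param n_disparity_bins Histogram bins for `P(D)`.
#' @param n_bins Distance bins per curve when deriving reference binnings;
#'   comparisons want coarser bins than displays so that every bin carries
#'   enough links for the normalized error to be signal- rather than
#'   noise-dominated.
#' @return A `property_set` list with elements `p1`, `pk`, `r`, `jf`, `cd`,
#'   `pd`, `n_connected`, `mean_local_clustering` and `binnings`.
#' @export
network_properties <- function(net, binnings = NULL, pair_budget = 1e7,
                               n_disparity_bins = 20, n_bins = 30) {
  ref_mode <- is.null(binnings)
  p1 <- link_probability_curve(net, bins = binnings$p1,
                               pair_budget = pair_budget, n_bins = n_bins)
  r <- tryCatch(reciprocity_curve(net, bins = binnings$r, n_bins = n_bins),
                error = function(e) NULL)
  jf <- tryCatch(overlap_curve(net, bins = binnings$jf, n_bins = n_bins),
                 error = function(e) NULL)
  cd <- clustering_curve(net, bins = binnings$cd, n_bins = n_bins)
  pk <- degree_distribution(net)
  k_max <- if (ref_mode) max(pk$k) else binnings$k_max
  pk_vec <- numeric(k_max + 1)
  kk <- pk$k[pk$k <= k_max]
  pk_vec[kk + 1] <- pk$p[pk$k <= k_max]
  nb_d <- if (ref_mode) n_disparity_bins else binnings$n_disparity_bins
  pd <- disparity_distribution(net, n_bins = nb_d)
  s <- scalar_summary(net)
  structure(list(
    p1 = p1, pk = pk_vec, r = r, jf = jf, cd = cd, pd = pd,
    n_connected = s$n_connected,
    mean_local_clustering = s$mean_local_clustering,
    binnings = list(
      p1 = curve_bins(p1),
      r = if (!is.null(r)) curve_bins(r),
      jf = if (!is.null(jf)) curve_bins(jf),
      cd = curve_bins(cd),
      k_max = k_max, n_disparity_bins = nb_d)),
    class = "property_set")
}

#' Per-property discrepancy
#'
#' The normalized error of one property between a reference and a model:
#' `E_X = (1/n) * sum_i |a_i - b_i| / (|a_i| + |b_i|)`, where `i` runs over
#' the `n` bins on which both sides are defined (a scalar has one term);
#' `0/0` terms contribute 0. The statistic is symmetric, bounded in
#' \[0, 1\], and insensitive to the property's order of magnitude.
#'
#' @param reference,model Numeric vectors (aligned bins, `NA` = undefined
#'   bin) or `metric_curve`s on identical binnings, or scalars.
#' @return The scalar `E_X`.
#' @export
property_error <- function(reference, model) {
  a <- if (inherits(reference, "metric_curve")) reference$value
       else as.numeric(reference)
  b <- if (inherits(model, "metric_curve")) model$value
       else as.numeric(model)
  if (inherits(reference, "metric_curve") &&
      inherits(model, "metric_curve") &&
      !isTRUE(all.equal(curve_bins(reference), curve_bins(model))))
    stop("curves are on different binnings", call. = FALSE)
  if (length(a) != length(b))
    stop("properties have different lengths", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("no overlapping defined bins", call. = FALSE)
  a <- a[ok]; b <- b[ok]
  terms <- ifelse(a == 0 & b == 0, 0, abs(a - b) / (abs(a) + abs(b)))
  mean(terms)
}

#' Total multi-property error
#'
#' Unweighted mean of the eight per-property discrepancies between a
#' reference and a model property set (see [network_properties()] and
#' [property_error()]). Distribution-valued properties whose curve is
#' missing on one side (e.g. an edgeless model network) score the maximal
#' error 1 for that property.
#'
#' @param reference,model `property_set` objects; the model side must have
#'   been computed with the reference's binnings.
#' @return Tibble with `err` and per-property columns `e_p1`, `e_pk`,
#'   `e_r`, `e_jf`, `e_cd`, `e_pd`, `e_nc`, `e_lc`.
#' @export
total_err <- function(reference, model) {
  stopifnot(inherits(reference, "property_set"),
            inherits(model, "property_set"))
  curve_err <- function(a, b) {
    if (is.null(a) || is.null(b)) return(1)
    tryCatch(property_error(a, b), error = function(e) 1)
  }
  e <- c(
    e_p1 = curve_err(reference$p1, model$p1),
    e_pk = property_error(reference$pk, model$pk),
    e_r = curve_err(reference$r, model$r),
    e_jf = curve_err(reference$jf, model$jf),
    e_cd = curve_err(reference$cd, model$cd),
    e_pd = curve_err(reference$pd$value, model$pd$value),
    e_nc = property_error(reference$n_connected, model$n_connected),
    e_lc = property_error(reference$mean_local_clustering,
                          model$mean_local_clustering))
  dplyr::bind_cols(tibble::tibble(err = mean(e)), tibble::as_tibble(as.list(e)))
}

#' Pool property sets over reference replicas
#'
#' Averages the property sets of several reference networks generated by
#' the same process, yielding an estimate of the process's expected
#' properties: distance curves are combined by pooling per-bin counts,
#' distributions and scalars by averaging. All sets must share the first
#' set's binnings (compute the others with `binnings = first$binnings`).
#' Pooling suppresses single-realization noise in the reference, which
#' otherwise shifts the whole error surface coherently.
#'
#' @param ps_list List of `property_set` objects on common binnings.
#' @return A pooled `property_set`.
#' @export
pool_property_sets <- function(ps_list) {
  stopifnot(length(ps_list) >= 1,
            all(vapply(ps_list, inherits, logical(1), "property_set")))
  out <- ps_list[[1]]
  if (length(ps_list) == 1) return(out)
  for (nm in c("p1", "r", "jf", "cd")) {
    if (any(vapply(ps_list, function(p) is.null(p[[nm]]), logical(1)))) {
      out[nm] <- list(NULL)
      next
    }
    vs <- vapply(ps_list, function(p) {
      x <- p[[nm]]$value * p[[nm]]$n
      x[is.na(x)] <- 0
      x
    }, numeric(nrow(out[[nm]])))
    ns <- vapply(ps_list, function(p) p[[nm]]$n,
                 numeric(nrow(out[[nm]])))
    tot <- rowSums(ns)
    out[[nm]]$value <- ifelse(tot > 0, rowSums(vs) / tot, NA_real_)
    out[[nm]]$n <- tot
  }
  out$pk <- rowMeans(vapply(ps_list, function(p) p$pk,
                            numeric(length(out$pk))))
  out$pd$value <- rowMeans(vapply(ps_list, function(p) p$pd$value,
                                  numeric(nrow(out$pd))))
  out$n_connected <- mean(vapply(ps_list, function(p) p$n_connected,
                                 numeric(1)))
  out$mean_local_clustering <- mean(vapply(
    ps_list, function(p) p$mean_local_clustering, numeric(1)))
  out
}

#' Latin-square design over (p_v, p_c)
#'
#' `k` levels of the visit probability on a linear grid and `k` levels of
#' the random-link probability on a logarithmic grid; the design picks `k`
#' cells such that every row and every column is used exactly once.
#'
#' @param k Number of levels (>= 2).
#' @param p_v_range,p_c_range Length-2 ranges (`p_c_range` must be
#'   positive).
#' @return Tibble `row`, `col`, `p_v`, `p_c`.
#' @export
latin_square_design <- function(k, p_v_range = c(0.05, 0.95),
                                p_c_range = c(0.001, 0.3)) {
  stopifnot(k >= 2, all(p_c_range > 0))
  p_v_levels <- seq(p_v_range[1], p_v_range[2], length.out = k)
  p_c_levels <- exp(seq(log(p_c_range[1]), log(p_c_range[2]),
                        length.out = k))
  col <- sample.int(k)
  tibble::tibble(row = seq_len(k), col = col,
                 p_v = p_v_levels, p_c = p_c_levels[col])
}

#' Latin-square calibration scan
#'
#' Evaluates the total error [total_err()] of the travel-and-friend model
#' against a reference network over a Latin-square design in
#' `(p_v, p_c)`: each design cell is simulated `replicas` times with
#' derived seeds and its error averaged. Deterministic given `seed`.
#'
#' @param reference A [geonet] (the reference network) or a precomputed
#'   `property_set`.
#' @param grid A [population_grid] (the world the model runs on).
#' @param positions Initial agent positions for the model runs.
#' @param base_params [model_params()] supplying everything but `p_v`,
#'   `p_c`.
#' @param k Design size.
#' @param replicas Model replicas per design cell.
#' @param p_v_range,p_c_range Scanned ranges.
#' @param seed Optional integer seed (local to this call).
#' @param pair_budget Pair budget for the link-probability curves.
#' @param n_bins Distance bins per comparison curve (see
#'   [network_properties()]); the coarse default keeps per-bin link counts
#'   high enough that the error surface reflects parameters, not binning
#'   noise.
#' @param cells `"design"` (default: the k Latin-design cells) or `"all"`
#'   (every cell of the k x k grid, i.e. the union of the k disjoint
#'   cyclic shifts of a Latin square). The full grid is what a recovery
#'   experiment needs when the error surface has a narrow valley whose
#'   bottom a k-cell design rarely samples.
#' @param measure_at `"final"` (statistics at the agents' simulated final
#'   positions, default) or `"initial"` (at the supplied positions, the
#'   analogue of users' last known positions, which preserves the
#'   creation-distance signature of the random-link rate).
#' @return A `latin_scan` tibble (`p_v`, `p_c`, `err`, per-property
#'   columns) with attribute `best` (the minimizing row).
#' @export
latin_square_scan <- function(reference, grid, positions, base_params,
                              k = 7, replicas = 3,
                              p_v_range = c(0.05, 0.95),
                              p_c_range = c(0.001, 0.3), seed = NULL,
                              pair_budget = 1e6, n_bins = 10,
                              cells = c("design", "all"),
                              measure_at = c("final", "initial")) {
  cells <- match.arg(cells)
  measure_at <- match.arg(measure_at)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  ref_props <- if (inherits(reference, "property_set")) reference
               else network_properties(reference, pair_budget = pair_budget,
                                       n_bins = n_bins)
  eval_cell <- function(p_v, p_c) {
    pars <- base_params
    pars$p_v <- p_v
    pars$p_c <- p_c
    errs <- purrr::map(seq_len(replicas), function(rep) {
      run_seed <- sample.int(.Machine$integer.max - 1, 1)
      sim <- suppressWarnings(
        run_tf(pars, grid, positions, seed = run_seed))
      net <- if (measure_at == "initial")
        geonet(positions, sim$net$edges) else sim$net
      mod <- network_properties(net, binnings = ref_props$binnings,
                                pair_budget = pair_budget)
      total_err(ref_props, mod)
    })
    dplyr::summarise_all(dplyr::bind_rows(errs), mean)
  }
  if (cells == "design") {
    design <- latin_square_design(k, p_v_range, p_c_range)
    rows <- purrr::map(seq_len(k), function(cell)
      dplyr::bind_cols(design[cell, ],
                       eval_cell(design$p_v[cell], design$p_c[cell])))
  } else {
    p_v_levels <- seq(p_v_range[1], p_v_range[2], length.out = k)
    p_c_levels <- exp(seq(log(p_c_range[1]), log(p_c_range[2]),
                          length.out = k))
    rows <- purrr::map(seq_len(k * k), function(cell) {
      i <- (cell - 1) %/% k + 1
      j <- (cell - 1) %% k + 1
      dplyr::bind_cols(
        tibble::tibble(row = i, col = j, p_v = p_v_levels[i],
                       p_c = p_c_levels[j]),
        eval_cell(p_v_levels[i], p_c_levels[j]))
    })
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("latin_scan", class(out)),
            best = out[which.min(out$err), ])
}

#' @method tidy latin_scan
#' @export
tidy.latin_scan <- function(x, ...) tibble::as_tibble(x)

#' @method glance latin_scan
#' @export
glance.latin_scan <- function(x, ...) {
  tibble::as_tibble(attr(x, "best"))
}

#' One-parameter sensitivity sweep
#'
#' Reruns the travel-and-friend model along one axis of the parameter space
#' (all other parameters fixed), recording for every swept value and
#' replica the scalar summaries and, optionally, all metric curves.
#'
#' @param param `"p_v"` or `"p_c"`.
#' @param values Swept parameter values.
#' @param base_params [model_params()] providing the fixed parameters.
#' @param grid A [population_grid].
#' @param positions Initial agent positions.
#' @param replicas Replicas per value.
#' @param seed Optional integer seed (local to this call).
#' @param keep_curves Attach the per-run metric curves as list-columns.
#' @return Tibble with one row per (value, replica): scalar summaries,
#'   `mean_overlap` (sample-weighted mean of the overlap curve), and
#'   curve list-columns when requested.
#' @export
sensitivity_sweep <- function(param = c("p_v", "p_c"), values, base_params,
                              grid, positions, replicas = 3, seed = NULL,
                              keep_curves = FALSE) {
  param <- match.arg(param)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 length(values) * replicas),
                      nrow = length(values))
  rows <- purrr::map(seq_along(values), function(vi) {
    pars <- base_params
    pars[[param]] <- values[vi]
    purrr::map(seq_len(replicas), function(rep) {
      sim <- suppressWarnings(
        run_tf(pars, grid, positions, seed = run_seeds[vi, rep]))
      s <- scalar_summary(sim$net)
      jf <- tryCatch(overlap_curve(sim$net), error = function(e) NULL)
      mean_jf <- if (is.null(jf) || sum(jf$n) == 0) NA_real_
                 else sum(jf$value * jf$n, na.rm = TRUE) / sum(jf$n)
      row <- tibble::tibble(
        value = values[vi], replicate = rep,
        global_reciprocity = s$global_reciprocity,
        global_clustering = s$global_clustering,
        mean_local_clustering = s$mean_local_clustering,
        n_connected = s$n_connected,
        mean_overlap = mean_jf)
      if (keep_curves) {
        row$p1 <- list(link_probability_curve(sim$net, pair_budget = 1e6))
        row$r <- list(tryCatch(reciprocity_curve(sim$net),
                               error = function(e) NULL))
        row$jf <- list(jf)
        row$cd <- list(clustering_curve(sim$net))
      }
      row
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "param") <- param
  out
}
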