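#' Logarithmic distance bins
#'
#' Distance-resolved statistics are accumulated on log-spaced bins. The
#' default binning used throughout is 30 log bins from 1 km to the 99.9th
#' percentile pair distance; curve constructors derive data-driven bins
#' when none are given. Distances below 1 m are clamped to 1 m before
#' binning so that co-located agents (e.g. right after a friend visit) do
#' not break log bins.
#'
#' @param d_min,d_max Strictly positive bin range, `d_max > d_min`.
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` strictly increasing bin edges.
#' @export
distance_bins <- function(d_min = 1, d_max = 1e4, n_bins = 30) {
  stopifnot(d_min > 0, d_max > d_min, n_bins >= 1)
  exp(seq(log(d_min), log(d_max), length.out = n_bins + 1))
}

D_FLOOR_KM <- 1e-3

# data-driven log bins covering all of d (used when no binning is supplied)
covering_log_bins <- function(d, n_bins = 30) {
  d <- pmax(d, D_FLOOR_KM)
  distance_bins(min(d) * 0.999, max(d) * 1.001 + 1e-9, n_bins)
}

bin_of <- function(d, edges) {
  d <- pmax(d, D_FLOOR_KM)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(edges) - 1] <- NA_integer_
  idx
}

new_metric_curve <- function(edges, value, n, metric) {
  nb <- length(edges) - 1
  structure(tibble::tibble(
    bin_low = edges[-(nb + 1)], bin_high = edges[-1],
    mid = sqrt(edges[-(nb + 1)] * edges[-1]),
    value = value, n = n),
    class = c("metric_curve", "tbl_df", "tbl", "data.frame"),
    metric = metric, bins = edges)
}

curve_bins <- function(curve) attr(curve, "bins")

#' Link probability versus distance
#'
#' The probability `P1(d)` that two users at distance `d` are linked: the
#' ratio of linked pairs (either directed edge counts) to all pairs in each
#' distance bin. All pairs are enumerated exactly for networks up to
#' `exact_threshold` nodes; larger networks are estimated by Monte-Carlo
#' over `pair_budget` uniformly sampled pairs.
#'
#' @param net A [geonet].
#' @param bins Bin edges (km); default 30 log bins from 1 km to the 99.9th
#'   percentile pair distance.
#' @param pair_budget Monte-Carlo pair sample size.
#' @param exact_threshold Node count up to which all pairs are enumerated.
#' @return A `metric_curve` tibble (`value` is `NA` in empty bins).
#' @export
link_probability_curve <- function(net, bins = NULL, pair_budget = 1e7,
                                   exact_threshold = 5000, n_bins = 30) {
  n <- n_nodes(net)
  if (n < 2) stop("network needs at least 2 nodes", call. = FALSE)
  ue <- union_edges(net)
  ekeys <- ue$u * (n + 1) + ue$v
  lat <- net$nodes$lat; lon <- net$nodes$lon
  if (is.null(bins)) {
    m <- min(100000L, n * (n - 1) / 2)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    ok <- i != j
    ds <- cpp_haversine(lat[i[ok]], lon[i[ok]], lat[j[ok]], lon[j[ok]])
    bins <- distance_bins(1, max(stats::quantile(ds, 0.999), 2), n_bins)
  }
  nb <- length(bins) - 1
  tot <- numeric(nb); lnk <- numeric(nb)
  if (n <= exact_threshold) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      b <- bin_of(cpp_haversine(rep(lat[i], length(j)), rep(lon[i], length(j)),
                                lat[j], lon[j]), bins)
      linked <- (i * (n + 1) + j) %in% ekeys
      ok <- !is.na(b)
      tot <- tot + tabulate(b[ok], nb)
      lnk <- lnk + tabulate(b[ok & linked], nb)
    }
  } else {
    left <- pair_budget
    while (left > 0) {
      m <- as.integer(min(left, 2e6))
      a <- sample.int(n, m, replace = TRUE)
      bnd <- sample.int(n, m, replace = TRUE)
      keep <- a != bnd
      u <- pmin(a[keep], bnd[keep]); v <- pmax(a[keep], bnd[keep])
      b <- bin_of(cpp_haversine(lat[u], lon[u], lat[v], lon[v]), bins)
      linked <- (u * (n + 1) + v) %in% ekeys
      ok <- !is.na(b)
      tot <- tot + tabulate(b[ok], nb)
      lnk <- lnk + tabulate(b[ok & linked], nb)
      left <- left - m
    }
  }
  val <- ifelse(tot > 0, lnk / tot, NA_real_)
  new_metric_curve(bins, val, tot, "P1")
}

#' Degree distribution
#'
#' Distribution of node degrees; by default degrees of the symmetrized
#' network (mutual directed edges count once). The probabilities sum to 1
#' over the `N` nodes, including isolated ones at `k = 0`.
#'
#' @param net A [geonet].
#' @param symmetrize Use undirected union degrees (default) or total
#'   in+out degree.
#' @return Tibble with `k`, `count`, `p`.
#' @export
degree_distribution <- function(net, symmetrize = TRUE) {
  n <- n_nodes(net)
  ei <- edge_index(net)
  if (symmetrize) {
    ue <- union_edges(net)
    deg <- tabulate(c(ue$u, ue$v), n)
  } else {
    deg <- tabulate(c(ei$src, ei$dst), n)
  }
  kmax <- if (n) max(deg) else 0L
  cnt <- tabulate(deg + 1L, kmax + 1L)
  tibble::tibble(k = 0:kmax, count = cnt, p = cnt / n)
}

#' Reciprocity versus distance
#'
#' Over the directed edges falling in each distance bin, the fraction whose
#' reverse edge also exists.
#'
#' @param net A [geonet].
#' @param bins Bin edges (km); default data-driven log bins covering all
#'   edge distances.
#' @return A `metric_curve` tibble.
#' @export
reciprocity_curve <- function(net, bins = NULL, n_bins = 30) {
  et <- tidy.geonet(net)
  if (is.null(bins)) {
    if (!nrow(et)) stop("network has no edges", call. = FALSE)
    bins <- covering_log_bins(et$distance_km, n_bins)
  }
  nb <- length(bins) - 1
  b <- bin_of(et$distance_km, bins)
  ok <- !is.na(b)
  tot <- tabulate(b[ok], nb)
  rec <- tabulate(b[ok & et$reciprocated], nb)
  new_metric_curve(bins, ifelse(tot > 0, rec / tot, NA_real_), tot, "R")
}

#' Social overlap of two connected users
#'
#' Modified Jaccard index of the symmetrized neighbour sets of two
#' connected users `i` and `j`:
#' `|G_i intersect G_j| / |(G_i union G_j) \\ {i, j}|`.
#' It is 1 when the two users share all their friends and 0 when they share
#' none; it is undefined (`NA`) when the denominator is zero (the pair has
#' no neighbours besides each other).
#'
#' @param net A [geonet].
#' @param i,j Node ids; must be connected in the symmetrized network.
#' @return A value in \[0, 1\] or `NA`.
#' @export
social_overlap <- function(net, i, j) {
  pi_ <- match(i, net$nodes$id); pj <- match(j, net$nodes$id)
  stopifnot(!is.na(pi_), !is.na(pj))
  adj <- adj_list(net, "union")
  if (!(pj %in% adj[[pi_]]))
    stop("i and j are not connected", call. = FALSE)
  overlap_value(adj[[pi_]], adj[[pj]], pi_, pj)
}

overlap_value <- function(gi, gj, pi_, pj) {
  inter <- length(intersect(gi, gj))
  denom <- length(setdiff(union(gi, gj), c(pi_, pj)))
  if (denom == 0) NA_real_ else inter / denom
}

#' Average social overlap versus distance
#'
#' Mean of [social_overlap()] over all connected (symmetrized) pairs in
#' each distance bin; pairs with an undefined overlap (zero denominator)
#' are excluded from both numerator and sample counts.
#'
#' @inheritParams reciprocity_curve
#' @return A `metric_curve` tibble.
#' @export
overlap_curve <- function(net, bins = NULL, n_bins = 30) {
  ue <- union_edges(net)
  if (!length(ue$u)) stop("network has no edges", call. = FALSE)
  adj <- adj_list(net, "union")
  ov <- vapply(seq_along(ue$u), function(e)
    overlap_value(adj[[ue$u[e]]], adj[[ue$v[e]]], ue$u[e], ue$v[e]),
    numeric(1))
  d <- node_distance(net, ue$u, ue$v)
  if (is.null(bins)) bins <- covering_log_bins(d, n_bins)
  nb <- length(bins) - 1
  b <- bin_of(d, bins)
  ok <- !is.na(b) & !is.na(ov)
  n_bin <- tabulate(b[ok], nb)
  sum_bin <- vapply(seq_len(nb), function(k) sum(ov[ok][b[ok] == k]),
                    numeric(1))
  new_metric_curve(bins, ifelse(n_bin > 0, sum_bin / n_bin, NA_real_),
                   n_bin, "Jf")
}

#' Triad census with centre-leaf distances
#'
#' Enumerates every triad of the symmetrized network (a centre `j`
#' connected to an unordered pair of leaves `i`, `k`), with the two
#' centre-leaf distances and whether the triad is closed (the leaves are
#' also connected). A triangle contributes three closed triads, one per
#' centre.
#'
#' @param net A [geonet].
#' @return Tibble `center`, `leaf1`, `leaf2` (node ids), `d1`, `d2` (km),
#'   `closed`.
#' @export
triad_census <- function(net) {
  adj <- adj_list(net, "union")
  n <- n_nodes(net)
  ue <- union_edges(net)
  ekeys <- ue$u * (n + 1) + ue$v
  cen <- list(); l1 <- list(); l2 <- list(); dd1 <- list(); dd2 <- list()
  m <- 0L
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    k <- length(nb)
    if (k < 2) next
    pr <- utils::combn(k, 2)
    a <- nb[pr[1, ]]; b <- nb[pr[2, ]]
    dj <- node_distance(net, rep(j, k), nb)
    m <- m + 1L
    cen[[m]] <- rep(j, ncol(pr)); l1[[m]] <- a; l2[[m]] <- b
    dd1[[m]] <- dj[pr[1, ]]; dd2[[m]] <- dj[pr[2, ]]
  }
  if (m == 0L)
    return(tibble::tibble(center = net$nodes$id[0], leaf1 = net$nodes$id[0],
                          leaf2 = net$nodes$id[0], d1 = numeric(),
                          d2 = numeric(), closed = logical()))
  a <- unlist(l1); b <- unlist(l2); cenv <- unlist(cen)
  closed <- (pmin(a, b) * (n + 1) + pmax(a, b)) %in% ekeys
  tibble::tibble(center = net$nodes$id[cenv],
                 leaf1 = net$nodes$id[a], leaf2 = net$nodes$id[b],
                 d1 = unlist(dd1), d2 = unlist(dd2), closed = closed)
}

#' Clustering coefficient versus triad distance
#'
#' The probability `C(d)` of closing a triangle given the triad distance
#' `d`: closed triads over all triads per distance bin, with the triad
#' distance the mean (default) or max of the two centre-leaf distances. The
#' sample-weighted average of the curve equals the global clustering
#' coefficient `N_closed / N_triads`, exposed as attribute `global_C`.
#'
#' @inheritParams reciprocity_curve
#' @param triad_distance `"mean"` (default) or `"max"` of the two
#'   centre-leaf distances.
#' @return A `metric_curve` tibble with attribute `global_C`.
#' @export
clustering_curve <- function(net, bins = NULL,
                             triad_distance = c("mean", "max"),
                             n_bins = 30) {
  triad_distance <- match.arg(triad_distance)
  tc <- triad_census(net)
  if (!nrow(tc)) {
    if (is.null(bins)) bins <- distance_bins()
    return(structure(
      new_metric_curve(bins, rep(NA_real_, length(bins) - 1),
                       rep(0, length(bins) - 1), "C"),
      global_C = NA_real_))
  }
  d <- if (triad_distance == "mean") (tc$d1 + tc$d2) / 2 else pmax(tc$d1, tc$d2)
  if (is.null(bins)) bins <- covering_log_bins(d, n_bins)
  nb <- length(bins) - 1
  b <- bin_of(d, bins)
  ok <- !is.na(b)
  tot <- tabulate(b[ok], nb)
  clo <- tabulate(b[ok & tc$closed], nb)
  structure(new_metric_curve(bins, ifelse(tot > 0, clo / tot, NA_real_),
                             tot, "C"),
            global_C = sum(tc$closed) / nrow(tc))
}

#' Triangle census with geographic edge lengths and disparity
#'
#' Enumerates each triangle of the symmetrized network once and computes
#' its three pairwise node distances and the disparity
#' `D = (d_max - d_min) / d_max`, a \[0, 1\] shape statistic that is 0 for
#' equilateral triangles and approaches 1 when one side is much shorter
#' than the other two (two users co-located, the third distant). Distances
#' are clamped below at 1 m to keep `D` defined for co-located nodes.
#'
#' @param net A [geonet].
#' @return Tibble `n1`, `n2`, `n3` (node ids), `d1`, `d2`, `d3` (km), `D`.
#' @export
triangle_census <- function(net) {
  n <- n_nodes(net)
  adj <- adj_list(net, "union")
  ue <- union_edges(net)
  t1 <- list(); t2 <- list(); t3 <- list(); m <- 0L
  for (e in seq_along(ue$u)) {
    u <- ue$u[e]; v <- ue$v[e]
    w <- intersect(adj[[u]], adj[[v]])
    w <- w[w > v]   # u < v < w: each triangle once
    if (length(w)) {
      m <- m + 1L
      t1[[m]] <- rep(u, length(w)); t2[[m]] <- rep(v, length(w)); t3[[m]] <- w
    }
  }
  if (m == 0L)
    return(tibble::tibble(n1 = net$nodes$id[0], n2 = net$nodes$id[0],
                          n3 = net$nodes$id[0], d1 = numeric(),
                          d2 = numeric(), d3 = numeric(), D = numeric()))
  a <- unlist(t1); b <- unlist(t2); cc <- unlist(t3)
  d1 <- pmax(node_distance(net, a, b), D_FLOOR_KM)
  d2 <- pmax(node_distance(net, a, cc), D_FLOOR_KM)
  d3 <- pmax(node_distance(net, b, cc), D_FLOOR_KM)
  dmax <- pmax(d1, d2, d3); dmin <- pmin(d1, d2, d3)
  tibble::tibble(n1 = net$nodes$id[a], n2 = net$nodes$id[b],
                 n3 = net$nodes$id[cc],
                 d1 = d1, d2 = d2, d3 = d3, D = (dmax - dmin) / dmax)
}

#' Distribution of triangle disparity
#'
#' Normalized histogram of the disparity `D` over all triangles of the
#' symmetrized network (see [triangle_census()]).
#'
#' @param net A [geonet].
#' @param n_bins Number of equal-width bins on \[0, 1\].
#' @return Tibble `bin_low`, `bin_high`, `value` (fraction of triangles,
#'   summing to 1 when triangles exist), `n`; attribute `n_triangles`.
#' @export
disparity_distribution <- function(net, n_bins = 20) {
  tc <- triangle_census(net)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(tc$D, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  cnt <- tabulate(idx, n_bins)
  total <- nrow(tc)
  structure(tibble::tibble(
    bin_low = edges[-(n_bins + 1)], bin_high = edges[-1],
    value = if (total > 0) cnt / total else rep(NA_real_, n_bins),
    n = cnt),
    n_triangles = total)
}

#' Scalar geo-social summary
#'
#' Computes the scalar properties used in calibration: `n_connected` (nodes
#' with symmetrized degree >= 1, i.e. nodes in connected components),
#' `mean_local_clustering` (undirected local clustering averaged over the
#' connected nodes; nodes of degree 1 contribute 0), `global_clustering`
#' (closed triads over triads) and `global_reciprocity` (fraction of
#' directed edges whose reverse exists; 0 for an edgeless network).
#'
#' @param net A [geonet].
#' @return Named list of the four scalars.
#' @export
scalar_summary <- function(net) {
  n <- n_nodes(net)
  ue <- union_edges(net)
  deg <- tabulate(c(ue$u, ue$v), n)
  n_conn <- sum(deg >= 1)
  tc <- triad_census(net)
  if (nrow(tc)) {
    cpos <- match(tc$center, net$nodes$id)
    per <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(center = cpos, closed = tc$closed),
                      .data$center),
      lc = mean(.data$closed), .groups = "drop")
    lc_all <- numeric(n)
    lc_all[per$center] <- per$lc
    mean_lc <- if (n_conn > 0) sum(lc_all[deg >= 1]) / n_conn else 0
    glob_c <- sum(tc$closed) / nrow(tc)
  } else {
    mean_lc <- 0
    glob_c <- 0
  }
  ne <- n_edges(net)
  glob_r <- if (ne > 0) {
    et <- tidy.geonet(net)
    mean(et$reciprocated)
  } else 0
  list(n_connected = n_conn, mean_local_clustering = mean_lc,
       global_clustering = glob_c, global_reciprocity = glob_r)
}

#' Fit a log-log slope to a link-probability curve
#'
#' Weighted least squares of `log(value)` on `log(mid)` over the defined,
#' positive bins (optionally restricted to a distance window and to bins
#' holding at least `min_n` samples), recovering the decay exponent of a
#' power-law link kernel.
#'
#' @param curve A `metric_curve` (e.g. from [link_probability_curve()]).
#' @param d_range Optional `c(lo, hi)` window in km.
#' @param min_n Minimum per-bin sample count.
#' @return List with `slope`, `intercept`, `n_bins`.
#' @export
fit_p1_slope <- function(curve, d_range = NULL, min_n = 10) {
  keep <- !is.na(curve$value) & curve$value > 0 & curve$n >= min_n
  if (!is.null(d_range))
    keep <- keep & curve$mid >= d_range[1] & curve$mid <= d_range[2]
  if (sum(keep) < 3) stop("too few defined bins for a slope fit",
                          call. = FALSE)
  fit <- stats::lm(log(value) ~ log(mid), data = curve[keep, ],
                   weights = curve$n[keep])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_bins = sum(keep))
}
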