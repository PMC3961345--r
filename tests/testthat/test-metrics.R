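test_that("link probability matches hand enumeration on a line", {
  # 3 equatorial nodes at 0, 1, 2 degrees; single edge 1 -> 2
  nodes <- tibble::tibble(id = 1:3, lat = 0, lon = c(0, 1, 2))
  net <- net_from(nodes, 1L, 2L)
  deg1 <- 2 * pi * 6371 / 360
  bins <- c(0.9, 1.1, 1.9, 2.1) * deg1
  p1 <- link_probability_curve(net, bins = bins)
  expect_equal(p1$value[1], 0.5)   # two ~111 km pairs, one linked
  expect_true(is.na(p1$value[2]))
  expect_equal(p1$value[3], 0)     # the 222 km pair is unlinked
  expect_equal(p1$n, c(2, 0, 1))

  # complete graph: every defined bin is 1
  ed <- expand.grid(src = 1:3, dst = 1:3)
  ed <- ed[ed$src != ed$dst, ]
  full <- geonet(nodes, ed)
  p1f <- link_probability_curve(full, bins = bins)
  expect_true(all(p1f$value[!is.na(p1f$value)] == 1))
})

test_that("Monte-Carlo link probability tracks the exact curve", {
  net <- random_geonet(1000, 6000, seed = 21)
  bins <- distance_bins(5, 600, 12)
  exact <- link_probability_curve(net, bins = bins)
  set.seed(22)
  mc <- link_probability_curve(net, bins = bins, exact_threshold = 100,
                               pair_budget = 1e7)
  ok <- !is.na(exact$value) & !is.na(mc$value)
  expect_gt(sum(ok), 6)
  expect_lt(max(abs(exact$value[ok] - mc$value[ok])), 0.01)
})

test_that("degree distributions symmetrize mutual edges", {
  nodes <- line_nodes(c(0, 10, 20))
  net <- net_from(nodes, c(1L, 2L, 1L), c(2L, 1L, 3L))
  dd <- degree_distribution(net)
  expect_equal(dd$count[dd$k == 2], 1)  # node 1
  expect_equal(dd$count[dd$k == 1], 2)  # nodes 2, 3
  expect_equal(sum(dd$count), 3)
  expect_equal(sum(dd$p), 1)

  empty <- geonet(nodes)
  de <- degree_distribution(empty)
  expect_equal(de$p[de$k == 0], 1)

  star <- net_from(line_nodes(seq(0, 50, 10)), rep(1L, 5), 2:6)
  ds <- degree_distribution(star)
  expect_equal(max(ds$k), 5)
})

test_that("reciprocity curve recovers planted per-bin rates", {
  fx <- make_fixture("planted_reciprocity", seed = 1)
  rc <- reciprocity_curve(fx$net)
  near_bin <- which(rc$bin_low <= 5 & rc$bin_high > 5)
  far_bin <- which(rc$bin_low <= 500 & rc$bin_high > 500)
  # directed-edge reciprocity: with m pairs of which r reciprocated, the
  # fraction of directed edges with a reverse is 2r/(m + r)
  expect_equal(rc$value[near_bin], 2 * 40 / (50 + 40))
  expect_equal(rc$value[far_bin], 2 * 10 / (50 + 10))

  pair <- net_from(line_nodes(c(0, 5)), c(1L, 2L), c(2L, 1L))
  expect_equal(reciprocity_curve(pair)$value |> na.omit() |> as.numeric(), 1)
  one <- net_from(line_nodes(c(0, 5)), 1L, 2L)
  expect_equal(reciprocity_curve(one)$value |> na.omit() |> as.numeric(), 0)
})

test_that("social overlap follows the modified Jaccard contract", {
  nodes <- line_nodes(seq(0, 40, 10))
  # G1 = {2, 3}, G2 = {1, 3}: share all friends -> 1
  net <- net_from(nodes, c(1L, 1L, 2L, 2L), c(2L, 3L, 1L, 3L))
  expect_equal(social_overlap(net, 1, 2), 1)

  # no common neighbours but one extra neighbour -> 0
  net2 <- net_from(nodes, c(1L, 1L), c(2L, 3L))
  expect_equal(social_overlap(net2, 1, 2), 0)

  # G1 = {2, 3, 4}, G2 = {1, 3}: 1 common of 2 eligible -> 1/2
  net3 <- net_from(nodes, c(1L, 1L, 1L, 2L), c(2L, 3L, 4L, 3L))
  expect_equal(social_overlap(net3, 1, 2), 1 / 2)

  # mutually exclusive dyad: undefined
  net4 <- net_from(nodes, 1L, 2L)
  expect_true(is.na(social_overlap(net4, 1, 2)))
  expect_error(social_overlap(net4, 1, 3), "not connected")
})

test_that("overlap curve averages per distance bin and K4 gives 1", {
  k4 <- expand.grid(src = 1:4, dst = 1:4)
  k4 <- k4[k4$src != k4$dst, ]
  nodes <- line_nodes(c(0, 1, 2, 3))
  net <- geonet(nodes, k4)
  oc <- overlap_curve(net)
  expect_true(all(oc$value[oc$n > 0] == 1))
  expect_equal(sum(oc$n), 6)
})

test_that("clustering curve closes the triad census identities", {
  nodes <- line_nodes(c(0, 7, 14))
  tri <- net_from(nodes, c(1L, 2L, 3L), c(2L, 3L, 1L))
  cc <- clustering_curve(tri)
  expect_equal(attr(cc, "global_C"), 1)
  expect_true(all(cc$value[cc$n > 0] == 1))
  expect_equal(sum(cc$n), 3)  # one triangle = three closed triads

  path <- net_from(nodes, c(1L, 2L), c(2L, 3L))
  cp <- clustering_curve(path)
  expect_equal(attr(cp, "global_C"), 0)

  # 2 triangles + 4 open triads at separated scales
  fx <- make_fixture("planted_triangles",
                     params = list(n_triangles = 2, n_open = 4), seed = 2)
  cf <- clustering_curve(fx$net)
  expect_equal(attr(cf, "global_C"), 6 / 10)
  short <- cf$mid < 100
  expect_true(all(cf$value[short & cf$n > 0] == 1))
  expect_true(all(cf$value[!short & cf$n > 0] == 0))
  # weighted bin average equals the global coefficient exactly
  expect_equal(sum(cf$value * cf$n, na.rm = TRUE) / sum(cf$n),
               attr(cf, "global_C"))
})

test_that("disparity captures triangle shape", {
  # equilateral-ish triangle: D near 0
  fx <- make_fixture("planted_triangles",
                     params = list(n_triangles = 1, n_open = 1), seed = 3)
  tc <- triangle_census(fx$net)
  expect_equal(nrow(tc), 1)
  expect_lt(tc$D, 0.1)

  # (100, 100, 200) km: three collinear equatorial nodes give side lengths
  # 100, 100 and 200 km, so D = 0.5 under (d_max - d_min)/d_max
  km <- 1 / (pi * 6371 / 180)
  nodes <- tibble::tibble(id = 1:3, lat = 0, lon = c(0, 100 * km, 200 * km))
  net <- net_from(nodes, c(1L, 2L, 3L), c(2L, 3L, 1L))
  tc2 <- triangle_census(net)
  expect_equal(tc2$D, 0.5, tolerance = 1e-4)

  # two co-located nodes plus a distant one: D -> 1
  nodes3 <- tibble::tibble(id = 1:3, lat = 0, lon = c(0, 0.001, 5))
  net3 <- net_from(nodes3, c(1L, 2L, 3L), c(2L, 3L, 1L))
  expect_gt(triangle_census(net3)$D, 0.99)

  pd <- disparity_distribution(net3, n_bins = 10)
  expect_equal(sum(pd$value), 1)
  expect_equal(pd$value[10], 1)
})

test_that("scalar summaries count connected nodes and reciprocity", {
  nodes <- line_nodes(seq(0, 90, 10))
  net <- net_from(nodes, c(1L, 2L, 3L, 4L, 5L, 6L),
                  c(2L, 3L, 4L, 5L, 6L, 1L))
  s <- scalar_summary(net)
  expect_equal(s$n_connected, 6)

  tri_iso <- net_from(line_nodes(c(0, 7, 14, 50)),
                      c(1L, 2L, 3L), c(2L, 3L, 1L))
  s2 <- scalar_summary(tri_iso)
  expect_equal(s2$mean_local_clustering, 1)
  expect_equal(s2$n_connected, 3)

  abc <- net_from(line_nodes(c(0, 5, 10)), c(1L, 2L, 1L), c(2L, 1L, 3L))
  expect_equal(scalar_summary(abc)$global_reciprocity, 2 / 3)
})

test_that("every metric matches brute-force enumeration on small graphs", {
  nets <- list(
    random_geonet(25, 60, seed = 31),
    random_geonet(40, 200, seed = 32),
    random_geonet(60, 350, seed = 33, extent_km = 1500),
    make_fixture("planted_triangles", seed = 4)$net,
    make_fixture("planted_reciprocity", params = list(n_pairs = 10),
                 seed = 5)$net)
  for (net in nets) {
    n <- nrow(net$nodes)
    bins <- distance_bins(0.5, 4000, 12)

    p1 <- link_probability_curve(net, bins = bins)
    o_p1 <- oracle_p1(net, bins)
    expect_equal(p1$value, ifelse(o_p1$n > 0, o_p1$value, NA), tolerance = 1e-12)
    expect_equal(p1$n, o_p1$n)

    dd <- degree_distribution(net)
    o_deg <- oracle_degrees(net)
    expect_equal(dd$count, tabulate(o_deg + 1, max(o_deg) + 1))
    expect_equal(sum(dd$p), 1)

    s <- scalar_summary(net)
    expect_equal(s$global_reciprocity, oracle_reciprocity_global(net))
    expect_equal(s$n_connected, sum(o_deg >= 1))
    o_lc <- oracle_local_clustering(net)
    expect_equal(s$mean_local_clustering,
                 sum(o_lc[o_deg >= 1]) / sum(o_deg >= 1))

    o_tr <- oracle_triads(net)
    cc <- clustering_curve(net)
    if (is.null(o_tr)) {
      expect_true(is.na(attr(cc, "global_C")))
    } else {
      expect_equal(attr(cc, "global_C"), mean(o_tr$closed))
      expect_equal(sum(cc$n), nrow(o_tr))
      expect_equal(sum(cc$value * cc$n, na.rm = TRUE), sum(o_tr$closed))
      # per-bin equality on the package's own binning
      d_o <- pmax((o_tr$d1 + o_tr$d2) / 2, 1e-3)
      b_o <- findInterval(d_o, curve_bins(cc), rightmost.closed = TRUE)
      for (bb in unique(b_o)) {
        expect_equal(cc$value[bb], mean(o_tr$closed[b_o == bb]))
      }
    }

    o_tg <- oracle_triangles(net)
    tg <- triangle_census(net)
    expect_equal(nrow(tg), if (is.null(o_tg)) 0 else nrow(o_tg))
    if (!is.null(o_tg)) {
      expect_equal(sort(tg$D), sort(o_tg$D), tolerance = 1e-12)
      expect_equal(3 * nrow(tg), sum(o_tr$closed))  # triangle = 3 closed triads
    }

    # overlap oracle on every connected pair
    ue <- travelfriend:::union_edges(net)
    if (length(ue$u)) {
      oc <- overlap_curve(net, bins = bins)
      ov <- sapply(seq_along(ue$u), function(e)
        oracle_overlap(net, ue$u[e], ue$v[e]))
      d <- sapply(seq_along(ue$u), function(e)
        oracle_dist(net$nodes, ue$u[e], ue$v[e]))
      b <- findInterval(pmax(d, 1e-3), bins, rightmost.closed = TRUE)
      for (bb in unique(b[!is.na(ov)])) {
        if (bb < 1 || bb > 12) next
        expect_equal(oc$value[bb], mean(ov[b == bb], na.rm = TRUE))
      }
    }
  }
})

test_that("curve values are probabilities and empty bins are undefined", {
  net <- random_geonet(50, 220, seed = 41)
  for (curve in list(link_probability_curve(net),
                     reciprocity_curve(net),
                     overlap_curve(net),
                     clustering_curve(net))) {
    v <- curve$value[!is.na(curve$value)]
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(is.na(curve$value[curve$n == 0])))
  }
})

test_that("global clustering and reciprocity agree with igraph", {
  skip_if_not_installed("igraph")
  net <- random_geonet(60, 300, seed = 42)
  g <- igraph::graph_from_edgelist(cbind(net$edges$src, net$edges$dst))
  s <- scalar_summary(net)
  expect_equal(s$global_reciprocity, igraph::reciprocity(g))
  gu <- igraph::as_undirected(g, mode = "collapse")
  expect_equal(attr(clustering_curve(net), "global_C"),
               igraph::transitivity(gu, type = "global"))
  lc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  deg <- igraph::degree(gu)
  expect_equal(s$mean_local_clustering, mean(lc[deg >= 1]))
})

test_that("spatial-model networks regress back to their planted slope", {
  fx <- make_fixture("planted_p1_slope",
                     params = list(n = 1200, slope = 1, L_target = 5000),
                     seed = 6)
  fit <- fit_p1_slope(link_probability_curve(fx$net), min_n = 100)
  expect_lt(abs(fit$slope - (-1)), 0.1)
})
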