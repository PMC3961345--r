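test_that("travel stage visits friends or jumps", {
  w <- small_world(n = 20, seed = 1)
  pos <- w$positions
  edges <- tibble::tibble(src = 1L, dst = 2L)

  # forced visit: p_v = 1 with exactly one friend
  pars <- model_params(p_v = 1, jump = jump_spec(d_max = 500))
  set.seed(1)
  mv <- travel_stage(1L, pos, edges, pars, w$grid)
  expect_equal(mv$lat, pos$lat[2])
  expect_equal(mv$lon, pos$lon[2])
  expect_true(mv$visited)

  # no friends: the jump is taken even at p_v = 1
  set.seed(2)
  mv2 <- travel_stage(3L, pos, edges, pars, w$grid)
  expect_false(mv2$visited)
  expect_false(mv2$lat == pos$lat[3] && mv2$lon == pos$lon[3])

  # p_v = 0: displacement lengths follow the jump law (KS on 400 moves)
  pars0 <- model_params(p_v = 0, jump = jump_spec("uniform", d_min = 50,
                                                  d_max = 60))
  set.seed(3)
  d <- replicate(400, {
    mv <- travel_stage(1L, pos, edges, pars0, w$grid)
    great_circle_distance(pos$lat[1], pos$lon[1], mv$lat, mv$lon)
  })
  # jitter inside the target cell widens the annulus tolerance slightly
  expect_true(all(d > 25 & d < 90))
  expect_gt(suppressWarnings(
    ks.test(d[d >= 50 & d <= 60], "punif", 50, 60))$p.value, 0.001)
})

test_that("friendship stage gates box links and random links", {
  # two agents in one 5 km box
  pos <- line_nodes(c(0, 0.5, 400))
  edges <- tibble::tibble(src = integer(), dst = integer())

  pars <- model_params(p = 1, p_c = 0)
  set.seed(4)
  new <- friendship_stage(1L, pos, edges, pars)
  expect_equal(nrow(new), 1)
  expect_equal(new$dst, 2L)

  # two box mates, no prior edges: exactly 2 directed edges
  pos2 <- line_nodes(c(0, 0.5, 1))
  set.seed(5)
  new2 <- friendship_stage(1L, pos2, edges, pars)
  expect_equal(nrow(new2), 2)
  expect_setequal(new2$dst, c(2L, 3L))

  # p = 0, p_c = 0: never creates anything
  pars0 <- model_params(p = 0, p_c = 0)
  set.seed(6)
  expect_equal(nrow(friendship_stage(1L, pos2, edges, pars0)), 0)

  # existing edges are not recreated
  set.seed(7)
  new3 <- friendship_stage(1L, pos2, tibble::tibble(src = 1L, dst = 2L),
                           pars)
  expect_equal(new3$dst, 3L)

  # random link: goes anywhere, never to self, avoids existing edges
  parsc <- model_params(p = 0, p_c = 1)
  set.seed(8)
  got <- replicate(200, friendship_stage(
    1L, pos2, tibble::tibble(src = 1L, dst = 2L), parsc)$dst)
  expect_setequal(unique(got), 3L)
})

test_that("neighborhood linking fires at the gate probability", {
  pos <- line_nodes(c(0, 0.5))
  edges <- tibble::tibble(src = integer(), dst = integer())
  pars <- model_params(p = 0.1, p_c = 0)
  set.seed(9)
  hits <- sum(replicate(2e4, nrow(friendship_stage(1L, pos, edges, pars))))
  expect_lt(abs(hits / 2e4 - 0.1), 3 * sqrt(0.1 * 0.9 / 2e4))
})

test_that("runs stop exactly at the link target and are reproducible", {
  w <- small_world(n = 100, seed = 2)
  pars <- model_params(p_v = 0.3, p_c = 0.05, L_target = 300,
                       jump = jump_spec(d_max = 2000))
  s1 <- run_tf(pars, w$grid, w$positions, seed = 11)
  expect_equal(n_edges(s1$net), 300)
  expect_false(s1$hit_max_steps)
  expect_true(all(diff(s1$series$links) >= 0))

  s2 <- run_tf(pars, w$grid, w$positions, seed = 11)
  expect_identical(s1$net$edges, s2$net$edges)
  expect_identical(s1$net$nodes, s2$net$nodes)

  # max_sweeps cap flags a partial result
  slow <- model_params(p_v = 0, p = 0, p_c = 0.001, L_target = 5000,
                       max_sweeps = 3, jump = jump_spec(d_max = 2000))
  expect_warning(s3 <- run_tf(slow, w$grid, w$positions, seed = 12),
                 "max_sweeps")
  expect_true(s3$hit_max_steps)
  expect_lt(n_edges(s3$net), 5000)

  expect_error(run_tf(pars, w$grid, w$positions[1, ]), "at least 2")
})

test_that("networks have no self-loops or duplicate edges", {
  w <- small_world(n = 80, seed = 3)
  pars <- model_params(p_v = 0.4, p_c = 0.1, L_target = 400,
                       jump = jump_spec(d_max = 2000))
  for (s in 1:3) {
    net <- run_tf(pars, w$grid, w$positions, seed = s)$net
    expect_true(all(net$edges$src != net$edges$dst))
    expect_false(anyDuplicated(paste(net$edges$src, net$edges$dst)) > 0)
  }
})

test_that("purely local linking stays within the encounter box", {
  w <- small_world(n = 150, seed = 4)
  pars <- model_params(p_v = 0.3, p_c = 0, p = 0.3, delta_km = 5,
                       L_target = 200, jump = jump_spec(d_max = 2000))
  sim <- run_tf(pars, w$grid, w$positions, seed = 13, log_creation = TRUE)
  expect_true(all(sim$creation_log$mechanism == "neighborhood"))
  # box membership bounds the creation-time separation by the box diagonal
  expect_true(all(sim$creation_log$distance_km <= 5 * sqrt(2) / 2 + 0.02))
})

test_that("visited locations grow linearly when all moves are jumps", {
  w <- small_world(n = 100, seed = 5)
  pars <- model_params(p_v = 0, p_c = 0.02, L_target = 400,
                       jump = jump_spec(d_max = 2000))
  sim <- run_tf(pars, w$grid, w$positions, seed = 14)
  gr <- diff(sim$series$unique_locations)
  gr <- gr[-length(gr)]  # final sweep is truncated by the stop rule
  expect_true(all(gr / 100 > 0.9))  # per-activation slope, N = 100
})

test_that("friend visits raise reciprocity", {
  w <- small_world(n = 300, seed = 6)
  base <- model_params(p_c = 0.05, L_target = 900,
                       jump = jump_spec(d_max = 2000))
  r_lo <- r_hi <- numeric(6)
  for (s in 1:6) {
    lo <- base; lo$p_v <- 0
    hi <- base; hi$p_v <- 0.6
    r_lo[s] <- scalar_summary(
      run_tf(lo, w$grid, w$positions, seed = 20 + s)$net)$global_reciprocity
    r_hi[s] <- scalar_summary(
      run_tf(hi, w$grid, w$positions, seed = 40 + s)$net)$global_reciprocity
  }
  expect_gt(mean(r_hi), mean(r_lo))
})

test_that("jump-law variants substitute cleanly", {
  w <- small_world(n = 100, seed = 7)
  pars <- model_params(p_v = 0, p_c = 0.05, L_target = 200)
  uni <- run_tf_variant(pars, jump_spec("uniform", d_min = 5, d_max = 30),
                        w$grid, w$positions, seed = 15)
  expect_equal(n_edges(uni$net), 200)
  nrm <- run_tf_variant(pars, jump_spec("normal", mean = 20, sd = 1e-6,
                                        d_min = 1), w$grid, w$positions,
                        seed = 16)
  expect_equal(n_edges(nrm$net), 200)
})
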