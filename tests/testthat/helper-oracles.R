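# Brute-force oracles: plain-loop reimplementations of every statistic,
# independent of the package's vectorised/incremental code paths.

oracle_dist <- function(nodes, i, j) {
  # haversine, R = 6371 km, scalar
  to_rad <- pi / 180
  p1 <- nodes$lat[i] * to_rad; p2 <- nodes$lat[j] * to_rad
  dphi <- (nodes$lat[j] - nodes$lat[i]) * to_rad
  dlam <- (nodes$lon[j] - nodes$lon[i]) * to_rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(min(max(a, 0), 1)))
}

oracle_adj <- function(net) {
  n <- nrow(net$nodes)
  has <- matrix(FALSE, n, n)
  si <- match(net$edges$src, net$nodes$id)
  di <- match(net$edges$dst, net$nodes$id)
  for (e in seq_along(si)) has[si[e], di[e]] <- TRUE
  has
}

oracle_union <- function(net) {
  has <- oracle_adj(net)
  has | t(has)
}

oracle_p1 <- function(net, bins) {
  u <- oracle_union(net)
  n <- nrow(net$nodes)
  nb <- length(bins) - 1
  tot <- numeric(nb); lnk <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- max(oracle_dist(net$nodes, i, j), 1e-3)
    b <- NA
    for (k in seq_len(nb))
      if (d >= bins[k] && (d < bins[k + 1] || (k == nb && d <= bins[k + 1])))
        { b <- k; break }
    if (is.na(b)) next
    tot[b] <- tot[b] + 1
    if (u[i, j]) lnk[b] <- lnk[b] + 1
  }
  list(value = ifelse(tot > 0, lnk / tot, NA), n = tot)
}

oracle_degrees <- function(net) {
  u <- oracle_union(net)
  rowSums(u)
}

oracle_reciprocity_global <- function(net) {
  has <- oracle_adj(net)
  si <- match(net$edges$src, net$nodes$id)
  di <- match(net$edges$dst, net$nodes$id)
  if (!length(si)) return(0)
  mean(sapply(seq_along(si), function(e) has[di[e], si[e]]))
}

oracle_triads <- function(net) {
  # every (center, unordered leaf pair); closed if leaves linked
  u <- oracle_union(net)
  n <- nrow(net$nodes)
  out <- NULL
  for (j in seq_len(n)) {
    nb <- which(u[j, ])
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      i <- nb[a]; k <- nb[b]
      out <- rbind(out, data.frame(
        center = j, i = i, k = k,
        d1 = oracle_dist(net$nodes, j, i),
        d2 = oracle_dist(net$nodes, j, k),
        closed = u[i, k]))
    }
  }
  out
}

oracle_local_clustering <- function(net) {
  u <- oracle_union(net)
  n <- nrow(net$nodes)
  sapply(seq_len(n), function(j) {
    nb <- which(u[j, ])
    if (length(nb) < 2) return(0)
    cl <- 0; tot <- 0
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      tot <- tot + 1
      if (u[nb[a], nb[b]]) cl <- cl + 1
    }
    cl / tot
  })
}

oracle_overlap <- function(net, i, j) {
  u <- oracle_union(net)
  gi <- which(u[i, ]); gj <- which(u[j, ])
  denom <- setdiff(union(gi, gj), c(i, j))
  if (!length(denom)) return(NA_real_)
  length(intersect(gi, gj)) / length(denom)
}

oracle_triangles <- function(net) {
  u <- oracle_union(net)
  n <- nrow(net$nodes)
  out <- NULL
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (u[i, j] && u[i, k] && u[j, k]) {
      d <- pmax(c(oracle_dist(net$nodes, i, j), oracle_dist(net$nodes, i, k),
                  oracle_dist(net$nodes, j, k)), 1e-3)
      out <- rbind(out, data.frame(i = i, j = j, k = k,
                                   D = (max(d) - min(d)) / max(d)))
    }
  out
}
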