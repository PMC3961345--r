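#' Directed geo-social networks
#'
#' A `geonet` couples a node table (agents with coordinates) and a directed
#' edge table. Self-loops and duplicate directed edges are rejected; both
#' reciprocity-aware (directed) and symmetrized views are supported by the
#' metric functions.
#'
#' @param nodes Data frame with columns `id`, `lat`, `lon`; ids unique.
#' @param edges Data frame with columns `src`, `dst` referencing node ids.
#' @return A `geonet` object.
#' @export
geonet <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "lat", "lon") %in% names(nodes)))
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique", call. = FALSE)
  validate_coords(nodes$lat, nodes$lon)
  if (is.null(edges))
    edges <- tibble::tibble(src = nodes$id[0], dst = nodes$id[0])
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("src", "dst") %in% names(edges)))
  if (nrow(edges)) {
    if (!all(edges$src %in% nodes$id) || !all(edges$dst %in% nodes$id))
      stop("edge endpoints must reference node ids", call. = FALSE)
    if (any(edges$src == edges$dst))
      stop("self-loops are not allowed", call. = FALSE)
    if (anyDuplicated(paste(edges$src, edges$dst)))
      stop("duplicate directed edges are not allowed", call. = FALSE)
  }
  structure(list(nodes = nodes[, c("id", "lat", "lon")],
                 edges = edges[, c("src", "dst")]),
            class = "geonet")
}

#' @export
print.geonet <- function(x, ...) {
  cat(sprintf("<geonet> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)
n_edges <- function(net) nrow(net$edges)

# edge endpoints as 1-based node positions
edge_index <- function(net) {
  list(src = match(net$edges$src, net$nodes$id),
       dst = match(net$edges$dst, net$nodes$id))
}

# adjacency as a list of integer node positions
adj_list <- function(net, mode = c("out", "in", "union")) {
  mode <- match.arg(mode)
  n <- n_nodes(net)
  ei <- edge_index(net)
  out <- rep(list(integer()), n)
  if (!length(ei$src)) return(out)
  pairs <- switch(mode,
    out = list(from = ei$src, to = ei$dst),
    `in` = list(from = ei$dst, to = ei$src),
    union = {
      u <- pmin(ei$src, ei$dst); v <- pmax(ei$src, ei$dst)
      keep <- !duplicated(u * (n + 1) + v)
      list(from = c(u[keep], v[keep]), to = c(v[keep], u[keep]))
    })
  sp <- split(pairs$to, factor(pairs$from, levels = seq_len(n)))
  lapply(sp, function(v) sort(unique(v)))
}

# unique undirected edges as positions (u < v)
union_edges <- function(net) {
  ei <- edge_index(net)
  if (!length(ei$src))
    return(list(u = integer(), v = integer()))
  u <- pmin(ei$src, ei$dst); v <- pmax(ei$src, ei$dst)
  keep <- !duplicated(u * (n_nodes(net) + 1) + v)
  list(u = u[keep], v = v[keep])
}

# distance in km between node positions
node_distance <- function(net, i, j) {
  cpp_haversine(net$nodes$lat[i], net$nodes$lon[i],
                net$nodes$lat[j], net$nodes$lon[j])
}

#' Tidy a geo-social network
#'
#' `tidy()` returns the directed edge table augmented with the great-circle
#' distance of each edge and whether its reverse edge exists; `glance()`
#' returns one-row scalar structure (nodes, edges, global clustering,
#' reciprocity, connected nodes).
#'
#' @param x A [geonet].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy geonet
#' @export
tidy.geonet <- function(x, ...) {
  ei <- edge_index(x)
  n <- n_nodes(x)
  key <- ei$src * (n + 1) + ei$dst
  rkey <- ei$dst * (n + 1) + ei$src
  tibble::tibble(
    src = x$edges$src, dst = x$edges$dst,
    distance_km = node_distance(x, ei$src, ei$dst),
    reciprocated = rkey %in% key)
}

#' @rdname tidy.geonet
#' @method glance geonet
#' @export
glance.geonet <- function(x, ...) {
  s <- scalar_summary(x)
  tibble::tibble(n_nodes = n_nodes(x), n_edges = n_edges(x),
                 n_connected = s$n_connected,
                 mean_local_clustering = s$mean_local_clustering,
                 global_clustering = s$global_clustering,
                 global_reciprocity = s$global_reciprocity)
}
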