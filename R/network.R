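#' Dispersal-thresholded habitat network
#'
#' Connects every pair of patches whose edge-to-edge distance is at most the
#' dispersal threshold `theta`; the distance becomes the edge weight. The
#' threshold rule is closed (`d <= theta`), so the printed round-number
#' thresholds are inclusive. Patches with no neighbour within `theta` stay as
#' isolated nodes.
#'
#' @param d Distance matrix from [pairwise_edge_distance()].
#' @param theta Dispersal threshold in metres (> 0). Typical odonate values:
#'   250, 500, 750, 1000, 2000 m.
#' @param timestep Time label carried from the source layer.
#' @return A `habitat_network`: list with `nodes` (patch ids), `edges`
#'   (tibble `from`, `to`, `weight`), `theta`, `timestep`.
#' @export
build_network <- function(d, theta, timestep = NA) {
  stopifnot(is.matrix(d), theta > 0)
  ids <- rownames(d)
  idx <- which(upper.tri(d) & d <= theta, arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          weight = as.numeric(d[idx]))
  structure(list(nodes = ids, edges = edges, theta = theta,
                 timestep = timestep),
            class = "habitat_network")
}

#' @export
print.habitat_network <- function(x, ...) {
  cat(sprintf("<habitat_network> t = %s, theta = %g m: %d nodes, %d edges\n",
              format(x$timestep), x$theta, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  igraph::V(g)$name <- net$nodes
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(net$edges$from, net$nodes),
                                    match(net$edges$to, net$nodes)))
    igraph::E(g)$weight <- net$edges$weight
  }
  g
}

#' Connected components of a habitat network
#'
#' Components are maximal sets of mutually reachable patches with no edges
#' leaving the set — the operational definition of a metacommunity. Two
#' patches farther apart than the threshold still share a component when a
#' chain of intermediate stepping-stone patches links them.
#'
#' @param net A [build_network()] result.
#' @return A `component_partition`: tibble with `patch_id` and integer
#'   `component` (numbered in order of first appearance in the node list),
#'   carrying the source network's `theta`/`timestep` as attributes.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "habitat_network"))
  memb <- igraph::components(as_igraph(net))$membership
  # deterministic relabel: component 1 contains the first node, etc.
  relab <- match(memb, unique(memb))
  structure(
    tibble::tibble(patch_id = net$nodes, component = relab),
    theta = net$theta, timestep = net$timestep,
    class = c("component_partition", class(tibble::tibble()))
  )
}

#' Mean (and maximum) shortest-path distance within a component
#'
#' Metacommunity "network diameter" in the sense used for gamma-diversity
#' scaling: the mean over all unordered member pairs of the weighted
#' shortest-path distance, with inter-patch distances as edge weights. The
#' graph-theoretic maximum-eccentricity diameter is reported alongside as an
#' attribute (`max`) for transparency, since the two usages conflict.
#'
#' @param net A [build_network()] result.
#' @param members Patch ids of one connected component (>= 2 nodes).
#' @return Mean shortest-path distance in metres (attribute `max` holds the
#'   maximum); `NA` with a warning for singleton components.
#' @export
network_diameter <- function(net, members) {
  stopifnot(inherits(net, "habitat_network"))
  members <- intersect(net$nodes, members)
  if (length(members) < 2) {
    warning("network diameter undefined for singleton component")
    return(structure(NA_real_, max = NA_real_))
  }
  g <- as_igraph(net)
  dm <- igraph::distances(g, v = members, to = members,
                          algorithm = "dijkstra")
  up <- dm[upper.tri(dm)]
  if (any(!is.finite(up))) stop("component members are not mutually connected")
  structure(mean(up), max = max(up))
}

#' Export a network as edge-list and node CSV files
#'
#' @param net A `habitat_network`.
#' @param edge_path,node_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network_csv <- function(net, edge_path, node_path) {
  readr::write_csv(dplyr::mutate(net$edges, weight = num12(.data$weight)),
                   edge_path)
  comp <- network_components(net)
  readr::write_csv(comp, node_path)
  invisible(c(edge_path, node_path))
}
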