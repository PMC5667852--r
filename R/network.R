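#' Merge contiguous high-protection reserves into complexes
#'
#' National parks, nature reserves and game reserves that share a common
#' border (positive shared boundary length; corner contact does not count)
#' are merged, transitively, into protected-area complexes. Lower-protection
#' areas are never merged and remain standalone network nodes.
#'
#' @param pas a [pa_table()].
#' @return a data.frame with one row per complex: `complex_id`, `members`
#'   (comma-joined PA ids), `n_members`.
#' @export
build_complexes <- function(pas) {
  hi <- which(is_high_protection(pas$protection_level))
  if (!length(hi))
    return(data.frame(complex_id = character(0), members = character(0),
                      n_members = integer(0), stringsAsFactors = FALSE))
  n <- length(hi)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (shared_border_length(pas$geometry[[hi[i]]],
                               pas$geometry[[hi[j]]]) > 0)
        edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  members <- split(pas$id[hi], comp)
  data.frame(
    complex_id = vapply(members, function(m) paste0("cx_", m[1]), ""),
    members = vapply(members, paste, "", collapse = ","),
    n_members = lengths(members), stringsAsFactors = FALSE,
    row.names = NULL)
}

node_of_pa <- function(pa_id, complexes) {
  if (nrow(complexes)) {
    for (i in seq_len(nrow(complexes))) {
      if (pa_id %in% strsplit(complexes$members[i], ",")[[1]])
        return(complexes$complex_id[i])
    }
  }
  pa_id
}

#' Assemble the corridor network graph
#'
#' Nodes are protected-area complexes plus standalone (low-protection)
#' areas; edges are classified corridor results. Dropped corridors are
#' excluded, as are corridors internal to a single complex. At most one
#' edge may join a node pair.
#'
#' @param complexes a [build_complexes()] table.
#' @param results a classified corridor table (data.frame with `pa_a`,
#'   `pa_b`, `status`, and optionally `cwd_weighted_km` and flag columns).
#' @param pas the [pa_table()] the results refer to.
#' @return an object of class `corridor_network`: list with `nodes`
#'   (node table) and `edges` (edge table with node ids and status).
#' @export
build_network <- function(complexes, results, pas) {
  unknown <- setdiff(unique(c(results$pa_a, results$pa_b)), pas$id)
  if (length(unknown))
    stop("corridor endpoints not in the protected-area table: ",
         paste(unknown, collapse = ", "))
  standalone <- pas$id[!is_high_protection(pas$protection_level)]
  nodes <- data.frame(
    node = c(complexes$complex_id, standalone),
    members = c(complexes$members, standalone),
    protection = c(rep("high", nrow(complexes)),
                   pas$protection_level[match(standalone, pas$id)]),
    stringsAsFactors = FALSE)

  keep <- results$status %in% c("open", "severed", "contiguous")
  res <- results[keep, , drop = FALSE]
  if (nrow(res)) {
    res$node_a <- vapply(res$pa_a, node_of_pa, "", complexes = complexes)
    res$node_b <- vapply(res$pa_b, node_of_pa, "", complexes = complexes)
    res <- res[res$node_a != res$node_b, , drop = FALSE]  # intra-complex
  }
  if (nrow(res)) {
    key <- apply(cbind(pmin(res$node_a, res$node_b),
                       pmax(res$node_a, res$node_b)), 1, paste,
                 collapse = "|")
    if (anyDuplicated(key))
      stop("duplicate corridor edge between the same node pair")
  }
  edge_cols <- intersect(c("node_a", "node_b", "pa_a", "pa_b", "status",
                           "cwd_weighted_km", "euclidean_km",
                           "crosses_converted", "crosses_future_converted",
                           "natural_barrier"),
                         names(res))
  structure(list(nodes = nodes,
                 edges = if (nrow(res)) res[edge_cols] else
                   data.frame(node_a = character(0), node_b = character(0),
                              status = character(0))),
            class = "corridor_network")
}

#' Reserves isolated from the rest of the network
#'
#' Nodes with no open and no contiguous edge — every linkage they ever had
#' is severed (or they never had one) — are completely isolated.
#'
#' @param net a [build_network()] result.
#' @return character vector of isolated node ids.
#' @export
isolated_nodes <- function(net) {
  e <- net$edges
  usable <- e[e$status %in% c("open", "contiguous"), , drop = FALSE]
  connected <- unique(c(usable$node_a, usable$node_b))
  setdiff(net$nodes$node, connected)
}

#' Low-protection stepping-stone reserves
#'
#' A stepping-stone is a lower-protection reserve lying on open corridors
#' that together reach at least two distinct high-protection nodes: either
#' as a corridor endpoint itself, or transited by the sliced corridor of
#' an open linkage between two high-protection nodes. Only the open
#' subgraph confers stepping-stone function.
#'
#' @param net a [build_network()] result.
#' @param pas the [pa_table()].
#' @param corridor_cells optional named list (by `"pa_a|pa_b"`) of logical
#'   corridor masks for transit detection.
#' @param grid the frame-defining [corridor_grid()] (needed with
#'   `corridor_cells`).
#' @return data.frame `node`, `linked_high_nodes`, `n_linked`, `role`
#'   (`"endpoint"`, `"transit"` or `"endpoint+transit"`), one row per
#'   stepping-stone.
#' @export
stepping_stones <- function(net, pas, corridor_cells = NULL, grid = NULL) {
  low <- net$nodes$node[net$nodes$protection != "high"]
  high <- net$nodes$node[net$nodes$protection == "high"]
  open_e <- net$edges[net$edges$status == "open", , drop = FALSE]
  out <- list()
  for (nd in low) {
    reached <- character(0); role <- character(0)
    # endpoint role: open edges from this node to high-protection nodes
    if (nrow(open_e)) {
      touch <- open_e$node_a == nd | open_e$node_b == nd
      other <- ifelse(open_e$node_a == nd, open_e$node_b, open_e$node_a)
      hits <- unique(other[touch & other %in% high])
      if (length(hits)) { reached <- union(reached, hits); role <- "endpoint" }
    }
    # transit role: node polygon intersected by an open high-high corridor
    if (!is.null(corridor_cells) && nrow(open_e)) {
      idx <- match(nd, pas$id)
      if (!is.na(idx) && !is.null(grid)) {
        nd_cells <- tryCatch(rasterize_sources(pas$geometry[[idx]], grid),
                             error = function(e) integer(0))
        hh <- open_e$node_a %in% high & open_e$node_b %in% high
        for (i in which(hh)) {
          key <- paste(open_e$pa_a[i], open_e$pa_b[i], sep = "|")
          mask <- corridor_cells[[key]]
          if (!is.null(mask) && length(nd_cells) && any(mask[nd_cells])) {
            reached <- union(reached, c(open_e$node_a[i], open_e$node_b[i]))
            role <- union(role, "transit")
          }
        }
      }
    }
    if (length(reached) >= 2)
      out[[nd]] <- data.frame(node = nd,
                              linked_high_nodes = paste(sort(reached),
                                                        collapse = ","),
                              n_linked = length(reached),
                              role = paste(sort(role), collapse = "+"),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(node = character(0), linked_high_nodes = character(0),
                      n_linked = integer(0), role = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
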