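#' Skeleton-to-graph conversion and topological counts
#'
#' The thinned nerve network is transformed into a connected graph of typed
#' nodes and weighted paths. Skeleton pixels are classified by their
#' 8-neighbour count (1 = end, 2 = path, >= 3 = junction); maximal
#' 8-connected sets of junction pixels collapse into single branch nodes;
#' fibre terminals in the 1-px border band are connectivity points (a nerve
#' entering or leaving the imaged field), other terminals are true nerve
#' endings. Edges are traced along path pixels between node pixels and
#' weighted by chain-code length: 1 per orthogonal step, sqrt(2) per
#' diagonal step, times the pixel pitch.
#'
#' @name graph_topology
NULL

SQRT2 <- sqrt(2)

#' Classify skeleton pixels
#'
#' @param skel an `sbp_skeleton`.
#' @return data.frame with one row per skeleton pixel: `row`, `col`,
#'   `nbrs` (8-neighbour count), `class` in
#'   `{"isolated","end","path","junction"}`, and `border` (logical; pixel
#'   lies in the outermost row/column band).
#' @export
classify_pixels <- function(skel) {
  stopifnot(inherits(skel, "sbp_skeleton"))
  m <- skel$skeleton
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  B <- ring_stats(pad)$B[2:(nr + 1L), 2:(nc + 1L)]
  fg <- which(m == 1L)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  nbrs <- B[fg]
  cls <- ifelse(nbrs == 0L, "isolated",
         ifelse(nbrs == 1L, "end",
         ifelse(nbrs == 2L, "path", "junction")))
  data.frame(row = rr, col = cc, nbrs = nbrs, class = cls,
             border = rr == 1L | rr == nr | cc == 1L | cc == nc,
             stringsAsFactors = FALSE)
}

# walk from a node pixel `start` into neighbour `nxt` along path pixels
# until another node pixel (or `start` again, for loops) is hit.
# `is_node` is a logical matrix; returns the full pixel path incl both ends.
trace_path <- function(m, is_node, start, nxt) {
  nr <- nrow(m)
  path <- c(start, nxt)
  prev <- start
  cur <- nxt
  while (!is_node[cur]) {
    r <- ((cur - 1L) %% nr) + 1L
    c <- ((cur - 1L) %/% nr) + 1L
    nbs <- cur + (RING[, 2] * nr + RING[, 1])   # linear indices of ring
    ok <- r + RING[, 1] >= 1L & r + RING[, 1] <= nr &
        c + RING[, 2] >= 1L & c + RING[, 2] <= ncol(m)
    nbs <- nbs[ok]
    nbs <- nbs[m[nbs] == 1L & nbs != prev]
    if (length(nbs) == 0L) break           # dangling path end (defensive)
    # path pixel has exactly 2 neighbours; take the one we did not come from
    prev <- cur
    cur <- nbs[1L]
    path <- c(path, cur)
  }
  path
}

path_length_steps <- function(path, nr) {
  r <- ((path - 1L) %% nr) + 1L
  c <- ((path - 1L) %/% nr) + 1L
  dr <- abs(diff(r)); dc <- abs(diff(c))
  diag <- sum(dr == 1L & dc == 1L)
  orth <- length(dr) - diag
  c(orth = orth, diag = diag)
}

#' Chain-code length of an edge
#'
#' @param edge one row of the graph's edge table (or a list with `n_orth`,
#'   `n_diag`).
#' @param pixel_pitch_um micrometres per pixel.
#' @return length in micrometres: `(n_orth + sqrt(2) n_diag) * pitch`.
#' @export
edge_length <- function(edge, pixel_pitch_um = DEFAULT_PITCH_UM) {
  (edge$n_orth + SQRT2 * edge$n_diag) * pixel_pitch_um
}

# core graph extraction on a skeleton matrix; no pruning
build_graph_raw <- function(m, pitch) {
  nr <- nrow(m); nc <- ncol(m)
  px <- classify_pixels(as_skeleton(m, pitch))
  nodes <- list()     # each: list(kind, pixels (linear), rep_row, rep_col)
  node_of <- matrix(0L, nr, nc)   # pixel -> node id (0 = not a node pixel)

  lin <- function(r, c) (c - 1L) * nr + r

  # branch nodes: 8-connected clusters of junction pixels
  jmask <- matrix(0L, nr, nc)
  j <- px[px$class == "junction", ]
  if (nrow(j)) jmask[lin(j$row, j$col)] <- 1L
  jlab <- label_binary(jmask)
  nid <- 0L
  if (max(jlab) > 0L) {
    for (k in seq_len(max(jlab))) {
      pix <- which(jlab == k)
      nid <- nid + 1L
      rr <- ((pix - 1L) %% nr) + 1L
      cc <- ((pix - 1L) %/% nr) + 1L
      o <- order(rr, cc)
      nodes[[nid]] <- list(kind = "branch", pixels = pix,
                           row = rr[o[1L]], col = cc[o[1L]])
      node_of[pix] <- nid
    }
  }
  # terminal nodes: end pixels; border band => connectivity point
  term <- px[px$class == "end", ]
  if (nrow(term)) {
    o <- order(term$row, term$col)
    for (i in o) {
      nid <- nid + 1L
      kind <- if (term$border[i]) "connectivity" else "endpoint"
      pix <- lin(term$row[i], term$col[i])
      nodes[[nid]] <- list(kind = kind, pixels = pix,
                           row = term$row[i], col = term$col[i])
      node_of[pix] <- nid
    }
  }
  # isolated single pixels: degree-0 nodes
  iso <- px[px$class == "isolated", ]
  if (nrow(iso)) {
    for (i in order(iso$row, iso$col)) {
      nid <- nid + 1L
      pix <- lin(iso$row[i], iso$col[i])
      nodes[[nid]] <- list(kind = "isolated", pixels = pix,
                           row = iso$row[i], col = iso$col[i])
      node_of[pix] <- nid
    }
  }

  is_node <- node_of > 0L
  # trace edges out of every node pixel; dedupe on (node id, first path px)
  edges <- list()
  paths <- list()
  eid <- 0L
  used <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(nodeid, firstpix) paste0(nodeid, "_", firstpix)
  node_order <- order(vapply(nodes, function(n) n$row, 0L),
                      vapply(nodes, function(n) n$col, 0L))
  for (ni in node_order) {
    if (nodes[[ni]]$kind == "isolated") next
    for (p in sort(nodes[[ni]]$pixels)) {
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- r + RING[k, 1]; c2 <- c + RING[k, 2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- lin(r2, c2)
        if (m[q] != 1L) next
        if (node_of[q] == ni) next          # internal cluster adjacency
        if (!is.null(used[[key(ni, q)]])) next
        path <- trace_path(m, is_node, p, q)
        last <- path[length(path)]
        n2 <- node_of[last]
        if (n2 == 0L) next                  # defensive: dangling trace
        # consume both directed entries of this edge
        used[[key(ni, q)]] <- TRUE
        used[[key(n2, path[length(path) - 1L])]] <- TRUE
        st <- path_length_steps(path, nr)
        eid <- eid + 1L
        edges[[eid]] <- c(node1 = ni, node2 = n2,
                          n_orth = st[["orth"]], n_diag = st[["diag"]])
        paths[[eid]] <- path
      }
    }
  }
  # pure cycles: remaining path pixels not visited by any traced edge
  visited <- matrix(FALSE, nr, nc)
  for (pp in paths) visited[pp] <- TRUE
  leftover <- which(m == 1L & !visited & !is_node)
  if (length(leftover)) {
    lrr <- ((leftover - 1L) %% nr) + 1L
    lcc <- ((leftover - 1L) %/% nr) + 1L
    for (i in order(lrr, lcc)) {
      p <- leftover[i]
      if (visited[p]) next
      # anchor the cycle at p: walk to one neighbour until we return
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      nbs <- integer(0)
      for (k in 1:8) {
        r2 <- r + RING[k, 1]; c2 <- c + RING[k, 2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (m[lin(r2, c2)] == 1L) nbs <- c(nbs, lin(r2, c2))
      }
      anchor_node <- matrix(FALSE, nr, nc)
      anchor_node[p] <- TRUE
      path <- trace_path(m, anchor_node, p, nbs[1L])
      nid <- nid + 1L
      nodes[[nid]] <- list(kind = "loop", pixels = p, row = r, col = c)
      st <- path_length_steps(path, nr)
      eid <- eid + 1L
      edges[[eid]] <- c(node1 = nid, node2 = nid,
                        n_orth = st[["orth"]], n_diag = st[["diag"]])
      paths[[eid]] <- path
      visited[path] <- TRUE
    }
  }

  node_df <- data.frame(
    id = seq_along(nodes),
    kind = vapply(nodes, function(n) n$kind, ""),
    row = vapply(nodes, function(n) n$row, 0L),
    col = vapply(nodes, function(n) n$col, 0L),
    stringsAsFactors = FALSE)
  if (eid > 0L) {
    em <- do.call(rbind, edges)
    edge_df <- data.frame(id = seq_len(eid), em)
    edge_df$length_um <- (edge_df$n_orth + SQRT2 * edge_df$n_diag) * pitch
  } else {
    edge_df <- data.frame(id = integer(0), node1 = integer(0),
                          node2 = integer(0), n_orth = integer(0),
                          n_diag = integer(0), length_um = numeric(0))
  }
  list(nodes = node_df, edges = edge_df,
       node_pixels = lapply(nodes, function(n) n$pixels),
       edge_paths = paths, skeleton = m, pixel_pitch_um = pitch)
}

# remove spur edges and isolated pixels from the skeleton matrix; returns
# the cleaned matrix. A spur is an edge shorter than min_segment_um with a
# degree-1 endpoint/connectivity terminal; its terminal and interior path
# pixels are erased (junction clusters stay).
prune_skeleton <- function(g, min_segment_um) {
  m <- g$skeleton
  if (nrow(g$edges) == 0L && nrow(g$nodes) == 0L) return(m)
  deg <- tabulate(c(g$edges$node1, g$edges$node2), nbins = nrow(g$nodes))
  # isolated single pixels carry no length
  for (i in which(g$nodes$kind == "isolated")) m[g$node_pixels[[i]]] <- 0L
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      if (g$edges$length_um[e] >= min_segment_um) next
      n1 <- g$edges$node1[e]; n2 <- g$edges$node2[e]
      k1 <- g$nodes$kind[n1]; k2 <- g$nodes$kind[n2]
      t1 <- k1 %in% c("endpoint", "connectivity") && deg[n1] == 1L
      t2 <- k2 %in% c("endpoint", "connectivity") && deg[n2] == 1L
      if (!t1 && !t2) next
      path <- g$edge_paths[[e]]
      if (t1 && t2) {
        m[path] <- 0L                      # whole tiny segment
      } else if (t1) {
        m[path[-length(path)]] <- 0L       # keep the node at the far end
      } else {
        m[path[-1L]] <- 0L
      }
    }
  }
  m
}

# merge branch nodes connected by an internal edge shorter than the
# junction scale: thinning a wide or shallow-angle Y-junction splits one
# anatomical branch point into nearby 3-valent clusters; the connecting
# micro-edge is absorbed into a single branch node.
merge_close_branches <- function(g, junction_merge_um) {
  if (nrow(g$edges) == 0L) return(g)
  short <- which(g$edges$length_um < junction_merge_um &
                 g$nodes$kind[g$edges$node1] == "branch" &
                 g$nodes$kind[g$edges$node2] == "branch" &
                 g$edges$node1 != g$edges$node2)
  if (!length(short)) return(g)
  # union-find over nodes through the short internal edges
  parent <- seq_len(nrow(g$nodes))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in short) {
    r1 <- find(g$edges$node1[e]); r2 <- find(g$edges$node2[e])
    if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
  }
  root <- vapply(seq_len(nrow(g$nodes)), find, 0L)
  # absorb the connecting path pixels into the merged node cluster
  for (e in short) {
    tgt <- root[g$edges$node1[e]]
    inner <- g$edge_paths[[e]]
    g$node_pixels[[tgt]] <- sort(unique(c(g$node_pixels[[tgt]], inner)))
  }
  keep_e <- setdiff(seq_len(nrow(g$edges)), short)
  g$edges <- g$edges[keep_e, , drop = FALSE]
  g$edge_paths <- g$edge_paths[keep_e]
  g$edges$node1 <- root[g$edges$node1]
  g$edges$node2 <- root[g$edges$node2]
  # drop absorbed nodes, renumber
  keep_n <- which(root == seq_along(root))
  remap <- integer(nrow(g$nodes)); remap[keep_n] <- seq_along(keep_n)
  for (i in keep_n) {
    members <- which(root == i & root != seq_along(root))
    for (mm in members)
      g$node_pixels[[i]] <- sort(unique(c(g$node_pixels[[i]],
                                          g$node_pixels[[mm]])))
  }
  g$nodes <- g$nodes[keep_n, , drop = FALSE]
  g$nodes$id <- seq_len(nrow(g$nodes))
  g$node_pixels <- g$node_pixels[keep_n]
  g$edges$node1 <- remap[g$edges$node1]
  g$edges$node2 <- remap[g$edges$node2]
  if (nrow(g$edges)) g$edges$id <- seq_len(nrow(g$edges))
  g
}

#' Build the nerve-fibre graph from a skeleton
#'
#' Converts the medial-axis image into a graph: branch nodes (clustered
#' junction pixels), endpoints, border-crossing connectivity points, and
#' edges traced along path pixels with chain-code lengths. Spur edges
#' shorter than `min_segment_um` that end in a free terminal are pruned
#' (thinning artefacts), isolated single pixels are dropped, and branch
#' nodes joined by an internal edge shorter than `min_segment_um` are merged
#' into one branch point; node types are then recomputed on the cleaned
#' skeleton. Closed loops with no node receive an anchor of kind `"loop"`
#' carrying a self-loop edge, so total length is conserved; loop anchors are
#' not counted as branches, endpoints or connectivity points.
#'
#' @param skel an `sbp_skeleton`.
#' @param min_segment_um spur-pruning threshold in micrometres (default 2).
#' @param junction_merge_um branch nodes joined by an internal edge shorter
#'   than this are one anatomical branch point (default 10; a Y-junction of
#'   3-px strokes meeting at a shallow angle thins into junction pixels up
#'   to ~10 um apart).
#' @param prune set `FALSE` to keep spurs and isolated pixels.
#' @return object of class `sbp_graph`: `nodes` and `edges` data frames,
#'   `node_pixels` and `edge_paths` (pixel support, column-major linear
#'   indices), the cleaned `skeleton` matrix, `pixel_pitch_um`, and
#'   `n_components` (graph components).
#' @export
build_graph <- function(skel, min_segment_um = 2, junction_merge_um = 10,
                        prune = TRUE) {
  stopifnot(inherits(skel, "sbp_skeleton"))
  g <- build_graph_raw(skel$skeleton, skel$pixel_pitch_um)
  if (prune) {
    cleaned <- prune_skeleton(g, min_segment_um)
    if (!identical(cleaned, g$skeleton)) {
      # spur removal can leave a redundant nub on the remaining line
      cleaned <- cleanup_cropped(cleaned)
      g <- build_graph_raw(cleaned, skel$pixel_pitch_um)
    }
    g <- merge_close_branches(g, junction_merge_um)
    # micro-cycles around a single branch node (thinned Y-junctions can
    # leave a pixel triangle): absorb into the node; anatomical fibre
    # loops are orders of magnitude longer than the junction scale
    micro <- which(g$edges$node1 == g$edges$node2 &
                   g$nodes$kind[g$edges$node1] == "branch" &
                   g$edges$length_um < junction_merge_um)
    if (length(micro)) {
      for (e in micro) {
        tgt <- g$edges$node1[e]
        g$node_pixels[[tgt]] <- sort(unique(c(g$node_pixels[[tgt]],
                                              g$edge_paths[[e]])))
      }
      keep <- setdiff(seq_len(nrow(g$edges)), micro)
      g$edges <- g$edges[keep, , drop = FALSE]
      g$edge_paths <- g$edge_paths[keep]
      if (nrow(g$edges)) g$edges$id <- seq_len(nrow(g$edges))
    }
  }
  # component partition of the node/edge graph
  if (nrow(g$nodes)) {
    ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
    if (nrow(g$edges))
      ig <- igraph::add_edges(ig, rbind(g$edges$node1, g$edges$node2))
    g$membership <- igraph::components(ig)$membership
    g$n_components <- max(g$membership)
  } else {
    g$membership <- integer(0)
    g$n_components <- 0L
  }
  class(g) <- "sbp_graph"
  g
}

#' Count graph nodes of a given kind
#'
#' @param g an `sbp_graph`.
#' @param kind one of `"branch"`, `"endpoint"`, `"connectivity"`.
#' @return node count.
#' @export
count_nodes <- function(g, kind) {
  stopifnot(inherits(g, "sbp_graph"))
  if (!kind %in% c("branch", "endpoint", "connectivity"))
    stop("unknown node kind: ", kind)
  sum(g$nodes$kind == kind)
}

#' Total fibre length of a graph
#'
#' @param g an `sbp_graph`.
#' @return sum of chain-code edge lengths in micrometres.
#' @export
total_length_um <- function(g) {
  stopifnot(inherits(g, "sbp_graph"))
  sum(g$edges$length_um)
}

#' @export
print.sbp_graph <- function(x, ...) {
  cat(sprintf(
    "<sbp_graph> %d nodes (%d branch, %d endpoint, %d connectivity), %d edges, %d components, %.1f um\n",
    nrow(x$nodes), count_nodes(x, "branch"), count_nodes(x, "endpoint"),
    count_nodes(x, "connectivity"), nrow(x$edges), x$n_components,
    total_length_um(x)))
  invisible(x)
}

#' Export a graph as a plain-text edge list
#'
#' Writes two sections: nodes (`node_id kind row col`) then edges
#' (`edge_id node1 node2 n_orth n_diag length_um`), whitespace-separated,
#' for debugging and external inspection.
#'
#' @param g an `sbp_graph`.
#' @param path output file.
#' @export
write_graph_txt <- function(g, path) {
  stopifnot(inherits(g, "sbp_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodes: id kind row col", con)
  if (nrow(g$nodes))
    writeLines(sprintf("%d %s %d %d", g$nodes$id, g$nodes$kind,
                       g$nodes$row, g$nodes$col), con)
  writeLines("# edges: id node1 node2 n_orth n_diag length_um", con)
  if (nrow(g$edges))
    writeLines(sprintf("%d %d %d %d %d %.6f", g$edges$id, g$edges$node1,
                       g$edges$node2, g$edges$n_orth, g$edges$n_diag,
                       g$edges$length_um), con)
  invisible(path)
}
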