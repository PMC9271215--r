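#' Spatial vessel graph
#'
#' A multigraph of nodes (branch points, endpoints, control-volume
#' boundary cuts) joined by segments; each segment carries an ordered
#' polyline in micrometre coordinates and a radius per polyline point.
#' The first polyline point coincides with \code{node_a}'s position and
#' the last with \code{node_b}'s.
#'
#' @param nodes data.frame with columns \code{id, x, y, z, kind};
#'   \code{kind} one of \code{"branch"}, \code{"endpoint"},
#'   \code{"boundary"}, \code{"interior"}, \code{"isolated"}.
#' @param segments data.frame with columns \code{id, node_a, node_b};
#'   \code{length_um} and \code{mean_radius_um} are recomputed.
#' @param polylines list of n x 3 numeric matrices, one per segment row.
#' @param radii list of numeric vectors matching the polylines.
#' @return An object of class \code{vessel_graph}.
#' @export
vessel_graph <- function(nodes = NULL, segments = NULL, polylines = list(),
                         radii = list()) {
  if (is.null(nodes))
    nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        z = numeric(), kind = character())
  if (is.null(segments))
    segments <- data.frame(id = integer(), node_a = integer(),
                           node_b = integer())
  stopifnot(nrow(segments) == length(polylines),
            length(polylines) == length(radii))
  g <- structure(list(nodes = nodes, segments = segments,
                      polylines = polylines, radii = radii),
                 class = "vessel_graph")
  refresh_graph(g)
}

#' @exportS3Method base::print
print.vessel_graph <- function(x, ...) {
  cat(sprintf(
    "<vessel_graph> %d nodes, %d segments, total length %.1f um\n",
    nrow(x$nodes), nrow(x$segments), graph_total_length(x)))
  if (nrow(x$nodes)) {
    kt <- table(x$nodes$kind)
    cat("  nodes:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  }
  invisible(x)
}

polyline_length <- function(p) {
  if (is.null(p) || nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Total centreline length of a graph in micrometres
#' @param g a \code{vessel_graph}.
#' @return total length (um).
#' @export
graph_total_length <- function(g) {
  if (!nrow(g$segments)) return(0)
  sum(g$segments$length_um)
}

#' Node degrees of a vessel graph
#' @param g a \code{vessel_graph}.
#' @return named integer vector, degree per node id (self-loops count twice).
#' @export
node_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  names(deg) <- as.character(g$nodes$id)
  if (nrow(g$segments)) {
    t1 <- table(as.character(g$segments$node_a))
    t2 <- table(as.character(g$segments$node_b))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

# Recompute lengths, mean radii and node kinds (boundary kind is sticky).
refresh_graph <- function(g) {
  n <- nrow(g$segments)
  if (n) {
    g$segments$length_um <- vapply(g$polylines, polyline_length, 0)
    g$segments$mean_radius_um <-
      vapply(g$radii, function(r) if (length(r)) mean(r) else NA_real_, 0)
  } else {
    g$segments$length_um <- numeric(0)
    g$segments$mean_radius_um <- numeric(0)
  }
  if (nrow(g$nodes)) {
    deg <- node_degrees(g)
    kind <- ifelse(deg == 0, "isolated",
            ifelse(deg == 1, "endpoint",
            ifelse(deg == 2, "interior", "branch")))
    keep <- g$nodes$kind == "boundary" & !is.na(g$nodes$kind)
    g$nodes$kind <- ifelse(keep, "boundary", kind[as.character(g$nodes$id)])
  }
  g
}

#' Connected components of a vessel graph
#' @param g a \code{vessel_graph}.
#' @return integer vector of component labels, one per node (named by id).
#' @export
graph_components <- function(g) {
  if (!nrow(g$nodes)) return(setNames(integer(0), character(0)))
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$segments$node_a),
                   to = as.character(g$segments$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id)))
  igraph::components(ig)$membership[as.character(g$nodes$id)]
}

#' Number of independent cycles (first Betti number)
#' @param g a \code{vessel_graph}.
#' @return integer cycle count: edges - nodes + components.
#' @export
graph_cycle_count <- function(g) {
  if (!nrow(g$nodes)) return(0L)
  comp <- length(unique(graph_components(g)))
  nrow(g$segments) - nrow(g$nodes) + comp
}

# Drop nodes not referenced by any segment unless they are isolated on
# purpose; renumber nothing (ids are stable).
drop_orphan_nodes <- function(g, keep_isolated_nodes = FALSE) {
  used <- unique(c(g$segments$node_a, g$segments$node_b))
  if (keep_isolated_nodes) return(g)
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  rownames(g$nodes) <- NULL
  g
}

# Merge pairs of segments meeting at interior (degree-2, non-boundary)
# nodes into single polylines; self-loops are left alone.
collapse_interior_nodes <- function(g) {
  repeat {
    deg <- node_degrees(g)
    cand <- g$nodes$id[deg[as.character(g$nodes$id)] == 2 &
                         g$nodes$kind != "boundary"]
    done <- TRUE
    for (nid in cand) {
      inc <- which(g$segments$node_a == nid | g$segments$node_b == nid)
      if (length(inc) != 2) next  # self-loop at nid (single segment twice)
      s1 <- inc[1]; s2 <- inc[2]
      p1 <- g$polylines[[s1]]; r1 <- g$radii[[s1]]
      p2 <- g$polylines[[s2]]; r2 <- g$radii[[s2]]
      # orient: s1 ends at nid, s2 starts at nid
      if (g$segments$node_a[s1] == nid) {
        p1 <- p1[nrow(p1):1, , drop = FALSE]; r1 <- rev(r1)
        a <- g$segments$node_b[s1]
      } else a <- g$segments$node_a[s1]
      if (g$segments$node_b[s2] == nid) {
        p2 <- p2[nrow(p2):1, , drop = FALSE]; r2 <- rev(r2)
        b <- g$segments$node_a[s2]
      } else b <- g$segments$node_b[s2]
      g$polylines[[s1]] <- rbind(p1, p2[-1, , drop = FALSE])
      g$radii[[s1]] <- c(r1, r2[-1])
      g$segments$node_a[s1] <- a
      g$segments$node_b[s1] <- b
      g$segments <- g$segments[-s2, , drop = FALSE]
      g$polylines[[s2]] <- NULL
      g$radii[[s2]] <- NULL
      rownames(g$segments) <- NULL
      done <- FALSE
      break
    }
    if (done) break
  }
  refresh_graph(drop_orphan_nodes(g))
}

# --- I/O -------------------------------------------------------------------

#' Write a vessel graph as SWC plus table sidecars
#'
#' Writes one SWC file per connected component (spanning tree; SWC cannot
#' encode cycles, so off-tree closures are listed in the JSON sidecar),
#' \code{nodes.csv}, \code{segments.csv} and \code{polylines.json}.
#'
#' @param g a \code{vessel_graph}.
#' @param dir output directory (created if missing).
#' @param stem file-name stem for SWC files.
#' @return character vector of written paths, invisibly.
#' @export
write_graph_files <- function(g, dir, stem = "graph") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  nodes <- g$nodes
  deg <- node_degrees(g)
  nodes$degree <- as.integer(deg[as.character(nodes$id)])
  p <- file.path(dir, "nodes.csv")
  utils::write.csv(nodes, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "segments.csv")
  utils::write.csv(
    g$segments[, c("id", "node_a", "node_b", "length_um", "mean_radius_um")],
    p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "polylines.json")
  pl <- lapply(seq_len(nrow(g$segments)), function(i)
    list(segment = g$segments$id[i],
         points = unname(apply(g$polylines[[i]], 1, as.numeric, simplify = FALSE)),
         radii_um = as.numeric(g$radii[[i]])))
  jsonlite::write_json(pl, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  # SWC per component: each polyline point becomes an SWC sample
  comp <- graph_components(g)
  if (length(comp)) {
    extra <- list()
    for (cc in sort(unique(comp))) {
      segs <- which(g$segments$node_a %in% names(comp)[comp == cc] |
                    g$segments$node_b %in% names(comp)[comp == cc])
      swc <- .swc_component(g, segs)
      f <- file.path(dir, sprintf("%s_c%03d.swc", stem, cc))
      writeLines(c("# SWC export (radius in um); cycles listed in polylines.json",
                   swc$lines), f)
      paths <- c(paths, f)
      if (length(swc$closures)) extra[[length(extra) + 1]] <- swc$closures
    }
  }
  invisible(paths)
}

# Build SWC lines for a set of segment rows via BFS spanning tree.
.swc_component <- function(g, segs) {
  lines <- character(0)
  counter <- 0L
  node_sample <- new.env()
  visited <- rep(FALSE, length(segs))
  closures <- list()
  emit <- function(x, y, z, r, parent) {
    counter <<- counter + 1L
    lines <<- c(lines, sprintf("%d 3 %.4f %.4f %.4f %.4f %d",
                               counter, x, y, z, r, parent))
    counter
  }
  repeat {
    start <- which(!visited)[1]
    if (is.na(start)) break
    queue <- list(list(seg = segs[start], from = g$segments$node_a[segs[start]]))
    visited[start] <- TRUE
    while (length(queue)) {
      item <- queue[[1]]; queue <- queue[-1]
      si <- item$seg
      pl <- g$polylines[[si]]; rr <- g$radii[[si]]
      a <- g$segments$node_a[si]; b <- g$segments$node_b[si]
      if (item$from == b && a != b) {
        pl <- pl[nrow(pl):1, , drop = FALSE]; rr <- rev(rr)
        tmp <- a; a <- b; b <- tmp
      }
      akey <- as.character(a); bkey <- as.character(b)
      parent <- if (!is.null(node_sample[[akey]])) node_sample[[akey]] else -1L
      if (parent == -1L) {
        parent <- emit(pl[1, 1], pl[1, 2], pl[1, 3], rr[1], -1L)
        node_sample[[akey]] <- parent
      }
      n <- nrow(pl)
      if (!is.null(node_sample[[bkey]]) && bkey != akey) {
        closures[[length(closures) + 1]] <- g$segments$id[si]
      }
      for (i in seq(2, length.out = max(0, n - 1))) {
        parent <- emit(pl[i, 1], pl[i, 2], pl[i, 3], rr[min(i, length(rr))], parent)
      }
      if (is.null(node_sample[[bkey]])) node_sample[[bkey]] <- parent
      # enqueue unvisited segments incident to b
      inc <- which((g$segments$node_a == b | g$segments$node_b == b))
      for (j in seq_along(segs)) {
        if (!visited[j] && segs[j] %in% inc) {
          visited[j] <- TRUE
          queue[[length(queue) + 1]] <- list(seg = segs[j], from = b)
        }
      }
    }
  }
  list(lines = lines, closures = closures)
}

#' Read an SWC morphology file as a vessel graph
#'
#' Degree-2 chains are collapsed into segments; sample radii become
#' per-point radii.
#'
#' @param path SWC file.
#' @return a \code{vessel_graph}.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r",
                                         "parent"))
  if (!nrow(tab)) return(vessel_graph())
  pts <- as.matrix(tab[, c("x", "y", "z")])
  rownames(pts) <- tab$id
  edges <- tab[tab$parent > 0, c("id", "parent")]
  deg <- integer(nrow(tab)); names(deg) <- as.character(tab$id)
  for (cn in c("id", "parent")) {
    t1 <- table(as.character(edges[[cn]]))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
  }
  .chains_to_graph(tab$id, pts, tab$r, edges, deg)
}

# Shared chain-walk: build a vessel_graph from point ids, positions,
# radii and an edge list, collapsing degree-2 runs.
.chains_to_graph <- function(ids, pts, radii, edges, deg) {
  id2i <- setNames(seq_along(ids), as.character(ids))
  adj <- vector("list", length(ids))
  for (k in seq_len(nrow(edges))) {
    a <- id2i[[as.character(edges[k, 1])]]
    b <- id2i[[as.character(edges[k, 2])]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  is_node <- deg != 2
  node_ids <- which(is_node)
  nodes <- data.frame(id = seq_along(node_ids),
                      x = pts[node_ids, 1], y = pts[node_ids, 2],
                      z = pts[node_ids, 3], kind = "interior",
                      stringsAsFactors = FALSE)
  pt2node <- setNames(nodes$id, as.character(node_ids))
  used <- matrix(FALSE, length(ids), max(1, max(deg)))
  segments <- data.frame(id = integer(), node_a = integer(), node_b = integer())
  polylines <- list(); rads <- list()
  sid <- 0L
  for (start in node_ids) {
    for (ei in seq_along(adj[[start]])) {
      if (used[start, ei]) next
      used[start, ei] <- TRUE
      path <- c(start)
      prev <- start
      cur <- adj[[start]][ei]
      repeat {
        path <- c(path, cur)
        if (is_node[cur]) {
          back <- which(adj[[cur]] == prev)
          used[cur, back[1]] <- TRUE
          break
        }
        nxt <- adj[[cur]][adj[[cur]] != prev][1]
        prev <- cur; cur <- nxt
      }
      sid <- sid + 1L
      segments <- rbind(segments, data.frame(
        id = sid, node_a = pt2node[[as.character(start)]],
        node_b = pt2node[[as.character(path[length(path)])]]))
      polylines[[sid]] <- pts[path, , drop = FALSE]
      rads[[sid]] <- radii[path]
    }
  }
  rownames(segments) <- NULL
  vessel_graph(nodes, segments, polylines, rads)
}
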