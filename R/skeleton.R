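# Skeletonization and skeleton-graph morphometry: centerline length, tip
# count, mean diameter, directionality.

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
mirror_lr <- function(m) m[, ncol(m):1, drop = FALSE]

# Zhang-Suen parallel thinning to a 1-px 8-connected skeleton, vectorised
# over matrix shifts. Input/output: 0/1 integer matrix.
zhang_suen <- function(v) {
  p <- v != 0
  # neighbour planes P2..P9 clockwise from north
  nb <- function(m) list(
    p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
    p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
    p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
    p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      n <- nb(p * 1)
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) A <- A + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
      if (phase == 1) {
        c1 <- n$p2 * n$p4 * n$p6 == 0
        c2 <- n$p4 * n$p6 * n$p8 == 0
      } else {
        c1 <- n$p2 * n$p4 * n$p8 == 0
        c2 <- n$p2 * n$p6 * n$p8 == 0
      }
      kill <- p & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(kill)) {
        p[kill] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  matrix(as.integer(p), nrow(p), ncol(p))
}

# Thin in a canonical orientation chosen over the dihedral group (4 rotations
# x optional left-right mirror) by hashing each candidate raster, then map the
# skeleton back. This makes the skeleton -- and hence length, tips, diameter --
# exactly equivariant under 90-degree rotations and mirroring, which parallel
# thinning alone does not guarantee.
thin_canonical <- function(v) {
  cands <- vector("list", 8)
  m <- v
  for (k in 0:3) {
    cands[[k + 1]] <- list(mat = m, rot = k, mir = FALSE)
    m <- rot90cw(m)
  }
  m <- mirror_lr(v)
  for (k in 0:3) {
    cands[[k + 5]] <- list(mat = m, rot = k, mir = TRUE)
    m <- rot90cw(m)
  }
  keys <- vapply(cands, function(cc)
    paste(dim(cc$mat)[1], dim(cc$mat)[2], rlang::hash(cc$mat)), character(1))
  best <- cands[[which.min(rank(keys, ties.method = "first"))]]
  s <- zhang_suen(best$mat)
  for (k in seq_len(best$rot)) s <- rot90ccw(s)
  if (best$mir) s <- mirror_lr(s)
  s
}

NB_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                    dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

empty_skeleton_graph <- function(h = 0L, w = 0L) {
  structure(list(
    nodes = tibble(id = integer(), row = integer(), col = integer(),
                   degree = integer(), radius = numeric()),
    edges = tibble(id = integer(), from = integer(), to = integer(),
                   chain = list(), length = numeric()),
    skeleton = matrix(0L, h, w),
    radius_map = matrix(0, h, w),
    crown_node = NA_integer_,
    mask_dim = c(h, w), mask_area = 0L),
    class = "skeleton_graph")
}

chain_length <- function(chain) {
  if (nrow(chain) < 2) return(0)
  steps <- abs(diff(chain))
  sum(ifelse(rowSums(steps) == 2, sqrt(2), 1))
}

#' Thin a root mask to a centerline skeleton graph
#'
#' The mask is thinned to a 1-pixel-wide 8-connected skeleton; skeleton
#' pixels with one neighbour become endpoint nodes, clusters of pixels with
#' three or more neighbours become junction nodes, and the 8-connected chains
#' between nodes become edges. Each node carries the local root radius, read
#' from the Euclidean distance transform of the mask. The crown node is the
#' node nearest the top-center of the root bounding box (the cutting's
#' attachment point).
#'
#' @param mask a [root_mask()].
#' @return A `skeleton_graph`: tibbles of nodes (0-based `row`, `col`,
#'   `degree`, `radius`) and edges (pixel `chain`s with diagonal-corrected
#'   `length`), plus the skeleton raster and per-pixel radius map. An empty
#'   mask yields an empty graph.
#' @export
skeletonize <- function(mask) {
  v <- mask$values
  h <- nrow(v); w <- ncol(v)
  if (sum(v) == 0) return(empty_skeleton_graph(h, w))
  skel <- thin_canonical(v)
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(v)))
  radius_map <- dt * skel

  # pad by 1 to drop bounds checks during tracing
  S <- matrix(FALSE, h + 2, w + 2)
  S[2:(h + 1), 2:(w + 1)] <- skel == 1L
  ncount <- matrix(0L, h + 2, w + 2)
  for (i in 1:8) {
    ncount <- ncount + shift_mat(S * 1L, NB_OFFSETS[i, 1], NB_OFFSETS[i, 2])
  }
  ncount[!S] <- 0L

  node_px <- S & (ncount != 2L)
  # junction clusters (>= 3 neighbours) merge into one node each
  node_id <- matrix(0L, h + 2, w + 2)
  jn <- S & ncount >= 3L
  n_nodes <- 0L
  if (any(jn)) {
    jlab <- label_components8(matrix(as.integer(jn), h + 2, w + 2))
    n_nodes <- max(jlab)
    node_id[jn] <- jlab[jn]
  }
  singles <- which(node_px & !jn)
  if (length(singles)) {
    node_id[singles] <- n_nodes + seq_along(singles)
    n_nodes <- n_nodes + length(singles)
  }

  # representative pixel per node: member nearest the member centroid
  node_rep <- matrix(0L, n_nodes, 2)
  if (n_nodes > 0) {
    idx <- which(node_id > 0, arr.ind = TRUE)
    ids <- node_id[node_id > 0]
    for (nid in seq_len(n_nodes)) {
      mem <- idx[ids == nid, , drop = FALSE]
      ctr <- colMeans(mem)
      d2 <- (mem[, 1] - ctr[1])^2 + (mem[, 2] - ctr[2])^2
      node_rep[nid, ] <- mem[which.min(d2), ]
    }
  }

  visited <- matrix(FALSE, h + 2, w + 2)   # consumed chain (non-node) pixels
  edges_from <- integer(); edges_to <- integer()
  chains <- list(); seen_nodepair <- character()

  neighbors_of <- function(r, c) {
    rr <- r + NB_OFFSETS[, 1]; cc <- c + NB_OFFSETS[, 2]
    on <- S[cbind(rr, cc)]
    cbind(rr[on], cc[on])
  }

  node_cells <- which(node_id > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(node_cells))) {
    r0 <- node_cells[i, 1]; c0 <- node_cells[i, 2]
    id0 <- node_id[r0, c0]
    nbs <- neighbors_of(r0, c0)
    for (j in seq_len(nrow(nbs))) {
      r1 <- nbs[j, 1]; c1 <- nbs[j, 2]
      id1 <- node_id[r1, c1]
      if (id1 > 0) {
        if (id1 != id0) {  # direct node-node adjacency
          key <- paste(min(id0, id1), max(id0, id1),
                       min((r0 - 1) * (w + 2) + c0, (r1 - 1) * (w + 2) + c1))
          if (!key %in% seen_nodepair) {
            seen_nodepair <- c(seen_nodepair, key)
            edges_from <- c(edges_from, id0); edges_to <- c(edges_to, id1)
            chains <- c(chains, list(rbind(c(r0, c0), c(r1, c1))))
          }
        }
        next
      }
      if (visited[r1, c1]) next
      # trace through degree-2 chain pixels until the next node pixel
      chain <- list(c(r0, c0), c(r1, c1))
      visited[r1, c1] <- TRUE
      pr <- r0; pc <- c0; cr <- r1; cc <- c1
      end_id <- NA_integer_
      repeat {
        nn <- neighbors_of(cr, cc)
        keep <- !(nn[, 1] == pr & nn[, 2] == pc)
        nn <- nn[keep, , drop = FALSE]
        if (nrow(nn) == 0) { end_id <- 0L; break }   # dead end (shouldn't happen)
        # prefer an unvisited continuation; chain pixels have exactly one
        nxt <- NULL
        for (q in seq_len(nrow(nn))) {
          if (node_id[nn[q, 1], nn[q, 2]] > 0) { nxt <- nn[q, ]; break }
        }
        if (is.null(nxt)) {
          for (q in seq_len(nrow(nn))) {
            if (!visited[nn[q, 1], nn[q, 2]]) { nxt <- nn[q, ]; break }
          }
        }
        if (is.null(nxt)) { end_id <- 0L; break }
        chain <- c(chain, list(nxt))
        if (node_id[nxt[1], nxt[2]] > 0) { end_id <- node_id[nxt[1], nxt[2]]; break }
        visited[nxt[1], nxt[2]] <- TRUE
        pr <- cr; pc <- cc; cr <- nxt[1]; cc <- nxt[2]
      }
      if (!is.na(end_id) && end_id > 0) {
        edges_from <- c(edges_from, id0); edges_to <- c(edges_to, end_id)
        chains <- c(chains, list(do.call(rbind, chain)))
      }
    }
  }

  # pure cycles: degree-2 pixels never visited and not nodes
  leftover <- which(S & !visited & node_id == 0L & ncount == 2L, arr.ind = TRUE)
  while (nrow(leftover) > 0) {
    r0 <- leftover[1, 1]; c0 <- leftover[1, 2]
    n_nodes <- n_nodes + 1L
    node_id[r0, c0] <- n_nodes
    node_rep <- rbind(node_rep, c(r0, c0))
    nbs <- neighbors_of(r0, c0)
    chain <- list(c(r0, c0), nbs[1, ])
    visited[nbs[1, 1], nbs[1, 2]] <- TRUE
    pr <- r0; pc <- c0; cr <- nbs[1, 1]; cc <- nbs[1, 2]
    repeat {
      nn <- neighbors_of(cr, cc)
      keep <- !(nn[, 1] == pr & nn[, 2] == pc)
      nn <- nn[keep, , drop = FALSE]
      if (nrow(nn) == 0) break
      nxt <- nn[1, ]
      chain <- c(chain, list(nxt))
      if (node_id[nxt[1], nxt[2]] == n_nodes) break
      visited[nxt[1], nxt[2]] <- TRUE
      pr <- cr; pc <- cc; cr <- nxt[1]; cc <- nxt[2]
    }
    edges_from <- c(edges_from, n_nodes); edges_to <- c(edges_to, n_nodes)
    chains <- c(chains, list(do.call(rbind, chain)))
    leftover <- which(S & !visited & node_id == 0L, arr.ind = TRUE)
    leftover <- leftover[ncount[leftover[, , drop = FALSE]] == 2L, , drop = FALSE]
  }

  deg <- tabulate(c(edges_from, edges_to), nbins = max(n_nodes, 1L))
  # 0-based original coordinates (strip padding, shift to 0-base)
  chains0 <- lapply(chains, function(ch) ch - 2L)
  lens <- vapply(chains0, chain_length, numeric(1))
  nodes <- tibble(
    id = seq_len(n_nodes),
    row = as.integer(node_rep[seq_len(n_nodes), 1] - 2L),
    col = as.integer(node_rep[seq_len(n_nodes), 2] - 2L),
    degree = as.integer(deg[seq_len(n_nodes)]),
    radius = dt[cbind(node_rep[seq_len(n_nodes), 1] - 1L,
                      node_rep[seq_len(n_nodes), 2] - 1L)])
  edges <- tibble(id = seq_along(chains0), from = edges_from, to = edges_to,
                  chain = chains0, length = lens)

  crown <- NA_integer_
  if (nrow(nodes) > 0) {
    bb <- mask_bbox(mask)
    tc_row <- bb["min_row"]; tc_col <- (bb["min_col"] + bb["max_col"]) / 2
    ends <- nodes[nodes$degree <= 1, , drop = FALSE]
    pool <- if (nrow(ends) > 0) ends else nodes
    d2 <- (pool$row - tc_row)^2 + (pool$col - tc_col)^2
    crown <- pool$id[which.min(d2)]
  }

  structure(list(nodes = nodes, edges = edges, skeleton = skel,
                 radius_map = radius_map, crown_node = crown,
                 mask_dim = c(h, w), mask_area = sum(v)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph: %d nodes, %d edges, length %.1f px>\n",
              nrow(x$nodes), nrow(x$edges), measure_length(x)))
  invisible(x)
}

#' Total skeleton length
#'
#' Sum over edge chains of per-step lengths: 1 for a 4-neighbour step and
#' `sqrt(2)` for a diagonal step.
#'
#' @param graph a `skeleton_graph`.
#' @return Length in pixels (0 for an empty graph).
#' @export
measure_length <- function(graph) {
  if (nrow(graph$edges) == 0) return(0)
  sum(graph$edges$length)
}

#' Count root tips (skeleton endpoints)
#'
#' Counts degree-1 nodes. With `exclude_crown` the endpoint nearest the
#' top-center of the root bounding box — the cutting's attachment, not a
#' biological root tip — is excluded.
#'
#' @param graph a `skeleton_graph`.
#' @param exclude_crown drop the crown endpoint (default `TRUE`).
#' @return Integer tip count.
#' @export
count_tips <- function(graph, exclude_crown = TRUE) {
  ends <- graph$nodes[graph$nodes$degree == 1, , drop = FALSE]
  n <- nrow(ends)
  if (n == 0) return(0L)
  if (exclude_crown && !is.na(graph$crown_node) &&
      graph$crown_node %in% ends$id) {
    n <- n - 1L
  }
  as.integer(n)
}

#' Mean root diameter along the skeleton
#'
#' Mean over all skeleton pixels of `2 * r - 1` where `r` is the Euclidean
#' distance-transform value of the mask at that pixel, floored at 1 so that
#' a 1-px-wide structure reports diameter 1.
#'
#' @param graph a `skeleton_graph`.
#' @return Mean diameter in pixels.
#' @export
mean_diameter <- function(graph) {
  px <- graph$radius_map[graph$skeleton == 1L]
  if (length(px) == 0) {
    abort("cannot measure diameter of an empty skeleton",
          class = "rhizo_measurement_error")
  }
  mean(pmax(2 * px - 1, 1))
}

#' Mean direction of root segments
#'
#' Each edge chain is split into straight sub-segments every `k` chain pixels
#' (and at nodes); each sub-segment contributes its absolute angle from the
#' downward vertical, in `[0, 90]` degrees, weighted by its Euclidean length.
#'
#' @param graph a `skeleton_graph`.
#' @param k sub-segment step in chain pixels (default 5; raw per-pixel angles
#'   are quantized to multiples of 45 degrees, so a coarser step is used).
#' @return Length-weighted mean angle in degrees.
#' @export
directionality <- function(graph, k = 5L) {
  if (nrow(graph$edges) == 0) {
    abort("cannot measure directionality of a graph with no edges",
          class = "rhizo_measurement_error")
  }
  angs <- numeric(); wts <- numeric()
  for (ch in graph$edges$chain) {
    n <- nrow(ch)
    if (n < 2) next
    cuts <- unique(c(seq(1, n, by = k), n))
    if (length(cuts) < 2) next
    p <- ch[cuts[-length(cuts)], , drop = FALSE]
    q <- ch[cuts[-1], , drop = FALSE]
    dr <- q[, 1] - p[, 1]; dc <- q[, 2] - p[, 2]
    len <- sqrt(dr^2 + dc^2)
    ok <- len > 0
    angs <- c(angs, atan2(abs(dc[ok]), abs(dr[ok])) * 180 / pi)
    wts <- c(wts, len[ok])
  }
  if (!length(wts)) return(0)
  sum(angs * wts) / sum(wts)
}

#' Export a skeleton graph as JSON
#'
#' @param graph a `skeleton_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_skeleton_json <- function(graph, path) {
  obj <- list(
    nodes = graph$nodes,
    edges = list(from = graph$edges$from, to = graph$edges$to,
                 length = graph$edges$length,
                 chain = lapply(graph$edges$chain, unname)),
    crown_node = graph$crown_node,
    mask_dim = graph$mask_dim)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
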