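# Zhang-Suen morphological thinning. No installed R package exposes binary
# skeletonization, so the classic two-subiteration algorithm is implemented
# here, vectorised over the whole (padded) image.

zhang_suen_thin <- function(mask, max_iter = 1000) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  ri <- 2:(h + 1); ci <- 2:(w + 1)

  neighbours <- function(p) {
    # clockwise from north: P2..P9
    list(
      p2 = p[ri - 1, ci], p3 = p[ri - 1, ci + 1], p4 = p[ri, ci + 1],
      p5 = p[ri + 1, ci + 1], p6 = p[ri + 1, ci], p7 = p[ri + 1, ci - 1],
      p8 = p[ri, ci - 1], p9 = p[ri - 1, ci - 1]
    )
  }

  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighbours(pad)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      A <- matrix(0L, h, w)
      for (k in 1:8) {
        A <- A + as.integer(seqs[[k]] == 0 & seqs[[k + 1]] == 1)
      }
      if (sub == 1) {
        c1 <- nb$p2 * nb$p4 * nb$p6 == 0
        c2 <- nb$p4 * nb$p6 * nb$p8 == 0
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8 == 0
        c2 <- nb$p2 * nb$p6 * nb$p8 == 0
      }
      del <- pad[ri, ci] == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        core <- pad[ri, ci]
        core[del] <- 0L
        pad[ri, ci] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[ri, ci] == 1
}

# Ordered path through a skeleton: build the 8-connected pixel graph and take
# its weighted diameter path (longest shortest path between endpoints). Side
# spurs shorter than the main path are bypassed automatically, which acts as
# spur pruning. Returns an n x 2 matrix of (x, y) or NULL when no usable path
# exists.
skeleton_path <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 3) return(NULL)
  h <- nrow(skel)
  ys <- ((idx - 1) %% h) + 1
  xs <- ((idx - 1) %/% h) + 1
  n <- length(idx)
  key <- ys + (xs - 1) * h
  lookup <- integer(max(key))
  lookup[key] <- seq_len(n)

  edges <- NULL; weights <- NULL
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    nx <- xs + shifts[s, 1]; ny <- ys + shifts[s, 2]
    ok <- nx >= 1 & nx <= ncol(skel) & ny >= 1 & ny <= h
    nk <- ny[ok] + (nx[ok] - 1) * h
    present <- nk <= length(lookup) & lookup[pmin(nk, length(lookup))] > 0
    from <- seq_len(n)[ok][present]
    to <- lookup[nk[present]]
    if (length(from)) {
      edges <- rbind(edges, cbind(from, to))
      weights <- c(weights, rep(sqrt(sum(shifts[s, ]^2)), length(from)))
    }
  }
  if (is.null(edges)) return(NULL)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = weights)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vs <- which(comp$membership == main)
  deg <- igraph::degree(g)
  ends <- vs[deg[vs] <= 1]
  if (length(ends) < 2) ends <- vs  # loop: fall back to all vertices
  if (length(ends) > 12) {
    # distance-based heuristic: keep the pair candidates far apart
    d0 <- igraph::distances(g, v = ends[1], to = ends)[1, ]
    ends <- ends[order(d0, decreasing = TRUE)][1:12]
  }
  dmat <- igraph::distances(g, v = ends, to = ends)
  dmat[!is.finite(dmat)] <- -1
  pk <- arrayInd(which.max(dmat), dim(dmat))
  p <- igraph::shortest_paths(g, from = ends[pk[1]], to = ends[pk[2]],
                              output = "vpath")$vpath[[1]]
  p <- as.integer(p)
  if (length(p) < 3) return(NULL)
  cbind(x = xs[p], y = ys[p])
}

#' Extract the vessel centreline of a patch mask
#'
#' Fig.-style centreline extraction: the patch mask is thinned to a 1-pixel
#' skeleton (Zhang-Suen), and the longest end-to-end path through the
#' skeleton graph is returned in order — short side-spurs are bypassed, so
#' the path length is unchanged by small segmentation warts. Only a path
#' passing near the patch centre is accepted; `trim` pixels are dropped from
#' each end, where thinning artefacts concentrate.
#'
#' @param patch_mask Logical (or 0/1) matrix containing one vessel segment
#'   crossing the patch.
#' @param trim Pixels discarded at each path end (default 5).
#' @param max_center_dist Maximum allowed distance (pixels) between the patch
#'   centre and the nearest path pixel; `Inf` disables the check.
#' @return `n x 2` matrix of ordered (x, y) centreline coordinates, or `NULL`
#'   when no dominant path exists (the measurement point is then skipped).
#' @export
centerline <- function(patch_mask, trim = 5, max_center_dist = 24) {
  if (inherits(patch_mask, "Image")) patch_mask <- EBImage::imageData(patch_mask)
  mask <- patch_mask > 0.5
  if (!any(mask)) return(NULL)
  skel <- zhang_suen_thin(mask)
  path <- skeleton_path(skel)
  if (is.null(path)) return(NULL)
  if (nrow(path) > 2 * trim + 5) {
    path <- path[(trim + 1):(nrow(path) - trim), , drop = FALSE]
  }
  if (is.finite(max_center_dist)) {
    cx <- (ncol(mask) + 1) / 2; cy <- (nrow(mask) + 1) / 2
    dmin <- min(sqrt((path[, 1] - cx)^2 + (path[, 2] - cy)^2))
    if (dmin > max_center_dist) return(NULL)
  }
  path
}
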