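## Binary-image morphology used by segmentation and arch extraction:
## 8-connected component labeling, similarity scaling of a region about its
## centroid ("magnification"), and Zhang-Suen thinning for centerlines.

## 8-connected labeling of a logical matrix; labels are renumbered in raster
## order of each component's first pixel (column-major, as stored).
.labelComponents <- function(m) {
  stopifnot(is.logical(m))
  lab <- matrix(0L, nrow(m), ncol(m))
  fg <- which(m)
  if (!length(fg)) return(lab)
  id <- integer(length(m)); id[fg] <- seq_along(fg)
  nr <- nrow(m)
  ii <- ((fg - 1L) %% nr) + 1L
  jj <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= ncol(m)
    nidx <- (nj[ok] - 1L) * nr + ni[ok]
    hit <- m[nidx]
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok][hit]], id[nidx[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  ## renumber by first occurrence in raster order
  first <- !duplicated(memb)
  renum <- integer(max(memb)); renum[memb[first]] <- seq_len(sum(first))
  lab[fg] <- renum[memb]
  lab
}

#' Keep only the largest 8-connected component
#'
#' Retains the largest 8-connected foreground component of a binary image;
#' area ties are broken toward the component whose first pixel comes first
#' in storage (raster) order. An empty image is returned unchanged.
#'
#' @param img a [BinaryImage2D-class] (or plain logical matrix)
#' @return object of the same type with one component retained
#' @export
largestComponent <- function(img) {
  m <- if (is(img, "BinaryImage2D")) img@data else img
  lab <- .labelComponents(m)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)  # first max = smallest raster-order label
    m <- lab == keep
  }
  if (is(img, "BinaryImage2D")) {
    img@data <- m
    img
  } else m
}

## similarity scaling of a binary region by `factor` about `center`
## (fractional 1-based pixel coordinates; default the region centroid),
## rasterized by inverse nearest-neighbour mapping.
.magnifyRegion <- function(m, factor, center = NULL) {
  stopifnot(is.logical(m), factor > 0)
  if (!any(m)) return(m)
  if (is.null(center)) {
    fg <- which(m)
    nr <- nrow(m)
    center <- c(mean(((fg - 1L) %% nr) + 1L), mean(((fg - 1L) %/% nr) + 1L))
  }
  ii <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  jj <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  si <- center[1] + (ii - center[1]) / factor
  sj <- center[2] + (jj - center[2]) / factor
  out <- .nearest(m, as.numeric(si), as.numeric(sj), fill = 0) > 0.5
  matrix(out, nrow(m), ncol(m))
}

## Zhang-Suen thinning: reduces a binary region to an 8-connected,
## unit-width skeleton.
.skeletonize <- function(m) {
  stopifnot(is.logical(m))
  nr <- nrow(m); nc <- ncol(m)
  img <- matrix(0L, nr + 2, nc + 2)
  img[2:(nr + 1), 2:(nc + 1)] <- as.integer(m)
  shift <- function(a, di, dj) {
    out <- matrix(0L, nrow(a), ncol(a))
    ri <- seq_len(nrow(a)) - di; cj <- seq_len(ncol(a)) - dj
    okR <- ri >= 1 & ri <= nrow(a); okC <- cj >= 1 & cj <= ncol(a)
    out[okR, okC] <- a[ri[okR], cj[okC]]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      ## neighbours P2..P9 clockwise from north (row-1)
      p2 <- shift(img, -1, 0); p3 <- shift(img, -1, 1); p4 <- shift(img, 0, 1)
      p5 <- shift(img, 1, 1);  p6 <- shift(img, 1, 0);  p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1); p9 <- shift(img, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- img == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nr + 1), 2:(nc + 1)] == 1L
}

## Extract the dominant path of a skeleton: graph over skeleton pixels with
## 8-neighbour edges (Euclidean weights), main path = weighted diameter.
## Returns the ordered n x 2 pixel coordinates of the path plus diagnostics.
.skeletonPath <- function(sk, spurFraction = 0.05) {
  fg <- which(sk)
  if (length(fg) < 2L) stop("skeleton too small to trace")
  nr <- nrow(sk)
  ii <- ((fg - 1L) %% nr) + 1L
  jj <- ((fg - 1L) %/% nr) + 1L
  id <- integer(length(sk)); id[fg] <- seq_along(fg)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= ncol(sk)
    nidx <- (nj[ok] - 1L) * nr + ni[ok]
    hit <- sk[nidx]
    if (any(hit)) {
      from <- c(from, id[fg[ok][hit]])
      to <- c(to, id[nidx[hit]])
      w <- c(w, rep(sqrt(sum(off^2)), sum(hit)))
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(fg),
                          directed = FALSE)
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("disconnected mask: skeleton has ", comp$no, " components")
  ## prune spur branches shorter than `spurFraction` of the total length
  totalLen <- sum(igraph::E(g)$weight)
  repeat {
    deg <- igraph::degree(g)
    ends <- which(deg == 1L)
    drop <- integer(0)
    for (e in ends) {
      walk <- e; len <- 0; cur <- e; prev <- 0L
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nb) != 1L) break          # junction reached or isolated
        nxt <- nb
        if (igraph::degree(g, nxt) >= 3L) {  # branch ends at a junction
          len <- len + igraph::E(g)$weight[igraph::get_edge_ids(g, c(cur, nxt))]
          if (len < spurFraction * totalLen) drop <- c(drop, walk)
          break
        }
        len <- len + igraph::E(g)$weight[igraph::get_edge_ids(g, c(cur, nxt))]
        if (len >= spurFraction * totalLen) break
        walk <- c(walk, nxt); prev <- cur; cur <- nxt
      }
    }
    drop <- unique(drop)
    if (!length(drop)) break
    keepIds <- setdiff(seq_len(igraph::vcount(g)), drop)
    g <- igraph::induced_subgraph(g, keepIds)
    ii <- ii[keepIds]; jj <- jj[keepIds]
  }
  d1 <- igraph::distances(g, v = 1)
  e1 <- which.max(d1)
  d2 <- igraph::distances(g, v = e1)
  e2 <- which.max(d2)
  vp <- igraph::shortest_paths(g, from = e1, to = e2)$vpath[[1]]
  vp <- as.integer(vp)
  ## residual branch depth: how far any remaining skeleton pixel strays
  ## from the main path (thinning leaves 1-px staircase duplicates; real
  ## side branches stray much farther)
  off <- setdiff(seq_along(ii), vp)
  offDepth <- 0
  nBranches <- 0L
  if (length(off)) {
    d2path <- sapply(off, function(v)
      sqrt(min((ii[v] - ii[vp])^2 + (jj[v] - jj[vp])^2)))
    offDepth <- max(d2path)
    sub <- igraph::induced_subgraph(g, off)
    nBranches <- igraph::components(sub)$no
  }
  list(path = cbind(ii[vp], jj[vp]),
       pathLength = d2[e2],
       nPixels = length(ii),
       offDepth = offDepth,
       nBranches = nBranches)
}
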