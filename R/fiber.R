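#' @title Fiber-length measurement
#' @description Length of elongated (fibrous) microdomain structures from
#'   a binary mask: each 8-connected component is thinned to a one-pixel
#'   skeleton (Zhang-Suen), and the skeleton's path length is the sum of
#'   inter-pixel steps (1 pixel for orthogonal, sqrt(2) for diagonal)
#'   scaled by the physical pixel size. Step double-counting through
#'   redundant diagonal adjacencies is avoided by summing over a minimum
#'   spanning tree of the skeleton's 8-neighbor graph.
#' @name fiber-length
NULL

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  mask <- as.matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- cl + offs[k, 2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# shifted copies of a 0/1 matrix for the 8 neighbors (zero-padded)
.neighbor_stack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  shift <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr),
                                (2L + dc):(nc + 1L + dc)]
  # Zhang-Suen neighbor order: p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW
  list(p2 = shift(-1L, 0L), p3 = shift(-1L, 1L), p4 = shift(0L, 1L),
       p5 = shift(1L, 1L), p6 = shift(1L, 0L), p7 = shift(1L, -1L),
       p8 = shift(0L, -1L), p9 = shift(-1L, -1L))
}

#' Zhang-Suen morphological thinning
#'
#' Iteratively deletes boundary pixels until the mask is a one-pixel-wide
#' skeleton. One-pixel-wide input lines are preserved unchanged.
#'
#' @param mask logical matrix.
#' @return logical matrix: the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(as.matrix(mask)),
              ncol(as.matrix(mask)))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- .neighbor_stack(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      # A = number of 0 -> 1 transitions in the p2..p9,p2 cycle
      A <- (nb$p2 == 0L & nb$p3 == 1L) + (nb$p3 == 0L & nb$p4 == 1L) +
        (nb$p4 == 0L & nb$p5 == 1L) + (nb$p5 == 0L & nb$p6 == 1L) +
        (nb$p6 == 0L & nb$p7 == 1L) + (nb$p7 == 0L & nb$p8 == 1L) +
        (nb$p8 == 0L & nb$p9 == 1L) + (nb$p9 == 0L & nb$p2 == 1L)
      if (step == 1L) {
        c3 <- nb$p2 * nb$p4 * nb$p6
        c4 <- nb$p4 * nb$p6 * nb$p8
      } else {
        c3 <- nb$p2 * nb$p4 * nb$p8
        c4 <- nb$p2 * nb$p6 * nb$p8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c3 == 0L & c4 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Per-component fiber lengths from a binary mask
#'
#' Skeletonizes the mask and measures each 8-connected skeleton
#' component's path length: the sum of minimum-spanning-tree edge weights
#' over the skeleton pixel graph (orthogonal step 1 px, diagonal step
#' sqrt(2) px), converted to micrometres. A single-pixel component has
#' length 0.
#'
#' @param mask logical matrix of fiber pixels.
#' @param pixel_size_um physical pixel size (um).
#' @return numeric vector of per-component lengths (um); empty for an
#'   empty mask.
#' @export
fiber_length <- function(mask, pixel_size_um) {
  mask <- as.matrix(mask)
  if (!any(mask)) return(numeric(0))
  skel <- skeletonize(mask)
  lab <- label_components(skel)
  ncomp <- max(lab)
  nr <- nrow(skel)
  out <- numeric(ncomp)
  for (comp in seq_len(ncomp)) {
    idx <- which(lab == comp)
    if (length(idx) <= 1L) { out[comp] <- 0; next }
    r <- ((idx - 1L) %% nr) + 1L
    cl <- ((idx - 1L) %/% nr) + 1L
    # all 8-neighbor pairs among component pixels
    pairs <- which(outer(r, r, function(a, b) abs(a - b)) <= 1L &
                   outer(cl, cl, function(a, b) abs(a - b)) <= 1L,
                   arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    wts <- sqrt((r[pairs[, 1]] - r[pairs[, 2]])^2 +
                (cl[pairs[, 1]] - cl[pairs[, 2]])^2)
    g <- igraph::graph_from_edgelist(cbind(pairs[, 1], pairs[, 2]),
                                     directed = FALSE)
    igraph::E(g)$weight <- wts
    mst <- igraph::mst(g)
    out[comp] <- sum(igraph::E(mst)$weight) * pixel_size_um
  }
  out
}
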