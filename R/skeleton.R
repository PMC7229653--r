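## Zhang-Suen binary thinning and geodesic path lengths on the skeleton.
## Used by the sprout-length measurement; no installed package provides a
## skeletonization primitive.

# Zhang-Suen thinning of a logical matrix; returns a 1-pixel-wide skeleton.
thinSkeleton <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nbr <- function(p, dr, dc)
    p[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc, drop = FALSE]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- nbr(pad, -1, 0); p3 <- nbr(pad, -1, 1); p4 <- nbr(pad, 0, 1)
      p5 <- nbr(pad, 1, 1);  p6 <- nbr(pad, 1, 0);  p7 <- nbr(pad, 1, -1)
      p8 <- nbr(pad, 0, -1); p9 <- nbr(pad, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      core <- pad[2:(nr + 1), 2:(nc + 1)] & bsum >= 2 & bsum <= 6 & a == 1
      del <- if (step == 1) {
        core & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        core & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(nr + 1), 2:(nc + 1)]
        inner[del] <- FALSE
        pad[2:(nr + 1), 2:(nc + 1)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)]
}

# 8-connected pixel graph of a skeleton; nodes are skeleton pixels, edges
# weighted 1 (axial) or sqrt(2) (diagonal).
skeletonGraph <- function(skel) {
  idx <- which(skel)
  if (!length(idx))
    return(list(graph = NULL, idx = idx))
  nr <- nrow(skel)
  id <- match(seq_len(length(skel)), idx)  # pixel -> node id or NA
  edges <- integer(0); weights <- numeric(0)
  offs <- list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skel)
    tgt <- (c2[ok] - 1) * nr + r2[ok]
    hit <- !is.na(id[tgt])
    from <- id[idx[ok][hit]]
    to <- id[tgt[hit]]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(o[3], length(from)))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- weights
  list(graph = g, idx = idx, row = rr, col = cc)
}
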