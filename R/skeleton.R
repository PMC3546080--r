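#' Topology-preserving skeletonisation
#'
#' Reduces the segmented fibre mask to its one-pixel-wide medial axis by
#' iterative two-subcycle boundary thinning with an explicit topology audit.
#' Each subcycle marks Zhang-Suen-style deletion candidates (boundary pixels
#' with 2-6 neighbours, a single 0-1 transition around the pixel, and the
#' subcycle's directional condition) and removes them in parallel. Parallel
#' removal of such candidates almost always preserves topology, but has
#' known failure patterns (isolated 2x2 blocks, two-pixel-wide diagonal
#' ribbons), so after every batch the number of 8-connected foreground
#' components and 4-connected background components is re-counted; if either
#' changed, the batch is rolled back and replayed pixel-by-pixel in raster
#' order, deleting a pixel only if it is still exactly 8-simple (Yokoi
#' connectivity number 1) and still satisfies the subcycle conditions in the
#' current image. The result is strictly topology-preserving: skeleton
#' components match mask components and no hole is created or destroyed.
#'
#' The image is padded with one background ring during iteration (cropped
#' afterwards) so border pixels thin normally while border-crossing stubs
#' survive. The procedure is deterministic and idempotent: a stable skeleton
#' contains no removable pixel, so re-skeletonising returns it unchanged.
#'
#' @name skeleton
NULL

# ring order of the 8 neighbours: N, NE, E, SE, S, SW, W, NW
RING <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
              dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# neighbour planes (P), neighbour count (B) and 0->1 transition count (A),
# vectorized over the whole matrix
ring_stats <- function(m) {
  P <- vector("list", 8L)
  for (k in 1:8) P[[k]] <- shift_mat(m, -RING[k, 1], -RING[k, 2])
  B <- Reduce(`+`, P)
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) {
    nxt <- if (k == 8L) 1L else k + 1L
    A <- A + (P[[k]] == 0L & P[[nxt]] == 1L)
  }
  list(A = A, B = B, P = P)
}

# Yokoi connectivity number for the (8-foreground, 4-background) pairing at
# one pixel of the padded matrix; C == 1 iff the pixel is 8-simple
# (verified exhaustively against the component-counting definition over all
# 256 neighbourhood configurations). v is the ring N,NE,E,SE,S,SW,W,NW.
yokoi_number <- function(v) {
  x <- v[c(3, 2, 1, 8, 7, 6, 5, 4)]   # reorder to E,NE,N,NW,W,SW,S,SE
  xb <- 1L - x
  C <- 0L
  for (k in c(1L, 3L, 5L, 7L)) {
    k2 <- if (k == 7L) 8L else k + 1L
    k3 <- if (k == 7L) 1L else k + 2L
    C <- C + xb[k] - xb[k] * xb[k2] * xb[k3]
  }
  C
}

ring_values <- function(m, r, c) {
  c(m[r - 1, c], m[r - 1, c + 1], m[r, c + 1], m[r + 1, c + 1],
    m[r + 1, c], m[r + 1, c - 1], m[r, c - 1], m[r - 1, c - 1])
}

# number of 8-connected foreground components
count_fg_components <- function(m) {
  if (sum(m) == 0L) return(0L)
  max(label_binary(m))
}

# number of 4-connected background components (m already carries a
# background pad ring, so the outside counts once)
count_bg_components <- function(m) {
  bg <- which(m == 0L)
  idx <- matrix(0L, nrow(m), ncol(m))
  idx[bg] <- seq_along(bg)
  edges <- NULL
  for (k in list(c(0, 1), c(1, 0))) {
    nb <- shift_mat(idx, k[1], k[2])
    both <- bg[nb[bg] > 0L]
    if (length(both)) edges <- rbind(edges, cbind(idx[both], nb[both]))
  }
  g <- igraph::make_empty_graph(n = length(bg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# one thinning run on a padded work matrix; returns the thinned matrix.
# 2-neighbour candidates (line tips whose neighbours form an adjacent
# pair) may only be deleted during the first `b2_iters` iterations: they
# are needed to resolve stroke-width thickness, but in later iterations
# they would let staircase line ends recede indefinitely.
thin_work <- function(m, b2_iters = 2L) {
  n_fg <- count_fg_components(m)
  n_bg <- count_bg_components(m)
  iter <- 0L
  repeat {
    changed <- FALSE
    iter <- iter + 1L
    bmin <- if (iter <= b2_iters) 2L else 3L
    for (sub in 1:2) {
      s <- ring_stats(m)
      P <- s$P
      if (sub == 1L) {
        cond <- P[[1]] * P[[3]] * P[[5]] == 0L & P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        cond <- P[[1]] * P[[3]] * P[[7]] == 0L & P[[1]] * P[[5]] * P[[7]] == 0L
      }
      cand <- which(m == 1L & s$B >= bmin & s$B <= 6L & s$A == 1L & cond)
      if (length(cand) == 0L) next
      msave <- m
      m[cand] <- 0L
      if (count_fg_components(m) != n_fg || count_bg_components(m) != n_bg) {
        # rare parallel-deletion failure: replay this batch sequentially,
        # re-verifying exact simplicity and the subcycle conditions per pixel
        m <- msave
        rr <- ((cand - 1L) %% nrow(m)) + 1L
        cc <- ((cand - 1L) %/% nrow(m)) + 1L
        for (i in order(rr, cc)) {
          v <- ring_values(m, rr[i], cc[i])
          B <- sum(v)
          if (B < bmin || B > 6L || yokoi_number(v) != 1L) next
          okdir <- if (sub == 1L)
            v[1] * v[3] * v[5] == 0L && v[3] * v[5] * v[7] == 0L
          else
            v[1] * v[3] * v[7] == 0L && v[1] * v[5] * v[7] == 0L
          if (okdir) m[rr[i], cc[i]] <- 0L
        }
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  m
}

# remove redundant staircase pixels the two-subcycle pass leaves behind:
# exactly-8-simple pixels (Yokoi number 1) with >= 3 neighbours, plus
# 2-neighbour simple pixels (elbows: their two neighbours are mutually
# adjacent) whose neighbours BOTH continue beyond the local triple.
# The continuation test is what distinguishes a removable elbow from the
# tip of a staircase line: deleting tips would let line ends recede
# indefinitely and eat fibre length. Every removal is of a simple pixel,
# so topology is untouched.
cleanup_redundant <- function(m) {
  nrm <- nrow(m)
  repeat {
    s <- ring_stats(m)
    cand <- which(m == 1L & s$B >= 2L)
    changed <- FALSE
    rr <- ((cand - 1L) %% nrm) + 1L
    cc <- ((cand - 1L) %/% nrm) + 1L
    for (i in order(rr, cc)) {
      v <- ring_values(m, rr[i], cc[i])
      B <- sum(v)
      if (B < 2L || yokoi_number(v) != 1L) next
      if (B == 2L) {
        ks <- which(v == 1L)
        nb <- cand[i] + RING[ks, 2] * nrm + RING[ks, 1]
        triple <- c(cand[i], nb)
        continues <- vapply(nb, function(q) {
          qr <- ((q - 1L) %% nrm) + 1L
          qc <- ((q - 1L) %/% nrm) + 1L
          out <- q + RING[, 2] * nrm + RING[, 1]
          ok <- qr + RING[, 1] >= 1L & qr + RING[, 1] <= nrm &
                qc + RING[, 2] >= 1L & qc + RING[, 2] <= ncol(m)
          out <- out[ok]
          any(m[out] == 1L & !(out %in% triple))
        }, NA)
        if (sum(continues) == 1L) {
          # terminal 3-cycle cap: this pixel and the non-continuing
          # neighbour are interchangeable tips; keep the raster-smaller one
          q <- nb[!continues]
          keep_q <- c(((q - 1L) %% nrm) + 1L, ((q - 1L) %/% nrm) + 1L)
          here <- c(rr[i], cc[i])
          partner_terminal <- {
            out <- q + RING[, 2] * nrm + RING[, 1]
            ok <- keep_q[1] + RING[, 1] >= 1L & keep_q[1] + RING[, 1] <= nrm &
                  keep_q[2] + RING[, 2] >= 1L & keep_q[2] + RING[, 2] <= ncol(m)
            all(!(m[out[ok]] == 1L) | (out[ok] %in% triple))
          }
          if (!partner_terminal) next
          if (keep_q[1] > here[1] ||
              (keep_q[1] == here[1] && keep_q[2] > here[2])) next
        } else if (!all(continues)) {
          next
        }
      }
      m[cand[i]] <- 0L
      changed <- TRUE
    }
    if (!changed) break
  }
  m
}

# cleanup on an unpadded matrix: add a transient zero ring
cleanup_cropped <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mat
  cleanup_redundant(p)[2:(nr + 1L), 2:(nc + 1L)]
}

#' Skeletonise a segmented image
#'
#' @param img an [sbp_image].
#' @return object of class `sbp_skeleton`: list with `skeleton` (0/1 integer
#'   matrix of the same size as the mask), `pixel_pitch_um`, and
#'   `skeleton_pixels`.
#' @export
skeletonize <- function(img) {
  stopifnot(inherits(img, "sbp_image"))
  nr <- img$height_px; nc <- img$width_px
  mask <- img$mask
  work <- matrix(0L, nr + 2L, nc + 2L)
  work[2:(nr + 1L), 2:(nc + 1L)] <- mask
  skel <- cleanup_cropped(thin_work(work)[2:(nr + 1L), 2:(nc + 1L)])
  skel <- extend_border_stubs(skel, mask)
  structure(list(skeleton = skel,
                 pixel_pitch_um = img$pixel_pitch_um,
                 skeleton_pixels = sum(skel)),
            class = "sbp_skeleton")
}

# Thinning erodes the free end of a stroke by a few pixels, so the terminal
# of a fibre that crosses the image border comes to rest just inside the
# 1-px border band and would be misread as a nerve ending. Rebuild such
# stubs: walk outward from every near-border endpoint along its own fibre
# direction, through original mask foreground only, until the border is
# reached. The walk aborts on background, on contact with other skeleton
# pixels, or if the fibre does not point at the border, so fibres running
# parallel to the border are untouched; on an already-thin input the first
# outward step is background, so skeletonisation stays idempotent.
extend_border_stubs <- function(S, M, reach = 24L) {
  nr <- nrow(S); nc <- ncol(S)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- S
  B <- ring_stats(pad)$B[2:(nr + 1L), 2:(nc + 1L)]
  ends <- which(S == 1L & B == 1L)
  for (p in ends) {
    r <- ((p - 1L) %% nr) + 1L
    c <- ((p - 1L) %/% nr) + 1L
    db <- min(r - 1L, nr - r, c - 1L, nc - c)
    if (db == 0L || db > 20L) next
    # local fibre direction: walk back along the line up to 5 pixels
    prev <- p; cur <- p
    for (step in 1:5) {
      rr <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      nbs <- integer(0)
      for (k in 1:8) {
        r2 <- rr + RING[k, 1]; c2 <- cc + RING[k, 2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (S[q] == 1L && q != prev && q != cur) nbs <- c(nbs, q)
      }
      if (length(nbs) != 1L) break
      prev <- cur; cur <- nbs[1L]
    }
    if (cur == p) next
    tf <- c(r - (((cur - 1L) %% nr) + 1L),
            c - (((cur - 1L) %/% nr) + 1L))   # outward tangent
    if (all(tf == 0)) next
    # outward candidate steps, best-aligned first
    dots <- RING[, 1] * tf[1] + RING[, 2] * tf[2]
    cand_dirs <- order(-dots)
    cand_dirs <- cand_dirs[dots[cand_dirs] > 0]
    # the walk may only end on a border side the fibre points toward
    side_ok <- function(rr, cc)
      (rr == 1L && tf[1] < 0) || (rr == nr && tf[1] > 0) ||
      (cc == 1L && tf[2] < 0) || (cc == nc && tf[2] > 0)
    path <- integer(0)
    rr <- r; cc <- c
    ok <- FALSE
    for (step in seq_len(reach)) {
      moved <- FALSE
      for (k in cand_dirs) {
        r2 <- rr + RING[k, 1]; c2 <- cc + RING[k, 2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (M[q] != 1L || S[q] == 1L) next
        # no contact with unrelated skeleton pixels
        touch <- FALSE
        for (j in 1:8) {
          r3 <- r2 + RING[j, 1]; c3 <- c2 + RING[j, 2]
          if (r3 < 1L || r3 > nr || c3 < 1L || c3 > nc) next
          q2 <- (c3 - 1L) * nr + r3
          if (S[q2] == 1L && q2 != p && !(q2 %in% path)) { touch <- TRUE; break }
        }
        if (touch) next
        rr <- r2; cc <- c2
        path <- c(path, q)
        moved <- TRUE
        break
      }
      if (!moved) break
      if (side_ok(rr, cc)) { ok <- TRUE; break }
    }
    if (ok) S[path] <- 1L
  }
  S
}

#' Count medial-axis pixels
#'
#' @param skel an `sbp_skeleton`.
#' @return number of skeleton foreground pixels.
#' @export
skeleton_pixels <- function(skel) {
  stopifnot(inherits(skel, "sbp_skeleton"))
  sum(skel$skeleton)
}

#' Wrap an already-thin binary matrix as a skeleton
#'
#' Utility for building skeletons directly (tests, rotated inputs); the
#' matrix is taken as-is without thinning.
#'
#' @param mat 0/1 matrix assumed thin.
#' @param pixel_pitch_um calibration.
#' @export
as_skeleton <- function(mat, pixel_pitch_um = DEFAULT_PITCH_UM) {
  mat <- matrix(as.integer(mat != 0), nrow(mat), ncol(mat))
  structure(list(skeleton = mat, pixel_pitch_um = pixel_pitch_um,
                 skeleton_pixels = sum(mat)),
            class = "sbp_skeleton")
}

#' @export
print.sbp_skeleton <- function(x, ...) {
  cat(sprintf("<sbp_skeleton> %d x %d px, %d skeleton px\n",
              ncol(x$skeleton), nrow(x$skeleton), x$skeleton_pixels))
  invisible(x)
}
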