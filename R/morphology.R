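#' Stage-1 morphology: components, coverage and homogeneity
#'
#' Before skeletonisation the segmented mask is analysed as a set of
#' connected components, each interpreted as an individual nerve-fibre
#' network. Foreground uses 8-connectivity (diagonally touching nerve pixels
#' belong to the same fibre network), the standard pairing for thin
#' curvilinear structures.
#'
#' @name morphology
NULL

# shift a matrix by (dr, dc), padding with 0
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# offsets of the 8-neighbourhood
NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

# 8-connected labeling of a binary matrix via the pixel adjacency graph.
# Returns an integer matrix: 0 background, components labelled 1..n in order
# of first raster-scan (row-major) appearance.
label_binary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)                       # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  # undirected edges: each fg pixel to its E, S, SE, SW fg neighbours
  edges <- NULL
  for (k in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- shift_mat(idx, k[1], k[2])
    both <- fg[nb[fg] > 0L]
    if (length(both))
      edges <- rbind(edges, cbind(idx[both], nb[both]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # deterministic relabeling by first-encountered pixel in row-major order
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  raster_key <- (rr - 1L) * nc + cc
  first_seen <- tapply(raster_key, memb, min)
  new_id <- integer(length(first_seen))
  new_id[order(first_seen)] <- seq_along(first_seen)
  lab[fg] <- new_id[memb]
  lab
}

#' Label connected nerve-fibre networks
#'
#' Partitions the foreground into maximal 8-connected components. Labels are
#' assigned 1..n in order of each component's first pixel in a row-major
#' raster scan, so the labeling is deterministic.
#'
#' @param img an [sbp_image].
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `n_components`.
#' @export
label_components <- function(img) {
  stopifnot(inherits(img, "sbp_image"))
  lab <- label_binary(img$mask)
  list(labels = lab, n_components = max(lab))
}

#' Count nerve-fibre pixels
#'
#' @param img an [sbp_image].
#' @return number of foreground pixels.
#' @export
component_pixels <- function(img) {
  stopifnot(inherits(img, "sbp_image"))
  sum(img$mask)
}

#' Percentual nerve coverage of the image area
#'
#' @param img an [sbp_image].
#' @return coverage in percent, `100 * foreground / total pixels`.
#' @export
component_ratio <- function(img) {
  stopifnot(inherits(img, "sbp_image"))
  100 * sum(img$mask) / (img$width_px * img$height_px)
}

#' Homogeneity of nerve-pixel distribution
#'
#' Measures how uniformly the nerve pixels cover the field: the image is
#' divided into `tiles_per_axis^2` near-equal rectangular tiles (the last
#' tile per axis absorbs any remainder) and the population variance of the
#' per-tile foreground fractions is returned. A perfectly uniform coverage
#' (including the all-empty and all-full masks) gives 0; concentrating the
#' same pixel budget into fewer tiles increases the value.
#'
#' @param img an [sbp_image].
#' @param tiles_per_axis number of tiles along each axis (default 8).
#' @return population variance of per-tile coverage fractions (dimensionless,
#'   >= 0).
#' @export
homogeneity <- function(img, tiles_per_axis = 8L) {
  stopifnot(inherits(img, "sbp_image"))
  k <- as.integer(tiles_per_axis)
  if (k < 2L || k > min(img$width_px, img$height_px))
    stop("tiles_per_axis must be >= 2 and <= min(width, height)")
  nr <- img$height_px; nc <- img$width_px
  rbreak <- c(seq(0L, by = nr %/% k, length.out = k), nr)
  cbreak <- c(seq(0L, by = nc %/% k, length.out = k), nc)
  frac <- numeric(k * k)
  t <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      t <- t + 1L
      tile <- img$mask[(rbreak[i] + 1L):rbreak[i + 1L],
                       (cbreak[j] + 1L):cbreak[j + 1L], drop = FALSE]
      frac[t] <- mean(tile)
    }
  }
  mean((frac - mean(frac))^2)
}

#' Stage-1 metric bundle
#'
#' @param img an [sbp_image].
#' @param tiles_per_axis passed to [homogeneity()].
#' @return list with `component_pixels`, `component_ratio`, `n_components`
#'   and `homogeneity`.
#' @export
morpho_metrics <- function(img, tiles_per_axis = 8L) {
  list(component_pixels = component_pixels(img),
       component_ratio = component_ratio(img),
       n_components = label_components(img)$n_components,
       homogeneity = homogeneity(img, tiles_per_axis))
}
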