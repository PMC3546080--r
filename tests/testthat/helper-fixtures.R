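# fixtures and independent brute-force oracles used across the test files

# --- shape builders (0/1 matrices) -----------------------------------------

shape_bar <- function(nr = 10, nc = 54, rows = 4:6, cols = 3:52) {
  m <- matrix(0L, nr, nc); m[rows, cols] <- 1L; m
}

shape_T <- function() {
  m <- matrix(0L, 25, 25)
  m[12, 3:21] <- 1L
  m[13:22, 12] <- 1L
  m
}

shape_X <- function() {
  m <- matrix(0L, 21, 21)
  for (i in -8:8) { m[11 + i, 11 + i] <- 1L; m[11 + i, 11 - i] <- 1L }
  m
}

shape_ring <- function() {
  m <- matrix(0L, 21, 21)
  m[5, 5:15] <- 1L; m[15, 5:15] <- 1L; m[5:15, 5] <- 1L; m[5:15, 15] <- 1L
  skeletonize(sbp_image(m))$skeleton   # minimal 1-px loop
}

shape_disk <- function(radius, margin = 6) {
  n <- 2 * radius + 2 * margin + 1
  ctr <- (n + 1) / 2
  m <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n)
    if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) m[r, c] <- 1L
  m
}

rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# --- independent oracles ----------------------------------------------------

# recursive flood-fill connected-component count (8-connectivity)
oracle_n_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (r in 1:nr) for (c in 1:nc) {
    if (m[r, c] == 1L && !seen[r, c]) {
      n <- n + 1L
      stack <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr; c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              m[r2, c2] == 1L && !seen[r2, c2]) {
            seen[r2, c2] <- TRUE
            stack[[length(stack) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  n
}

# population variance of per-tile coverage, computed naively
oracle_homogeneity <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  rb <- c(seq(0, by = nr %/% k, length.out = k), nr)
  cb <- c(seq(0, by = nc %/% k, length.out = k), nc)
  f <- c()
  for (i in 1:k) for (j in 1:k)
    f <- c(f, mean(m[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]))
  mean((f - mean(f))^2)
}

# chain-code length of an ordered pixel path by per-step summation
oracle_path_length <- function(rows, cols, pitch) {
  s <- 0
  for (i in seq_len(length(rows) - 1)) {
    dr <- abs(rows[i + 1] - rows[i]); dc <- abs(cols[i + 1] - cols[i])
    s <- s + if (dr == 1 && dc == 1) sqrt(2) else 1
  }
  s * pitch
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# total degree of a graph (self-loops counted twice)
graph_degree_sum <- function(g) {
  length(g$edges$node1) * 0 + sum(tabulate(c(g$edges$node1, g$edges$node2),
                                           nbins = max(1, nrow(g$nodes))))
}

# pixel support of a graph: node clusters plus edge paths (deduplicated)
graph_pixel_support <- function(g) {
  unique(c(unlist(g$node_pixels), unlist(g$edge_paths)))
}

# small deterministic phantom set reused by property tests
make_phantoms <- function(seeds, n_fibres = 4, branch_prob = 0.6,
                          size = 192) {
  lapply(seeds, function(s)
    generate_phantom(phantom_spec(n_fibres = n_fibres,
                                  branch_prob = branch_prob, seed = s,
                                  width_px = size, height_px = size)))
}
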