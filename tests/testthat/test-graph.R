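test_that("pixel classification by neighbour count matches the node vocabulary", {
  # straight interior line: two ends, rest path
  m <- matrix(0L, 9, 30); m[5, 5:25] <- 1L
  px <- classify_pixels(as_skeleton(m))
  expect_equal(sum(px$class == "end"), 2)
  expect_equal(sum(px$class == "path"), 19)
  expect_false(any(px$border))

  # three-arm junction (arms west, north-east, south-east so that only the
  # centre has >= 3 neighbours): one junction pixel, three ends
  mY <- matrix(0L, 25, 25)
  mY[12, 2:12] <- 1L                                     # west arm
  for (i in 1:10) { mY[12 - i, 12 + i] <- 1L; mY[12 + i, 12 + i] <- 1L }
  pxT <- classify_pixels(as_skeleton(mY))
  expect_equal(sum(pxT$class == "junction"), 1)
  expect_equal(sum(pxT$class == "end"), 3)

  # full-width line: both terminals border-tagged
  m2 <- matrix(0L, 15, 30); m2[8, ] <- 1L
  px2 <- classify_pixels(as_skeleton(m2))
  ends <- px2[px2$class == "end", ]
  expect_equal(nrow(ends), 2)
  expect_true(all(ends$border))
})

test_that("canonical shapes build the expected graphs", {
  gT <- build_graph(as_skeleton(shape_T()))
  expect_equal(count_nodes(gT, "branch"), 1)
  expect_equal(count_nodes(gT, "endpoint"), 3)
  expect_equal(nrow(gT$edges), 3)

  gX <- build_graph(as_skeleton(shape_X()))
  expect_equal(count_nodes(gX, "branch"), 1)
  expect_equal(count_nodes(gX, "endpoint"), 4)
  expect_equal(nrow(gX$edges), 4)

  m <- matrix(0L, 20, 20); m[5, 3:17] <- 1L; m[15, 3:17] <- 1L
  g2 <- build_graph(as_skeleton(m))
  expect_equal(g2$n_components, 2)
  expect_equal(count_nodes(g2, "endpoint"), 4)
  expect_equal(count_nodes(g2, "branch"), 0)
  expect_equal(nrow(g2$edges), 2)

  mfull <- matrix(0L, 15, 30); mfull[8, ] <- 1L
  g3 <- build_graph(as_skeleton(mfull))
  expect_equal(count_nodes(g3, "connectivity"), 2)
  expect_equal(count_nodes(g3, "endpoint"), 0)
  expect_equal(nrow(g3$edges), 1)
})

test_that("a closed loop is one self-edge with no counted nodes", {
  g <- build_graph(as_skeleton(shape_ring()))
  expect_equal(count_nodes(g, "endpoint"), 0)
  expect_equal(count_nodes(g, "branch"), 0)
  expect_equal(count_nodes(g, "connectivity"), 0)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$node1, g$edges$node2)
  # the whole perimeter length is conserved in the single cycle edge
  expect_equal(total_length_um(g),
               sum(g$edges$n_orth + sqrt(2) * g$edges$n_diag) * DEFAULT_PITCH_UM)
  expect_error(count_nodes(g, "whatever"), "unknown")
})

test_that("handshake and skeleton-pixel conservation hold on phantoms", {
  for (ph in make_phantoms(11:16, size = 160)) {
    g <- build_graph(skeletonize(ph$image))
    expect_equal(graph_degree_sum(g), 2 * nrow(g$edges))
    expect_setequal(graph_pixel_support(g), which(g$skeleton == 1L))
  }
})

test_that("edge lengths follow the chain code and a step-sum oracle", {
  pitch <- DEFAULT_PITCH_UM
  m <- matrix(0L, 9, 51); m[5, 1:50] <- 1L
  g <- build_graph(as_skeleton(m, pitch))
  expect_equal(g$edges$length_um, 49 * pitch, tolerance = 1e-12)

  md <- matrix(0L, 52, 52); for (i in 1:50) md[i, i] <- 1L
  gd <- build_graph(as_skeleton(md, pitch))
  expect_equal(gd$edges$length_um, 49 * sqrt(2) * pitch, tolerance = 1e-12)

  # mixed path: compare against independent per-step summation
  set.seed(14)
  ph <- generate_phantom(phantom_spec(n_fibres = 2, seed = 5,
                                      width_px = 128, height_px = 128))
  g2 <- build_graph(skeletonize(ph$image))
  nr <- nrow(g2$skeleton)
  for (e in seq_len(nrow(g2$edges))) {
    path <- g2$edge_paths[[e]]
    expect_equal(g2$edges$length_um[e],
                 oracle_path_length(((path - 1) %% nr) + 1,
                                    ((path - 1) %/% nr) + 1,
                                    DEFAULT_PITCH_UM),
                 tolerance = 1e-9)
  }
})

test_that("tree topology relates endpoints, branch events and border crossings", {
  # for each tree component: edges = nodes - 1 and
  # terminals (endpoints + crossings) = branch-arm count + 2 - 2*branches
  for (ph in make_phantoms(21:26, size = 192)) {
    g <- build_graph(skeletonize(ph$image))
    tr <- ph$truth
    expect_equal(count_nodes(g, "endpoint") + count_nodes(g, "connectivity"),
                 tr$true_n_branches + 2 * (tr$true_n_fibres - 2 * tr$true_n_branches))
    expect_equal(nrow(g$edges), nrow(g$nodes) - g$n_components)
  }
})

test_that("rotating a skeleton by 90 degrees preserves counts and length", {
  for (s in c(31, 32)) {
    ph <- generate_phantom(phantom_spec(n_fibres = 3, branch_prob = 1,
                                        seed = s, width_px = 150,
                                        height_px = 150))
    sk <- skeletonize(ph$image)$skeleton
    g1 <- build_graph(as_skeleton(sk))
    g2 <- build_graph(as_skeleton(rot90(sk)))
    for (k in c("branch", "endpoint", "connectivity"))
      expect_equal(count_nodes(g2, k), count_nodes(g1, k))
    expect_equal(nrow(g2$edges), nrow(g1$edges))
    expect_equal(total_length_um(g2), total_length_um(g1), tolerance = 1e-9)
  }
})

test_that("spur pruning removes short whiskers and recomputes node types", {
  # a long line with a 2-px spur off its middle
  m <- matrix(0L, 15, 40)
  m[8, 5:35] <- 1L
  m[7, 20] <- 1L
  m[6, 20] <- 1L
  g <- build_graph(as_skeleton(m), min_segment_um = 2)
  expect_equal(count_nodes(g, "branch"), 0)
  expect_equal(count_nodes(g, "endpoint"), 2)
  expect_equal(nrow(g$edges), 1)
  # with pruning disabled the spur is a real branch
  g0 <- build_graph(as_skeleton(m), prune = FALSE)
  expect_equal(count_nodes(g0, "branch"), 1)
  expect_equal(count_nodes(g0, "endpoint"), 3)
  # isolated pixels disappear under pruning
  m2 <- matrix(0L, 10, 10); m2[5, 5] <- 1L
  expect_equal(nrow(build_graph(as_skeleton(m2))$nodes), 0)
  expect_equal(nrow(build_graph(as_skeleton(m2), prune = FALSE)$nodes), 1)
})

test_that("graph export writes a parseable edge list", {
  g <- build_graph(as_skeleton(shape_T()))
  p <- file.path(tempdir(), "graph.txt")
  write_graph_txt(g, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("^#", lines)), 2)
  expect_equal(length(lines), 2 + nrow(g$nodes) + nrow(g$edges))
  unlink(p)
})
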