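#' Synthetic nerve-plexus phantoms with exact ground truth
#'
#' Generates binary masks that emulate subbasal nerve plexus morphology:
#' roughly parallel fibres crossing the field with gentle sinusoidal
#' tortuosity, occasional branch events spawning a child fibre, and a
#' controllable stroke width. Fibres are smooth parametric curves; the truth
#' record carries their arc lengths (integrated from the generating curves
#' before rasterisation) and exact event counts, which is what makes the
#' phantoms usable as a validation oracle for the measurement pipeline.
#' Default presets enforce non-intersection by rejection sampling so that
#' the recorded topology is exact.
#'
#' @name synthetic
NULL

#' Phantom specification
#'
#' @param n_fibres number of primary fibres.
#' @param branch_prob probability that a fibre carries one branch event.
#' @param tortuosity_amp_um lateral sine amplitude in micrometres.
#' @param stroke_width_px odd stroke width in pixels.
#' @param width_px,height_px image size.
#' @param pixel_pitch_um calibration.
#' @param seed integer; fixes the full output bit-for-bit.
#' @param orientation_deg dominant fibre direction in degrees, or `NULL`
#'   for a random direction per phantom.
#' @param interior_end_prob probability that a fibre end stops inside the
#'   field (a true nerve ending) instead of crossing the border.
#' @param allow_intersections permit overlapping fibres (stress-test mode;
#'   ground-truth topology is no longer exact).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_fibres = 5L, branch_prob = 0.5,
                         tortuosity_amp_um = 8, stroke_width_px = 3L,
                         width_px = 384L, height_px = 384L,
                         pixel_pitch_um = DEFAULT_PITCH_UM, seed = 1L,
                         orientation_deg = NULL, interior_end_prob = 0.25,
                         allow_intersections = FALSE) {
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0,1]")
  if (interior_end_prob < 0 || interior_end_prob > 1)
    stop("interior_end_prob must be in [0,1]")
  if (stroke_width_px < 1L || stroke_width_px %% 2L == 0L)
    stop("stroke_width_px must be a positive odd integer")
  structure(list(n_fibres = as.integer(n_fibres), branch_prob = branch_prob,
                 tortuosity_amp_um = tortuosity_amp_um,
                 stroke_width_px = as.integer(stroke_width_px),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_pitch_um = pixel_pitch_um, seed = as.integer(seed),
                 orientation_deg = orientation_deg,
                 interior_end_prob = interior_end_prob,
                 allow_intersections = allow_intersections),
            class = "phantom_spec")
}

#' Group presets emulating the two study populations
#'
#' Returns phantom parameters whose expected measured fibre density on the
#' default 400x400 um field falls within the corresponding group's
#' literature range: dense, branching networks for `"healthy"` (around
#' 0.02 um/um^2) and sparse, depleted networks for `"neuropathic"` (around
#' 0.006 um/um^2).
#'
#' @param group `"healthy"` or `"neuropathic"`.
#' @param seed forwarded to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
preset <- function(group = c("healthy", "neuropathic"), seed = 1L) {
  group <- match.arg(group)
  switch(group,
    healthy = phantom_spec(n_fibres = 7L, branch_prob = 0.6,
                           tortuosity_amp_um = 8, stroke_width_px = 3L,
                           seed = seed),
    neuropathic = phantom_spec(n_fibres = 2L, branch_prob = 0.2,
                               tortuosity_amp_um = 10, stroke_width_px = 3L,
                               seed = seed))
}

# intersection points of the line  p(t) = C + t*d  with the rectangle
# [1,h] x [1,w] (pixel coordinates); returns the two boundary t values
chord_range <- function(C, d, h, w) {
  ts <- c()
  for (lim in list(c(1, NA), c(h, NA), c(NA, 1), c(NA, w))) {
    if (!is.na(lim[1]) && abs(d[1]) > 1e-12) {
      t <- (lim[1] - C[1]) / d[1]
      p <- C + t * d
      if (p[2] >= 1 - 1e-9 && p[2] <= w + 1e-9) ts <- c(ts, t)
    }
    if (!is.na(lim[2]) && abs(d[2]) > 1e-12) {
      t <- (lim[2] - C[2]) / d[2]
      p <- C + t * d
      if (p[1] >= 1 - 1e-9 && p[1] <= h + 1e-9) ts <- c(ts, t)
    }
  }
  if (length(ts) < 2) return(NULL)
  c(min(ts), max(ts))
}

# sample a sinusoidally displaced chord; returns n x 2 matrix (row, col) in
# pixel coordinates plus the analytic arc length in pixels
sample_curve <- function(A, B, amp_px, n_half_waves, phase_zero = TRUE,
                         step_px = 0.25) {
  chord <- sqrt(sum((B - A)^2))
  n <- max(8L, ceiling(chord / step_px))
  t <- seq(0, 1, length.out = n + 1L)
  d <- (B - A) / chord
  nrm <- c(-d[2], d[1])                     # unit normal
  disp <- amp_px * sin(pi * n_half_waves * t)   # zero at both ends
  pts <- cbind(A[1] + t * (B[1] - A[1]) + disp * nrm[1],
               A[2] + t * (B[2] - A[2]) + disp * nrm[2])
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  list(points = pts, length_px = len)
}

# stamp a stroke of odd width w along curve points into a logical matrix
rasterize_curve <- function(pts, h, w, stroke) {
  rad <- (stroke - 1) / 2
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= (rad + 0.5)^2, , drop = FALSE]
  r <- round(pts[, 1]); c <- round(pts[, 2])
  keep <- !duplicated(cbind(r, c))
  r <- r[keep]; c <- c[keep]
  rr <- rep(r, each = nrow(off)) + off$dr
  cc <- rep(c, each = nrow(off)) + off$dc
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  m <- matrix(FALSE, h, w)
  m[cbind(rr[ok], cc[ok])] <- TRUE
  m
}

# A fibre end is unambiguous when an interior ending keeps >= 6 px distance
# from every border and a border crossing meets its border at >= 20 degrees.
end_config_ok <- function(pts, i_end, interior, h, w, margin = 6,
                          min_sin = sin(20 * pi / 180)) {
  p <- pts[i_end, ]
  if (interior)
    return(min(p[1] - 1, h - p[1], p[2] - 1, w - p[2]) >= margin)
  i2 <- if (i_end == 1L) 2L else i_end - 1L
  tang <- p - pts[i2, ]
  nt <- sqrt(sum(tang^2))
  if (nt < 1e-12) return(FALSE)
  ok <- TRUE
  if (p[1] <= 1 + 1e-6 || p[1] >= h - 1e-6)
    ok <- ok && abs(tang[1]) / nt >= min_sin
  if (p[2] <= 1 + 1e-6 || p[2] >= w - 1e-6)
    ok <- ok && abs(tang[2]) / nt >= min_sin
  ok
}

dilate_by <- function(m, k) {
  out <- m
  for (dr in -k:k) for (dc in -k:k)
    if (dr != 0L || dc != 0L) out <- out | shift_mat(m * 1L, dr, dc) > 0L
  out
}

#' Generate a phantom image with ground truth
#'
#' Fibres are drawn as smooth chords with sinusoidal lateral displacement
#' around a dominant direction, running border-to-border or to interior
#' endpoints; a fibre may carry one branch event spawning a child curve at
#' 25-55 degrees. Curves are rasterised at the requested stroke width.
#' Unless intersections are allowed, each new fibre tree must keep a 2-px
#' clearance from the existing mask, interior endings keep a 6-px margin
#' from the border, and crossings meet the border at 20 degrees or more
#' (rejection sampling, up to 400 attempts per fibre over 5 fresh layouts),
#' so the truth counts are exact and unambiguous at raster scale.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (an [sbp_image]) and `truth` (list:
#'   `true_total_length_um`, `true_n_fibres`, `true_n_branches`,
#'   `true_n_endpoints`, `true_n_border_crossings`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  pitch <- spec$pixel_pitch_um
  amp_px <- spec$tortuosity_amp_um / pitch
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  mask <- matrix(FALSE, h, w)
  truth <- list(true_total_length_um = 0, true_n_fibres = 0L,
                true_n_branches = 0L, true_n_endpoints = 0L,
                true_n_border_crossings = 0L)
  if (spec$n_fibres == 0L)
    return(list(image = sbp_image(mask * 1L, pitch), truth = truth))

  for (layout in 1:5) {
    # a fresh dominant direction and empty field if a layout gets stuck
    theta0 <- if (is.null(spec$orientation_deg)) stats::runif(1, 0, 180)
              else spec$orientation_deg
    mask[] <- FALSE
    truth <- list(true_total_length_um = 0, true_n_fibres = 0L,
                  true_n_branches = 0L, true_n_endpoints = 0L,
                  true_n_border_crossings = 0L)
    all_placed <- TRUE
    for (f in seq_len(spec$n_fibres)) {
    placed <- FALSE
    for (attempt in 1:400) {
      th <- (theta0 + stats::rnorm(1, 0, 8)) * pi / 180
      d <- c(sin(th), cos(th))               # (row, col) direction
      C <- c(stats::runif(1, 0.15 * h, 0.85 * h),
             stats::runif(1, 0.15 * w, 0.85 * w))
      tr <- chord_range(C, d, h, w)
      if (is.null(tr)) next
      t1 <- tr[1]; t2 <- tr[2]
      end1_interior <- stats::runif(1) < spec$interior_end_prob
      end2_interior <- stats::runif(1) < spec$interior_end_prob
      if (end1_interior) t1 <- t1 + stats::runif(1, 0.15, 0.4) * (t2 - t1)
      if (end2_interior) t2 <- t2 - stats::runif(1, 0.15, 0.4) * (t2 - t1)
      if (t2 - t1 < 40) next                  # too short to be a fibre
      A <- C + t1 * d; B <- C + t2 * d
      nhw <- sample(1:3, 1)
      cur <- sample_curve(A, B, amp_px * stats::runif(1, 0.5, 1), nhw)
      if (any(cur$points[, 1] < 1 | cur$points[, 1] > h |
              cur$points[, 2] < 1 | cur$points[, 2] > w)) next
      # grazing border incidence and interior ends hugging the border make
      # "crossing" vs "ending" ambiguous at raster scale; exact ground
      # truth requires rejecting such configurations (as with fibre
      # intersections)
      if (!end_config_ok(cur$points, 1, end1_interior, h, w) ||
          !end_config_ok(cur$points, nrow(cur$points), end2_interior, h, w))
        next
      pieces <- list(cur)
      has_branch <- stats::runif(1) < spec$branch_prob
      if (has_branch) {
        tb <- stats::runif(1, 0.3, 0.7)
        i_b <- max(2L, round(tb * nrow(cur$points)))
        Pb <- cur$points[i_b, ]
        tang <- cur$points[i_b, ] - cur$points[i_b - 1L, ]
        tang <- tang / sqrt(sum(tang^2))
        ang <- sample(c(-1, 1), 1) * stats::runif(1, 25, 55) * pi / 180
        rot <- c(tang[1] * cos(ang) - tang[2] * sin(ang),
                 tang[1] * sin(ang) + tang[2] * cos(ang))
        trc <- chord_range(Pb, rot, h, w)
        if (is.null(trc) || trc[2] < 1e-6) { has_branch <- FALSE }
        else {
          # side branches are short relative to main fibres; they cross the
          # border only when the branch point lies near it (a full-field
          # child would also make non-intersecting layouts near-impossible)
          tc <- min(trc[2], stats::runif(1, 40, 160) / pitch)
          child_to_border <- abs(tc - trc[2]) < 1e-9
          Bc <- Pb + tc * rot
          if (tc < 15) { has_branch <- FALSE }
          else {
            ch <- sample_curve(Pb, Bc, amp_px * 0.3, 1)
            if (any(ch$points[, 1] < 1 | ch$points[, 1] > h |
                    ch$points[, 2] < 1 | ch$points[, 2] > w) ||
                !end_config_ok(ch$points, nrow(ch$points),
                               !child_to_border, h, w)) {
              has_branch <- FALSE
            } else if (!spec$allow_intersections) {
              # the child must not run back into its parent away from the
              # branch point, or the recorded topology would be wrong
              par_m <- rasterize_curve(cur$points, h, w,
                                       spec$stroke_width_px)
              ch_m <- rasterize_curve(ch$points, h, w, spec$stroke_width_px)
              # a 25-55 deg child clears its parent's dilated stroke only
              # ~12-15 px past the branch point; overlaps inside that zone
              # are the junction itself, not a self-intersection
              zone <- (spec$stroke_width_px + 12)^2
              rIdx <- which(dilate_by(ch_m, 2L) & par_m)
              if (length(rIdx)) {
                rr2 <- ((rIdx - 1L) %% h) + 1L
                cc2 <- ((rIdx - 1L) %/% h) + 1L
                if (any((rr2 - Pb[1])^2 + (cc2 - Pb[2])^2 > zone)) next
              }
              pieces <- c(pieces, list(ch))
            } else {
              pieces <- c(pieces, list(ch))
            }
          }
        }
      }
      cand <- Reduce(`|`, lapply(pieces, function(p)
        rasterize_curve(p$points, h, w, spec$stroke_width_px)))
      if (!spec$allow_intersections) {
        if (any(dilate_by(cand, 2L) & mask)) next
      }
      # accept
      mask <- mask | cand
      truth$true_total_length_um <- truth$true_total_length_um +
        sum(vapply(pieces, function(p) p$length_px, 0)) * pitch
      n_branch <- if (has_branch) 1L else 0L
      truth$true_n_branches <- truth$true_n_branches + n_branch
      # segments: parent counts 1, each branch event adds 2
      truth$true_n_fibres <- truth$true_n_fibres + 1L + 2L * n_branch
      ends_border <- sum(!c(end1_interior, end2_interior))
      ends_interior <- 2L - ends_border
      if (has_branch) {
        if (child_to_border) ends_border <- ends_border + 1L
        else ends_interior <- ends_interior + 1L
      }
      truth$true_n_border_crossings <- truth$true_n_border_crossings + ends_border
      truth$true_n_endpoints <- truth$true_n_endpoints + ends_interior
      placed <- TRUE
      break
    }
    if (!placed) { all_placed <- FALSE; break }
    }
    if (all_placed)
      return(list(image = sbp_image(mask * 1L, pitch), truth = truth))
  }
  stop("could not place all fibres without overlap ",
       "(400 attempts x 5 layouts)")
}
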