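#' Per-image metric set and 1 mm^2 normalisation
#'
#' Assembles the full parameter vector for one segmented image: stage-1
#' morphology (component pixels, coverage ratio, component count,
#' homogeneity) and stage-2 skeleton/graph topology (skeleton pixels, single
#' nerve fibres, fibre length, fibre density, branch/connectivity/endpoint
#' counts). Fibre density is stored in micrometres of fibre per square
#' micrometre of image area; multiplied by 1e6 it reads as um per mm^2.
#'
#' @name metrics
NULL

METRIC_COLUMNS <- c(
  "component_pixels", "component_ratio_pct", "n_components", "homogeneity",
  "skeleton_pixels", "single_nerve_fibres", "fibres_per_component",
  "total_fibre_length_um", "avg_single_fibre_length_um",
  "fibre_density_um_per_um2", "n_branches", "n_connectivity_points",
  "n_endpoints", "normalized", "image_area_mm2")

# quantities that scale with imaged area (counts and summed lengths)
EXTENSIVE <- c("component_pixels", "n_components", "skeleton_pixels",
               "single_nerve_fibres", "total_fibre_length_um",
               "n_branches", "n_connectivity_points", "n_endpoints")

#' Compute the full metric set for one image
#'
#' Runs morphology, skeletonisation and graph analysis and fills every
#' metric field with un-normalised (per-image) values.
#'
#' @param img an [sbp_image].
#' @param tiles_per_axis tiles per axis for the homogeneity measure.
#' @param min_segment_um spur-pruning threshold passed to [build_graph()].
#' @return object of class `sbp_metrics`: a named list with the metric
#'   fields, `normalized = FALSE`, and `image_area_mm2`.
#' @export
compute_metrics <- function(img, tiles_per_axis = 8L, min_segment_um = 2) {
  stopifnot(inherits(img, "sbp_image"))
  mo <- morpho_metrics(img, tiles_per_axis)
  sk <- skeletonize(img)
  g <- build_graph(sk, min_segment_um = min_segment_um)
  n_fib <- nrow(g$edges)
  tot_len <- total_length_um(g)
  area_um2 <- img$width_px * img$height_px * img$pixel_pitch_um^2
  if (mo$component_pixels == 0L)
    message("empty mask: averages reported as 0 by convention")
  m <- list(
    component_pixels = mo$component_pixels,
    component_ratio_pct = mo$component_ratio,
    n_components = mo$n_components,
    homogeneity = mo$homogeneity,
    skeleton_pixels = sum(g$skeleton),
    single_nerve_fibres = n_fib,
    fibres_per_component = if (mo$n_components > 0) n_fib / mo$n_components else 0,
    total_fibre_length_um = tot_len,
    avg_single_fibre_length_um = if (n_fib > 0) tot_len / n_fib else 0,
    fibre_density_um_per_um2 = tot_len / area_um2,
    n_branches = count_nodes(g, "branch"),
    n_connectivity_points = count_nodes(g, "connectivity"),
    n_endpoints = count_nodes(g, "endpoint"),
    normalized = FALSE,
    image_area_mm2 = area_um2 / 1e6)
  class(m) <- "sbp_metrics"
  m
}

#' Normalise extensive metrics to 1 mm^2
#'
#' Extensive quantities (pixel counts, fibre counts, summed lengths, node
#' counts) are divided by the imaged area in mm^2 (x6.25 for the default
#' 0.16 mm^2 field); intensive quantities (coverage ratio, homogeneity,
#' density, per-fibre and per-component averages) are left unchanged.
#'
#' @param m an `sbp_metrics` object with `normalized = FALSE`.
#' @return the normalised `sbp_metrics`.
#' @export
normalize_metrics <- function(m) {
  stopifnot(inherits(m, "sbp_metrics"))
  if (isTRUE(m$normalized)) stop("metrics are already normalised")
  if (!is.finite(m$image_area_mm2) || m$image_area_mm2 <= 0)
    stop("image area must be positive")
  for (f in EXTENSIVE) m[[f]] <- m[[f]] / m$image_area_mm2
  m$normalized <- TRUE
  m
}

#' @export
print.sbp_metrics <- function(x, ...) {
  cat(sprintf("<sbp_metrics>%s\n",
              if (isTRUE(x$normalized)) " (per 1 mm^2)" else " (per image)"))
  for (f in setdiff(METRIC_COLUMNS, c("normalized", "image_area_mm2")))
    cat(sprintf("  %-28s %g\n", f, x[[f]]))
  invisible(x)
}

#' Write per-subject metrics to CSV
#'
#' One row per subject in a fixed, documented column order:
#' `subject_id, group,` then the metric columns, `normalized`,
#' `image_area_mm2`. All rows must share the same normalisation state.
#'
#' @param rows list of lists with fields `subject_id`, `group`, `metrics`
#'   (an `sbp_metrics`).
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(rows, path) {
  if (length(rows)) {
    norm <- vapply(rows, function(r) isTRUE(r$metrics$normalized), NA)
    if (length(unique(norm)) > 1L)
      stop("mixed normalisation state across rows")
  }
  df <- metrics_table(rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
metrics_table <- function(rows) {
  cols <- c("subject_id", "group", METRIC_COLUMNS)
  if (!length(rows)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    vals <- unclass(r$metrics)[METRIC_COLUMNS]
    data.frame(subject_id = r$subject_id, group = r$group,
               as.data.frame(vals), stringsAsFactors = FALSE)
  }))
  df
}

#' Read a metrics CSV written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return data.frame with one row per subject.
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("metrics CSV must contain columns: ", paste(need, collapse = ", "))
  df
}
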