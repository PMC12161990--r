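# Simulator: region layouts on a rectangular grid, distance-based affinity
# mixing, proportion-to-count conversion, cell/read sampling from a
# single-cell reference, and immune-infiltration injection.

#' Region geometries
#'
#' Building blocks for [make_layout()]: a circular region (all grid spots
#' within Euclidean `radius` of `center`) or an axis-aligned rectangle
#' (inclusive 0-based bounds).
#'
#' @param type region-level cell type the shape represents.
#' @param center length-2 numeric `(row, col)` center of the circle.
#' @param radius circle radius in grid units.
#' @return a shape descriptor consumed by [make_layout()].
#' @export
circle_region <- function(type, center, radius) {
  structure(list(type = type, geometry = "circle", center = center,
                 radius = radius), class = "region_shape")
}

#' @rdname circle_region
#' @param row0,row1,col0,col1 inclusive 0-based bounds of the rectangle.
#' @export
rect_region <- function(type, row0, row1, col0, col1) {
  structure(list(type = type, geometry = "rectangle", row0 = row0,
                 row1 = row1, col0 = col0, col1 = col1),
            class = "region_shape")
}

.shape_mask <- function(shape, coords) {
  if (shape$geometry == "circle") {
    (coords$row - shape$center[1])^2 + (coords$col - shape$center[2])^2 <=
      shape$radius^2
  } else {
    coords$row >= shape$row0 & coords$row <= shape$row1 &
      coords$col >= shape$col0 & coords$col <= shape$col1
  }
}

#' Build a tissue layout of disjoint regions on a rectangular grid
#'
#' Spots are laid out row-major on an `n_rows` by `n_cols` 0-based integer
#' grid; each shape claims the spots inside its geometry. Shapes must be
#' pairwise disjoint and non-empty.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param shapes list of shapes from [circle_region()] / [rect_region()];
#'   each `type` may appear at most once.
#' @return An object of class `region_layout` with the full coordinate
#'   table, per-region spot masks and region types.
#' @examples
#' lay <- make_layout(20, 20, list(
#'   circle_region("cancer", c(5, 5), 3),
#'   rect_region("ductal", 12, 17, 2, 17)))
#' @export
make_layout <- function(n_rows, n_cols, shapes) {
  coords <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  coords <- data.frame(spot_id = sprintf("s%03d_%03d", coords$row, coords$col),
                       row = coords$row, col = coords$col,
                       stringsAsFactors = FALSE)
  types <- vapply(shapes, function(s) s$type, character(1))
  if (anyDuplicated(types)) .stopf("each region type may appear only once")
  masks <- lapply(shapes, .shape_mask, coords = coords)
  names(masks) <- types
  for (i in seq_along(masks)) {
    if (!any(masks[[i]]))
      .stopf("region '%s' covers no spot inside the %d x %d grid",
             types[i], n_rows, n_cols)
  }
  cover <- Reduce(`+`, masks)
  if (any(cover > 1)) {
    bad <- coords$spot_id[cover > 1]
    .stopf("overlapping region shapes at spots: %s%s",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, coords = coords,
                 masks = masks, region_types = types, shapes = shapes),
            class = "region_layout")
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("region_layout: %d x %d grid (%d spots), regions: %s\n",
              x$n_rows, x$n_cols, nrow(x$coords),
              paste(sprintf("%s (%d)", x$region_types,
                            vapply(x$masks, sum, integer(1))), collapse = ", ")))
  invisible(x)
}

#' Read and write region layouts as YAML
#'
#' A layout file holds `n_rows`, `n_cols` and a `shapes` list; each shape
#' has `type`, `geometry` (`"circle"` or `"rectangle"`) and its geometry
#' fields (`center` + `radius`, or `row0`/`row1`/`col0`/`col1`).
#'
#' @param path YAML file path.
#' @return [read_layout()] returns a validated `region_layout`.
#' @export
read_layout <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .stopf("layout files require the yaml package")
  spec <- yaml::read_yaml(path)
  shapes <- lapply(spec$shapes, function(s) {
    switch(s$geometry,
           circle = circle_region(s$type, unlist(s$center), s$radius),
           rectangle = rect_region(s$type, s$row0, s$row1, s$col0, s$col1),
           .stopf("unknown geometry '%s'", s$geometry))
  })
  make_layout(spec$n_rows, spec$n_cols, shapes)
}

#' @rdname read_layout
#' @param layout a `region_layout`.
#' @export
write_layout <- function(layout, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .stopf("layout files require the yaml package")
  shapes <- lapply(layout$shapes, function(s) {
    if (s$geometry == "circle")
      list(type = s$type, geometry = "circle",
           center = as.numeric(s$center), radius = s$radius)
    else
      list(type = s$type, geometry = "rectangle", row0 = s$row0,
           row1 = s$row1, col0 = s$col0, col1 = s$col1)
  })
  yaml::write_yaml(list(n_rows = layout$n_rows, n_cols = layout$n_cols,
                        shapes = shapes), path)
  invisible(path)
}

#' Ground-truth proportions from a region layout
#'
#' For a spot inside region `r` the proportion vector is the indicator of
#' `r` (regions are homogeneous cell populations). For an out-of-region
#' spot `s`, the affinity to region `r` is the inverse of the Euclidean
#' distance to the closest spot of `r`, plus Gaussian noise:
#' `A[s, r] = 1 / min_{s' in r} Dist(s, s') + delta`, with
#' `delta ~ Normal(0, noise_sd)`, clipped below at `1e-6` to stay positive.
#' Rows are then normalized to sum to one.
#'
#' Uses the current RNG state; seed upstream (see [simulate_st()]).
#'
#' @param layout a `region_layout`.
#' @param noise_sd standard deviation of the affinity noise (>= 0).
#' @return A region-level [proportion_matrix()] with the affinity matrix
#'   attached as attribute `"affinity"`.
#' @export
ground_truth_proportions <- function(layout, noise_sd = 0.05) {
  if (noise_sd < 0) .stopf("noise_sd must be non-negative")
  coords <- layout$coords
  n <- nrow(coords)
  types <- layout$region_types
  A <- matrix(0, n, length(types), dimnames = list(coords$spot_id, types))
  for (j in seq_along(types)) {
    pts <- coords[layout$masks[[j]], c("row", "col")]
    d2 <- outer(coords$row, pts$row, "-")^2 + outer(coords$col, pts$col, "-")^2
    dmin <- sqrt(apply(d2, 1, min))
    aff <- ifelse(dmin > 0, 1 / dmin, Inf)
    aff <- aff + stats::rnorm(n, 0, noise_sd)
    A[, j] <- pmax(aff, 1e-6)
  }
  inside <- vapply(layout$masks, identity, logical(n))
  P <- A / rowSums(A)
  for (j in seq_along(types)) {
    P[inside[, j], ] <- 0
    P[inside[, j], j] <- 1
  }
  out <- proportion_matrix(P, level = "region")
  attr(out, "affinity") <- A
  out
}

#' Convert proportions to integer cell counts per spot
#'
#' Counts are `C[s, r] = floor(cells_per_spot * P[s, r])` and the
#' ground-truth proportion saved for evaluation is the renormalized count,
#' `C[s, r] / sum_r' C[s, r']`. A spot whose row floors to all zeros gets
#' one cell of its largest-proportion type (ties to the lowest type index),
#' so every spot holds at least one cell.
#'
#' @param p_tilde a region-level [proportion_matrix()].
#' @param cells_per_spot cells captured per spot (default 10).
#' @return list with `counts` (integer matrix) and `proportions` (the
#'   renormalized ground truth).
#' @export
proportions_to_counts <- function(p_tilde, cells_per_spot = 10L) {
  if (cells_per_spot < 1) .stopf("cells_per_spot must be >= 1")
  C <- floor(cells_per_spot * unclass(p_tilde))
  zero <- rowSums(C) == 0
  if (any(zero)) {
    amax <- max.col(unclass(p_tilde)[zero, , drop = FALSE],
                    ties.method = "first")
    C[cbind(which(zero), amax)] <- 1
  }
  storage.mode(C) <- "integer"
  list(counts = C,
       proportions = proportion_matrix(C / rowSums(C), level = "region"))
}

.draw_spot_cells <- function(ref, c_row, region_of_cell = region_of_cells(ref)) {
  picked <- integer(0)
  for (r in names(c_row)[c_row > 0]) {
    idx <- which(region_of_cell == r)
    if (c_row[[r]] > length(idx))
      .stopf(paste0("requested %d cells of type '%s' but the reference has ",
                    "only %d; supply a larger reference or reduce ",
                    "cells_per_spot"), c_row[[r]], r, length(idx))
    picked <- c(picked, idx[sample.int(length(idx), c_row[[r]])])
  }
  picked
}

.thin_counts <- function(totals, rate) {
  if (rate >= 1) return(totals)
  out <- stats::rbinom(length(totals), size = as.integer(totals), prob = rate)
  names(out) <- names(totals)
  out
}

#' Sample one spot's expression from the reference
#'
#' Draws `c_row[r]` distinct cells of each region-level type `r` from the
#' reference (without replacement), then retains each read of the drawn
#' cells independently with probability `downsample_rate`. The per-gene
#' retained read count is drawn as a single binomial on the summed counts,
#' which is distributionally identical to thinning each cell separately.
#'
#' @param ref a `single_cell_reference`.
#' @param c_row named integer vector of cell counts per region-level type.
#' @param downsample_rate read retention probability (default 0.10).
#' @return named integer vector of gene counts for the spot.
#' @export
sample_spot_expression <- function(ref, c_row, downsample_rate = 0.10) {
  cells <- .draw_spot_cells(ref, c_row)
  totals <- colSums(ref$counts[cells, , drop = FALSE])
  .thin_counts(totals, downsample_rate)
}

#' Draw truncated-Gaussian infiltration proportions
#'
#' The immune proportion of an infiltrated spot is drawn from
#' `Normal(mu, sigma)` truncated to the open interval (0, 1) by rejection.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian mean and sd (defaults 0.5 and 0.2).
#' @return numeric vector of `n` proportions in (0, 1).
#' @export
sample_infiltration_proportion <- function(n, mu = 0.5, sigma = 0.2) {
  if (sigma == 0) {
    if (mu <= 0 || mu >= 1) .stopf("mu must lie in (0, 1) when sigma is 0")
    return(rep(mu, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    q <- stats::rnorm(n, mu, sigma)
    out <- c(out, q[q > 0 & q < 1])
  }
  out[seq_len(n)]
}

#' Inject immune infiltration into pure tumor spots
#'
#' Selects `round(fraction * n)` of the `n` pure tumor spots uniformly
#' without replacement. For each selected spot an immune proportion `q` is
#' drawn from the truncated Gaussian; `max(1, floor(q * total))` of the
#' spot's cells are replaced by immune cells (total cell count per spot is
#' preserved), and the ground-truth proportions are re-derived from the
#' updated counts.
#'
#' @param p ground-truth region-level [proportion_matrix()].
#' @param counts matching integer cell-count matrix.
#' @param cancer_type,immune_type column names of the tumor type and the
#'   injected type (the immune column is created if absent).
#' @param fraction fraction of pure tumor spots to infiltrate.
#' @param mu,sigma truncated-Gaussian parameters of the immune proportion.
#' @return list with updated `proportions`, `counts` and the logical
#'   `mask` of infiltrated spots.
#' @export
inject_infiltration <- function(p, counts, cancer_type, immune_type,
                                fraction = 0.10, mu = 0.5, sigma = 0.2) {
  if (!cancer_type %in% colnames(counts))
    .stopf("cancer type '%s' not present", cancer_type)
  if (fraction <= 0 || fraction > 1) .stopf("fraction must lie in (0, 1]")
  tot <- rowSums(counts)
  pure <- which(counts[, cancer_type] == tot & tot > 0)
  if (!length(pure)) .stopf("no pure '%s' spots to infiltrate", cancer_type)
  n_sel <- round(fraction * length(pure))
  mask <- stats::setNames(rep(FALSE, nrow(counts)), rownames(counts))
  if (n_sel == 0) {
    .warnf("fraction %g of %d pure spots rounds to 0; nothing injected",
           fraction, length(pure))
  } else {
    sel <- pure[sample.int(length(pure), n_sel)]
    q <- sample_infiltration_proportion(n_sel, mu, sigma)
    k <- pmax(1L, as.integer(floor(q * tot[sel])))
    if (!immune_type %in% colnames(counts)) {
      counts <- cbind(counts, 0L)
      colnames(counts)[ncol(counts)] <- immune_type
    }
    counts[sel, immune_type] <- counts[sel, immune_type] + k
    counts[sel, cancer_type] <- counts[sel, cancer_type] - k
    mask[sel] <- TRUE
  }
  list(proportions = proportion_matrix(counts / rowSums(counts),
                                       level = "region"),
       counts = counts, mask = mask)
}

#' Simulate a spatial transcriptomics sample with known composition
#'
#' End-to-end simulator: ground-truth proportions from the layout,
#' conversion to per-spot cell counts, optional immune-infiltration
#' injection, then cell and read sampling from the single-cell reference.
#' The fine-level ground truth is defined by the fine-type labels of the
#' cells actually drawn for each spot. Fully determined by
#' `config$rng_seed`.
#'
#' @param ref a `single_cell_reference` whose region-level grouping covers
#'   the layout's region types.
#' @param layout a `region_layout`.
#' @param config a [resort_config()].
#' @param infiltration `NULL`, or a named character vector
#'   `c(cancer = ..., immune = ...)` naming the tumor region type and the
#'   immune region-level type to inject.
#' @return list with `spatial` ([spatial_counts()]), `truth_region` and
#'   `truth_fine` ([proportion_matrix()]), `cell_counts`, and the logical
#'   `infiltration_mask`.
#' @examples
#' \donttest{
#' sc <- scenario("three-region", n_rows = 20, n_cols = 20)
#' sim <- simulate_st(sc$reference, sc$layout, sc$config)
#' }
#' @export
simulate_st <- function(ref, layout, config = resort_config(),
                        infiltration = NULL) {
  missing <- setdiff(layout$region_types, unique(region_of_cells(ref)))
  if (length(missing))
    .stopf("reference has no cells for region types: %s",
           paste(missing, collapse = ", "))
  set.seed(config$rng_seed)
  p_tilde <- ground_truth_proportions(layout, config$noise_sd)
  pc <- proportions_to_counts(p_tilde, config$cells_per_spot)
  C <- pc$counts
  P <- pc$proportions
  mask <- stats::setNames(rep(FALSE, nrow(C)), rownames(C))
  if (!is.null(infiltration)) {
    inj <- inject_infiltration(P, C, infiltration[["cancer"]],
                               infiltration[["immune"]],
                               config$infiltration_fraction,
                               config$infiltration_mu,
                               config$infiltration_sigma)
    C <- inj$counts
    P <- inj$proportions
    mask <- inj$mask
  }
  region_of_cell <- region_of_cells(ref)
  fine_types <- sort(unique(ref$fine_type))
  n_spots <- nrow(C)
  n_genes <- ncol(ref$counts)
  expr <- matrix(0L, n_spots, n_genes,
                 dimnames = list(rownames(C), ref$gene_ids))
  fine_counts <- matrix(0L, n_spots, length(fine_types),
                        dimnames = list(rownames(C), fine_types))
  refm <- as.matrix(ref$counts)
  for (s in seq_len(n_spots)) {
    cells <- .draw_spot_cells(ref, C[s, ], region_of_cell)
    fine_counts[s, ] <- tabulate(match(ref$fine_type[cells], fine_types),
                                 nbins = length(fine_types))
    totals <- colSums(refm[cells, , drop = FALSE])
    expr[s, ] <- .thin_counts(totals, config$downsample_rate)
  }
  list(spatial = spatial_counts(expr, layout$coords),
       truth_region = P,
       truth_fine = proportion_matrix(fine_counts / rowSums(fine_counts),
                                      level = "fine"),
       cell_counts = C,
       infiltration_mask = mask)
}
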