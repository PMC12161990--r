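#' resort: region-based cell sorting for spatial transcriptomics
#'
#' Deconvolution of spatial transcriptomics (ST) spots into cell-type
#' proportions without relying on an external single-cell reference at the
#' region level. The workflow: extract molecularly homogeneous spatial
#' regions ([extract_regions()]), build a pseudo-internal reference from the
#' region spots ([build_pseudo_reference()]), deconvolve region-level
#' proportions ([deconvolve_regions()]), and refine to finer cell types with
#' the two-step product estimator ([deconvolve_fine()]). A simulator with
#' known ground truth ([simulate_st()]) and an evaluation battery
#' ([spot_metrics()], [classify_infiltration()]) support benchmarking.
#'
#' @docType package
#' @name resort-package
#' @aliases resort
#' @keywords internal
"_PACKAGE"

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Spatial counts container
#'
#' A spots-by-genes integer count matrix with per-spot integer grid
#' coordinates, the basic ST data container used throughout the package.
#'
#' @param counts numeric matrix, spots in rows, genes in columns; entries
#'   must be non-negative. Row names (spot ids) and column names (gene ids)
#'   are taken from the matrix unless given explicitly.
#' @param coords data.frame with columns `spot_id`, `row`, `col`; integer
#'   0-based grid positions, one row per spot, same order as `counts`.
#' @param gene_ids,spot_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An object of class `spatial_counts`: a list with elements
#'   `counts`, `coords`, `gene_ids`, `spot_ids`.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 4,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' sc <- spatial_counts(m, data.frame(spot_id = rownames(m),
#'                                    row = c(0, 0, 1, 1),
#'                                    col = c(0, 1, 0, 1)))
#' @export
spatial_counts <- function(counts, coords, gene_ids = colnames(counts),
                           spot_ids = rownames(counts)) {
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  coords <- as.data.frame(coords)
  obj <- structure(list(counts = counts, coords = coords,
                        gene_ids = gene_ids, spot_ids = spot_ids),
                   class = "spatial_counts")
  validate_spatial_counts(obj)
}

#' @rdname spatial_counts
#' @param x a `spatial_counts` object.
#' @export
validate_spatial_counts <- function(x) {
  if (!all(c("spot_id", "row", "col") %in% names(x$coords)))
    .stopf("coords must have columns spot_id, row, col")
  if (nrow(x$counts) != nrow(x$coords))
    .stopf("dimension mismatch: %d spots in counts but %d coordinate rows",
           nrow(x$counts), nrow(x$coords))
  if (anyDuplicated(x$spot_ids))
    .stopf("duplicated spot ids: %s",
           paste(unique(x$spot_ids[duplicated(x$spot_ids)]), collapse = ", "))
  if (!identical(as.character(x$coords$spot_id), as.character(x$spot_ids)))
    .stopf("coords spot_id order does not match counts row order")
  if (anyDuplicated(x$coords[, c("row", "col")]))
    .stopf("duplicated grid coordinates")
  if (min(x$counts) < 0) .stopf("counts must be non-negative")
  x
}

#' @export
print.spatial_counts <- function(x, ...) {
  cat(sprintf("spatial_counts: %d spots x %d genes (grid %d x %d)\n",
              nrow(x$counts), ncol(x$counts),
              max(x$coords$row) - min(x$coords$row) + 1L,
              max(x$coords$col) - min(x$coords$col) + 1L))
  invisible(x)
}

#' Single-cell reference container
#'
#' Cells-by-genes counts with a fine cell-type label per cell and a mapping
#' from fine types to region-level types (e.g. fourteen fine types grouped
#' into cancer / ductal / other normal).
#'
#' @param counts numeric matrix, cells in rows, genes in columns.
#' @param fine_type character vector, one fine-type label per cell.
#' @param region_type_of named character vector mapping every fine type to
#'   its region-level type.
#' @return An object of class `single_cell_reference`.
#' @export
single_cell_reference <- function(counts, fine_type, region_type_of) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  obj <- structure(list(counts = counts,
                        fine_type = as.character(fine_type),
                        region_type_of = region_type_of,
                        gene_ids = colnames(counts),
                        cell_ids = rownames(counts)),
                   class = "single_cell_reference")
  validate_reference(obj)
}

#' @rdname single_cell_reference
#' @param x a `single_cell_reference` object.
#' @export
validate_reference <- function(x) {
  if (length(x$fine_type) != nrow(x$counts))
    .stopf("one fine-type label needed per cell (%d labels, %d cells)",
           length(x$fine_type), nrow(x$counts))
  missing <- setdiff(unique(x$fine_type), names(x$region_type_of))
  if (length(missing))
    .stopf("fine types without a region-level grouping entry: %s",
           paste(missing, collapse = ", "))
  if (min(x$counts) < 0) .stopf("reference counts must be non-negative")
  x
}

#' @export
print.single_cell_reference <- function(x, ...) {
  cat(sprintf("single_cell_reference: %d cells x %d genes, %d fine types -> %d region-level types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$fine_type)),
              length(unique(x$region_type_of))))
  invisible(x)
}

#' Region-level grouping of reference cells
#'
#' @param ref a `single_cell_reference`.
#' @return character vector of region-level types, one per cell.
#' @export
region_of_cells <- function(ref) {
  unname(ref$region_type_of[ref$fine_type])
}

#' Proportion matrix container
#'
#' A spots-by-types matrix of non-negative proportions whose rows sum to 1.
#' Used for ground-truth and estimated compositions at both the region and
#' fine level.
#'
#' @param values numeric matrix, spots in rows, cell types in columns;
#'   column names are the type ids.
#' @param level `"region"` or `"fine"`.
#' @param tol tolerance on the row-sum-to-one check.
#' @return The matrix with class `proportion_matrix` and attribute `level`.
#' @export
proportion_matrix <- function(values, level = c("region", "fine"),
                              tol = 1e-9) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colnames(values))) .stopf("proportion matrix needs type ids as column names")
  if (min(values) < -tol || max(values) > 1 + tol)
    .stopf("proportions must lie in [0, 1]")
  rs <- rowSums(values)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    .stopf("proportion rows must sum to 1; offending spots: %s",
           paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
  structure(values, class = c("proportion_matrix", class(values)),
            level = level)
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("proportion_matrix (%s level): %d spots x %d types [%s]\n",
              attr(x, "level"), nrow(x), ncol(x),
              paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Run configuration
#'
#' A single object carrying every tunable of the pipeline, so that each run
#' is fully described by a config plus a seed.
#'
#' @param rng_seed integer seed used by [simulate_st()] and the fixture
#'   generators.
#' @param downsample_rate fraction of each sampled cell's reads retained
#'   when forming a spot (default 0.10, which brings per-spot libraries to
#'   the order of magnitude of Visium spots).
#' @param cells_per_spot number of cells captured per spot (default 10).
#' @param infiltration_fraction fraction of pure tumor spots that receive
#'   injected immune cells (default 0.10).
#' @param infiltration_mu,infiltration_sigma mean and sd of the Gaussian
#'   the injected immune proportion is drawn from, truncated to (0, 1)
#'   (defaults 0.5 and 0.2).
#' @param k_pcs number of principal components used for spot-spot
#'   similarity (default 10).
#' @param min_region_size minimum number of spots for a connected component
#'   to count as a region (`m`; default 40, the Visium default).
#' @param epsilon optional manual edge-weight threshold; `NULL` means
#'   auto-selection via [select_epsilon()].
#' @param neighbor_scheme spatial adjacency: `"grid4"`, `"grid8"` or
#'   `"hex6"`.
#' @param infiltration_call_threshold estimated immune proportion at or
#'   above which a tumor spot is called infiltrated (default 0.05).
#' @param noise_sd standard deviation of the Gaussian noise added to
#'   spot-region affinities in the simulator (default 0.05).
#' @param n_top_genes genes kept per type in signature construction, ranked
#'   by one-vs-rest log fold change (default 200; the union over types is
#'   used).
#' @param downsample_mode read downsampling model; only `"binomial"`
#'   (per-gene binomial thinning) is implemented.
#' @return A list of class `resort_config`.
#' @export
resort_config <- function(rng_seed = 1L,
                          downsample_rate = 0.10,
                          cells_per_spot = 10L,
                          infiltration_fraction = 0.10,
                          infiltration_mu = 0.5,
                          infiltration_sigma = 0.2,
                          k_pcs = 10L,
                          min_region_size = 40L,
                          epsilon = NULL,
                          neighbor_scheme = c("grid4", "grid8", "hex6"),
                          infiltration_call_threshold = 0.05,
                          noise_sd = 0.05,
                          n_top_genes = 200L,
                          downsample_mode = "binomial") {
  neighbor_scheme <- match.arg(neighbor_scheme)
  cfg <- list(rng_seed = as.integer(rng_seed),
              downsample_rate = downsample_rate,
              cells_per_spot = as.integer(cells_per_spot),
              infiltration_fraction = infiltration_fraction,
              infiltration_mu = infiltration_mu,
              infiltration_sigma = infiltration_sigma,
              k_pcs = as.integer(k_pcs),
              min_region_size = as.integer(min_region_size),
              epsilon = epsilon,
              neighbor_scheme = neighbor_scheme,
              infiltration_call_threshold = infiltration_call_threshold,
              noise_sd = noise_sd,
              n_top_genes = as.integer(n_top_genes),
              downsample_mode = downsample_mode)
  class(cfg) <- "resort_config"
  validate_config(cfg)
}

#' @rdname resort_config
#' @param cfg a `resort_config` object.
#' @export
validate_config <- function(cfg) {
  fr <- c("downsample_rate", "infiltration_fraction", "infiltration_mu",
          "infiltration_sigma", "infiltration_call_threshold")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      .stopf("config field %s must lie in [0, 1], got %g", f, cfg[[f]])
  if (cfg$noise_sd < 0) .stopf("noise_sd must be non-negative")
  if (cfg$min_region_size < 1L) .stopf("min_region_size must be >= 1")
  if (cfg$k_pcs < 1L) .stopf("k_pcs must be >= 1")
  if (cfg$cells_per_spot < 1L) .stopf("cells_per_spot must be >= 1")
  if (!identical(cfg$downsample_mode, "binomial"))
    .stopf("unsupported downsample_mode: %s", cfg$downsample_mode)
  cfg
}

#' @export
print.resort_config <- function(x, ...) {
  cat("resort_config:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-28s %s\n", f, if (is.null(v)) "auto" else format(v)))
  }
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Fields absent from the file keep their [resort_config()] defaults.
#'
#' @param path YAML file with a flat mapping of config fields.
#' @return A `resort_config` object.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .stopf("reading YAML configs requires the yaml package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(resort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    .stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(resort_config, vals)
}
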