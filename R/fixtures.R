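# Programmatic synthetic single-cell references and ready-to-run
# simulation scenarios, so every pipeline stage is testable without
# downloads. Counts follow a negative-binomial baseline with disjoint
# planted marker blocks per fine type; an "external" variant applies
# per-gene multiplicative batch factors to emulate platform effects.

#' Specification of a synthetic single-cell reference
#'
#' @param grouping named character vector mapping fine types to
#'   region-level types (defaults to two subtypes for each of cancer,
#'   ductal and normal).
#' @param n_genes total genes (default 1000, the scale of a targeted gene
#'   panel; together with the baseline mean this puts per-spot libraries
#'   around 500 reads, the low end of Visium spot libraries).
#' @param cells_per_type cells generated per fine type (default 60; must
#'   be at least the cells-per-spot of any planned simulation).
#' @param markers_per_type planted marker genes per fine type (default
#'   25, putting roughly 17% of a cell's reads on its own type's markers
#'   -- the strong separation expected between distinct tissue
#'   compartments); marker blocks are disjoint across types.
#' @param marker_fold mean fold-change of a marker in its own type
#'   (default 8).
#' @param nb_mean baseline negative-binomial mean per gene (default 0.5).
#' @param nb_dispersion negative-binomial size parameter (default 0.5;
#'   variance = mean + mean^2 / size), giving sparse overdispersed counts
#'   as in single-cell data.
#' @param batch_sigma sd of the log-normal per-gene batch factor used by
#'   [make_external_reference()] (default 0.5).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(grouping = c(cancer.1 = "cancer", cancer.2 = "cancer",
                                      ductal.1 = "ductal", ductal.2 = "ductal",
                                      normal.1 = "normal", normal.2 = "normal"),
                         n_genes = 1000L, cells_per_type = 60L,
                         markers_per_type = 25L, marker_fold = 8,
                         nb_mean = 0.5, nb_dispersion = 0.5,
                         batch_sigma = 0.5) {
  n_fine <- length(grouping)
  if (n_fine * markers_per_type > n_genes)
    .stopf("%d fine types x %d markers exceed %d genes (marker blocks must be disjoint)",
           n_fine, markers_per_type, n_genes)
  structure(list(grouping = grouping, n_genes = as.integer(n_genes),
                 cells_per_type = as.integer(cells_per_type),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, batch_sigma = batch_sigma),
            class = "fixture_spec")
}

#' Planted marker genes per fine type
#'
#' @param spec a [fixture_spec()].
#' @return named list of marker gene ids per fine type (disjoint blocks).
#' @export
fixture_markers <- function(spec) {
  fine <- names(spec$grouping)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  out <- lapply(seq_along(fine), function(i)
    genes[((i - 1) * spec$markers_per_type + 1):(i * spec$markers_per_type)])
  stats::setNames(out, fine)
}

.fixture_mu <- function(spec) {
  fine <- names(spec$grouping)
  markers <- fixture_markers(spec)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  mu <- matrix(spec$nb_mean, length(fine), spec$n_genes,
               dimnames = list(fine, genes))
  for (ty in fine) mu[ty, markers[[ty]]] <- spec$nb_mean * spec$marker_fold
  mu
}

.draw_cells <- function(spec, mu) {
  fine <- names(spec$grouping)
  counts <- do.call(rbind, lapply(fine, function(ty) {
    matrix(stats::rnbinom(spec$cells_per_type * spec$n_genes,
                          mu = rep(mu[ty, ], each = spec$cells_per_type),
                          size = spec$nb_dispersion),
           nrow = spec$cells_per_type)
  }))
  colnames(counts) <- colnames(mu)
  rownames(counts) <- sprintf("c%04d", seq_len(nrow(counts)))
  labels <- rep(fine, each = spec$cells_per_type)
  single_cell_reference(counts, labels, spec$grouping)
}

#' Generate a synthetic single-cell reference
#'
#' Negative-binomial baseline counts with each fine type's marker genes
#' up-scaled by `marker_fold` in expectation. Uses the current RNG state;
#' wrap in `set.seed()` for reproducibility.
#'
#' @param spec a [fixture_spec()].
#' @return a [single_cell_reference()].
#' @export
make_reference <- function(spec) {
  .draw_cells(spec, .fixture_mu(spec))
}

#' Generate a batch-shifted external reference
#'
#' Regenerates cells from the same per-type model, but multiplies every
#' gene's mean by a log-normal factor `exp(Normal(0, batch_sigma))` shared
#' across cells -- a reference with the same type structure but
#' systematic gene-level differences, emulating batch/platform effects
#' between experiments.
#'
#' @param spec a [fixture_spec()].
#' @return a [single_cell_reference()] with the batch factors attached as
#'   attribute `"batch_factor"`.
#' @export
make_external_reference <- function(spec) {
  mu <- .fixture_mu(spec)
  f <- exp(stats::rnorm(spec$n_genes, 0, spec$batch_sigma))
  ref <- .draw_cells(spec, sweep(mu, 2, f, `*`))
  attr(ref, "batch_factor") <- stats::setNames(f, colnames(mu))
  ref
}

#' Bundled simulation scenarios
#'
#' Ready-to-run (reference, layout, config) bundles reproducing the
#' simulation designs at a configurable grid size:
#' * `"three-region"`: circular cancer and normal regions plus a
#'   rectangular ductal region on the grid, two fine types per region
#'   type.
#' * `"three-region-infiltrated"`: the same layout plus an immune
#'   region-level type in the reference and an `infiltration` directive
#'   (10% of pure cancer spots, truncated Normal(0.5, 0.2) immune
#'   proportion).
#' * `"two-block-regions"`: two rectangular blocks tiling the full grid
#'   with one fine type each -- the fixture used to validate region
#'   extraction. Its bundle carries an extra `noiseless_spatial` element:
#'   a [spatial_counts()] object whose spots hold their block's expected
#'   expression profile exactly (block-constant orthogonal marker
#'   blocks), on which region extraction must recover the two blocks
#'   perfectly.
#'
#' @param name scenario name.
#' @param n_rows,n_cols grid size (default 50 x 50, i.e. 2500 spots).
#' @param seed seed used both to build the reference and as the config's
#'   `rng_seed`.
#' @return list with `reference`, `external_reference` (batch-shifted),
#'   `layout`, `config`, `spec` and `infiltration` (`NULL` or the named
#'   vector for [simulate_st()]).
#' @export
scenario <- function(name = c("three-region", "three-region-infiltrated",
                              "two-block-regions"),
                     n_rows = 50L, n_cols = 50L, seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "two-block-regions") {
    spec <- fixture_spec(grouping = c(blockA.1 = "blockA", blockB.1 = "blockB"),
                         cells_per_type = 120L)
    half <- floor(n_cols / 2)
    layout <- make_layout(n_rows, n_cols, list(
      rect_region("blockA", 0, n_rows - 1, 0, half - 1),
      rect_region("blockB", 0, n_rows - 1, half, n_cols - 1)))
    infl <- NULL
  } else {
    grouping <- c(cancer.1 = "cancer", cancer.2 = "cancer",
                  ductal.1 = "ductal", ductal.2 = "ductal",
                  normal.1 = "normal", normal.2 = "normal")
    if (name == "three-region-infiltrated")
      grouping <- c(grouping, immune.1 = "immune", immune.2 = "immune")
    spec <- fixture_spec(grouping = grouping)
    r <- round(0.18 * min(n_rows, n_cols))
    c1 <- round(0.26 * c(n_rows, n_cols))
    c2 <- c(round(0.26 * n_rows), round(0.77 * n_cols))
    layout <- make_layout(n_rows, n_cols, list(
      circle_region("cancer", c1, r),
      circle_region("normal", c2, r),
      rect_region("ductal", round(0.64 * n_rows), round(0.80 * n_rows),
                  round(0.20 * n_cols), round(0.80 * n_cols))))
    infl <- if (name == "three-region-infiltrated")
      c(cancer = "cancer", immune = "immune") else NULL
  }
  reference <- make_reference(spec)
  external <- make_external_reference(spec)
  out <- list(reference = reference, external_reference = external,
              layout = layout, config = resort_config(rng_seed = seed),
              spec = spec, infiltration = infl)
  if (name == "two-block-regions") {
    mu <- .fixture_mu(spec)
    type_of_spot <- rep(NA_character_, nrow(layout$coords))
    for (ty in layout$region_types)
      type_of_spot[layout$masks[[ty]]] <- names(spec$grouping)[spec$grouping == ty][1]
    counts <- round(mu[type_of_spot, , drop = FALSE] *
                      out$config$cells_per_spot * out$config$downsample_rate)
    rownames(counts) <- layout$coords$spot_id
    out$noiseless_spatial <- spatial_counts(counts, layout$coords)
  }
  out
}
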