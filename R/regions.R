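# Homogeneous-region extraction: library-size normalization, PCA
# embedding, a similarity graph restricted to spatially adjacent spots,
# edge filtering at an auto-selected threshold epsilon, and connected
# components of size >= m.

#' Library-size normalize and log-transform spot counts
#'
#' Each spot is scaled to the median library size and log-transformed:
#' `log(1 + count / library * median(library))`. The resulting profile of a
#' spot is invariant to multiplying its counts by a constant.
#'
#' @param spatial a [spatial_counts()] object.
#' @return numeric matrix, spots by genes.
#' @export
normalize_log <- function(spatial) {
  m <- as.matrix(spatial$counts)
  lib <- rowSums(m)
  if (any(lib == 0))
    .stopf("spots with zero library size: %s",
           paste(utils::head(rownames(m)[lib == 0], 5), collapse = ", "))
  log1p(m / lib * stats::median(lib))
}

#' PCA embedding of normalized expression
#'
#' Column-centered principal component scores with a deterministic sign
#' convention: each component is flipped so that its largest-magnitude
#' gene loading is positive.
#'
#' @param expr numeric matrix, spots by genes (e.g. from
#'   [normalize_log()]).
#' @param k_pcs number of components to keep.
#' @return scores matrix, spots by `k_pcs`, with the rotation attached as
#'   attribute `"rotation"`.
#' @export
pca_embed <- function(expr, k_pcs = 10L) {
  k_pcs <- min(as.integer(k_pcs), nrow(expr) - 1L)
  if (k_pcs > min(nrow(expr), ncol(expr)))
    .stopf("k_pcs = %d exceeds min(n_spots, n_genes) = %d", k_pcs,
           min(nrow(expr), ncol(expr)))
  if (k_pcs < 1L) .stopf("k_pcs must be >= 1")
  pc <- stats::prcomp(expr, center = TRUE, scale. = FALSE, rank. = k_pcs)
  flip <- vapply(seq_len(k_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k_pcs), drop = FALSE], 2, flip, `*`)
  attr(scores, "rotation") <-
    sweep(pc$rotation[, seq_len(k_pcs), drop = FALSE], 2, flip, `*`)
  scores
}

.neighbor_offsets <- function(scheme, row_parity) {
  # canonical "forward" offsets only, so each undirected pair appears once
  switch(scheme,
         grid4 = cbind(c(0, 1), c(1, 0)),
         grid8 = cbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
         hex6 = if (row_parity == 0) cbind(c(0, 1), c(1, 0), c(1, -1))
                else cbind(c(0, 1), c(1, 0), c(1, 1)),
         .stopf("unknown neighbor scheme '%s'", scheme))
}

#' Build the spatially constrained similarity graph
#'
#' Nodes are spots; an edge connects every pair of spatially adjacent spots
#' (under `neighbor_scheme`), weighted by the Pearson correlation of the
#' two spots' PC embeddings. Weights lie in \[-1, 1\]; a zero-variance
#' embedding row yields weight 0.
#'
#' @param embedding spots-by-k score matrix from [pca_embed()] (k >= 2).
#' @param coords coordinate data.frame (`spot_id`, `row`, `col`).
#' @param neighbor_scheme `"grid4"` (rook), `"grid8"` (queen) or `"hex6"`
#'   (odd-row-offset hexagonal, the Visium arrangement).
#' @return An object of class `spot_graph`: list with `spot_ids` and an
#'   `edges` data.frame (`u`, `v`, `weight`).
#' @export
build_spot_graph <- function(embedding, coords,
                             neighbor_scheme = c("grid4", "grid8", "hex6")) {
  neighbor_scheme <- match.arg(neighbor_scheme)
  if (nrow(embedding) < 2) .stopf("need at least 2 spots to build a graph")
  if (ncol(embedding) < 2)
    .stopf("embedding must have >= 2 dimensions for a correlation weight")
  key <- paste(coords$row, coords$col)
  pos <- stats::setNames(seq_along(key), key)
  us <- integer(0); vs <- integer(0)
  parities <- if (neighbor_scheme == "hex6") c(0, 1) else 0
  for (par in parities) {
    offs <- .neighbor_offsets(neighbor_scheme, par)
    rows_sel <- if (neighbor_scheme == "hex6")
      which(coords$row %% 2 == par) else seq_len(nrow(coords))
    for (j in seq_len(ncol(offs))) {
      nk <- paste(coords$row[rows_sel] + offs[1, j],
                  coords$col[rows_sel] + offs[2, j])
      hit <- pos[nk]
      keep <- !is.na(hit)
      us <- c(us, rows_sel[keep])
      vs <- c(vs, unname(hit[keep]))
    }
  }
  E <- embedding - rowMeans(embedding)
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- Inf
  En <- E / nrm
  w <- rowSums(En[us, , drop = FALSE] * En[vs, , drop = FALSE])
  w <- pmin(pmax(w, -1), 1)
  structure(list(spot_ids = as.character(coords$spot_id),
                 edges = data.frame(u = coords$spot_id[us],
                                    v = coords$spot_id[vs],
                                    weight = w,
                                    stringsAsFactors = FALSE),
                 neighbor_scheme = neighbor_scheme),
            class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("spot_graph (%s): %d spots, %d edges, weights in [%.3f, %.3f]\n",
              x$neighbor_scheme, length(x$spot_ids), nrow(x$edges),
              min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

.components_at <- function(graph, epsilon) {
  keep <- graph$edges$weight >= epsilon
  g <- igraph::graph_from_data_frame(graph$edges[keep, c("u", "v")],
                                     directed = FALSE,
                                     vertices = graph$spot_ids)
  comp <- igraph::components(g)
  stats::setNames(comp$membership[graph$spot_ids], graph$spot_ids)
}

#' Auto-select the edge-weight threshold epsilon
#'
#' Scans candidate thresholds (percentiles 50-99 of the edge weights by
#' default). For each candidate, the coverage is the fraction of spots that
#' end up in connected components of size >= `m` after dropping edges below
#' the threshold, and the region count is the number of such components.
#' Candidates achieving the maximal region count are preferred -- at too
#' low a threshold distinct regions merge through boundary spots, which is
#' far more damaging to the downstream pseudo-internal reference than a
#' split region (splits are re-merged by the region-to-type mapping).
#' Within those candidates, the selected epsilon is the largest one whose
#' coverage is within `coverage_tol` of their maximum coverage. If no
#' candidate yields two regions, the maximum-coverage candidate is
#' returned.
#'
#' @param graph a `spot_graph`.
#' @param m minimum region size (default 40).
#' @param epsilon_grid optional numeric vector of candidate thresholds.
#' @param coverage_tol coverage tolerance for the knee rule (default 0.05).
#' @return the selected epsilon (numeric scalar).
#' @export
select_epsilon <- function(graph, m = 40L, epsilon_grid = NULL,
                           coverage_tol = 0.05) {
  w <- graph$edges$weight
  if (!length(w)) .stopf("graph has no edges")
  if (diff(range(w)) == 0) {
    .warnf("all edge weights equal (%g); returning that weight", w[1])
    return(w[1])
  }
  if (is.null(epsilon_grid))
    epsilon_grid <- unique(stats::quantile(w, probs = seq(0.50, 0.99, 0.01),
                                           names = FALSE))
  n <- length(graph$spot_ids)
  stats_ <- vapply(epsilon_grid, function(eps) {
    memb <- .components_at(graph, eps)
    sizes <- table(memb)
    c(coverage = sum(sizes[sizes >= m]) / n, n_regions = sum(sizes >= m))
  }, numeric(2))
  coverage <- stats_["coverage", ]
  n_regions <- stats_["n_regions", ]
  if (max(n_regions) < 2) return(epsilon_grid[which.max(coverage)])
  sel <- n_regions == max(n_regions)
  best <- max(coverage[sel])
  max(epsilon_grid[sel & coverage >= best - coverage_tol])
}

#' Extract regions as large connected components
#'
#' Drops edges with weight below `epsilon`; connected components with at
#' least `m` spots become regions. Region ids are `R1`, `R2`, ... ordered
#' by decreasing size (ties broken by the smallest member position in the
#' input spot order); all other spots are `"unassigned"`.
#'
#' @param graph a `spot_graph`.
#' @param epsilon edge-weight threshold in \[-1, 1\].
#' @param m minimum region size (default 40).
#' @return An object of class `region_assignment`: list with `label`
#'   (named character vector per spot) and `region_sizes`.
#' @export
extract_regions <- function(graph, epsilon, m = 40L) {
  memb <- .components_at(graph, epsilon)
  sizes <- table(memb)
  big <- names(sizes)[sizes >= m]
  first_pos <- vapply(big, function(cid) min(which(memb == cid)), numeric(1))
  ord <- big[order(-as.integer(sizes[big]), first_pos)]
  label <- stats::setNames(rep("unassigned", length(memb)), names(memb))
  for (i in seq_along(ord))
    label[memb == ord[i]] <- paste0("R", i)
  region_sizes <- table(label[label != "unassigned"])
  structure(list(label = label,
                 region_sizes = stats::setNames(as.integer(region_sizes),
                                                names(region_sizes)),
                 epsilon = epsilon, m = as.integer(m)),
            class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("region_assignment: %d regions (%s), %d unassigned of %d spots (epsilon = %.3f, m = %d)\n",
              length(x$region_sizes),
              paste(sprintf("%s: %d", names(x$region_sizes), x$region_sizes),
                    collapse = ", "),
              sum(x$label == "unassigned"), length(x$label), x$epsilon, x$m))
  invisible(x)
}

#' Run the full region-extraction pipeline
#'
#' Convenience wrapper: [normalize_log()] then [pca_embed()] then
#' [build_spot_graph()], epsilon auto-selection (unless fixed in the
#' config), and [extract_regions()].
#'
#' @param spatial a [spatial_counts()] object.
#' @param config a [resort_config()].
#' @return a `region_assignment`.
#' @export
detect_regions <- function(spatial, config = resort_config()) {
  emb <- pca_embed(normalize_log(spatial), config$k_pcs)
  graph <- build_spot_graph(emb, spatial$coords, config$neighbor_scheme)
  eps <- if (is.null(config$epsilon))
    select_epsilon(graph, config$min_region_size) else config$epsilon
  extract_regions(graph, eps, config$min_region_size)
}

#' Rand index between two partitions
#'
#' Classic (unadjusted) Rand index: the fraction of spot pairs on which the
#' two partitions agree (either grouped together in both or separated in
#' both). Spots labeled `"unassigned"` or `NA` in either partition are
#' excluded pairwise-consistently.
#'
#' @param labels_a,labels_b named label vectors over the same spot set.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (!length(common)) .stopf("label vectors share no spots")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    .stopf("unnamed label vectors must have equal length")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b) &
    labels_a != "unassigned" & labels_b != "unassigned"
  a <- labels_a[keep]; b <- labels_b[keep]
  n <- length(a)
  if (n < 2) .stopf("need at least 2 jointly assigned spots")
  tab <- table(a, b)
  total <- choose(n, 2)
  (total + 2 * sum(choose(tab, 2)) - sum(choose(rowSums(tab), 2)) -
      sum(choose(colSums(tab), 2))) / total
}
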