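# Deconvolution: pseudo-internal reference construction from detected
# regions, signature matrices, per-spot non-negative least squares, and
# the two-step product estimator for finer cell types.

#' Build the pseudo-internal reference from detected regions
#'
#' Rows of the pseudo-internal reference are the expression profiles of
#' spots inside labeled regions only (unassigned spots -- likely mixtures
#' -- are left out), each carrying the region-level cell type its region
#' maps to. Several regions may map to the same region-level type; their
#' spots then share the merged label.
#'
#' @param spatial a [spatial_counts()] object.
#' @param assignment a `region_assignment` from [extract_regions()] /
#'   [detect_regions()].
#' @param region_type_map named character vector mapping region labels
#'   (`"R1"`, ...) to region-level cell types. Regions absent from the map
#'   are dropped.
#' @return An object of class `pseudo_reference`: list with `profiles`
#'   (spots by genes, same gene set and order as the ST sample), `label`
#'   (region-level type per row), `spot_ids` and `source`
#'   (`"pseudo-internal"`).
#' @export
build_pseudo_reference <- function(spatial, assignment, region_type_map) {
  lab <- assignment$label[spatial$spot_ids]
  keep <- lab != "unassigned" & lab %in% names(region_type_map)
  types <- unname(region_type_map[lab[keep]])
  absent <- setdiff(unique(region_type_map), types)
  if (length(absent))
    .stopf("region-level types with zero labeled spots: %s",
           paste(absent, collapse = ", "))
  structure(list(profiles = as.matrix(spatial$counts)[keep, , drop = FALSE],
                 label = types,
                 spot_ids = spatial$spot_ids[keep],
                 source = "pseudo-internal"),
            class = "pseudo_reference")
}

#' @export
print.pseudo_reference <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("pseudo_reference: %d spots x %d genes (%s)\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Mean of library-normalized profiles per label. The matrix keeps every
# gene; the union of each label's top-n one-vs-rest log-fold-change genes
# is recorded in attribute "genes" and is what the solvers fit on, so
# that later augmentation can extend the gene set.
.make_signatures <- function(profiles, labels, n_top_genes = 200L,
                             pseudo = 1e-8) {
  profiles <- as.matrix(profiles)
  lib <- rowSums(profiles)
  if (any(lib == 0)) .stopf("reference rows with zero library size")
  norm <- profiles / lib
  types <- sort(unique(labels))
  M <- t(vapply(types, function(ty)
    colMeans(norm[labels == ty, , drop = FALSE]), numeric(ncol(norm))))
  rownames(M) <- types
  attr(M, "genes") <- .top_lfc_genes(M, n_top_genes, pseudo)
  M
}

# Union over signature rows of the top-n one-vs-rest log-fold-change
# genes; NULL when no restriction applies.
.top_lfc_genes <- function(M, n_top_genes, pseudo = 1e-8,
                           rows = seq_len(nrow(M))) {
  if (nrow(M) < 2 || n_top_genes >= ncol(M)) return(NULL)
  sel <- unique(unlist(lapply(rows, function(i) {
    rest <- colMeans(M[-i, , drop = FALSE])
    lfc <- log2((M[i, ] + pseudo) / (rest + pseudo))
    order(lfc, decreasing = TRUE)[seq_len(n_top_genes)]
  })))
  colnames(M)[sort(sel)]
}

#' Fitted gene set of a signature matrix
#'
#' The marker gene set the solvers fit on: the `"genes"` attribute when
#' gene selection applied, otherwise all columns.
#'
#' @param signatures a signature matrix.
#' @return character vector of gene ids.
#' @export
signature_genes <- function(signatures) {
  g <- attr(signatures, "genes")
  if (is.null(g)) colnames(signatures) else g
}

# Deterministic farthest-point seeding for kmeans on profile rows.
.farthest_centers <- function(X, k) {
  d2mean <- rowSums(sweep(X, 2, colMeans(X))^2)
  idx <- which.max(d2mean)
  while (length(idx) < k) {
    d2 <- vapply(seq_len(nrow(X)), function(i)
      min(colSums((t(X[idx, , drop = FALSE]) - X[i, ])^2)), numeric(1))
    idx <- c(idx, which.max(d2))
  }
  X[idx, , drop = FALSE]
}

#' Expression signatures of the pseudo-internal reference
#'
#' Per region-level type, the mean of the library-size-normalized spot
#' profiles, restricted to the union of each type's top `n_top_genes`
#' one-vs-rest log-fold-change genes.
#'
#' With `k_sub > 1`, each region-level type is additionally split into
#' `k_sub` sub-profiles by k-means clustering of its spot profiles
#' (deterministic farthest-point seeding). The returned matrix then has
#' one row per sub-profile and carries the parent region-level type of
#' each row in attribute `"parent"`; the solvers in
#' [deconvolve_regions()] sum sub-profile coefficients back into parent
#' types. Sub-profiles absorb within-region expression heterogeneity
#' (e.g. several fine cell types sharing one region) that a single mean
#' profile would misattribute to other region-level types.
#'
#' @param omega a `pseudo_reference`.
#' @param n_top_genes genes kept per type (default 200); the union across
#'   types is used. With a single type, no selection is applied.
#' @param k_sub sub-profiles per region-level type (default 1: plain mean
#'   signatures).
#' @return signature matrix, (sub-)profiles by selected genes.
#' @export
region_profiles <- function(omega, n_top_genes = 200L, k_sub = 1L) {
  if (k_sub <= 1L)
    return(.make_signatures(omega$profiles, omega$label, n_top_genes))
  norm <- omega$profiles / rowSums(omega$profiles)
  types <- sort(unique(omega$label))
  rows <- list()
  parent <- character(0)
  for (ty in types) {
    X <- norm[omega$label == ty, , drop = FALSE]
    k <- min(k_sub, nrow(X))
    cl <- if (k == 1) rep(1L, nrow(X)) else
      stats::kmeans(X, centers = .farthest_centers(X, k))$cluster
    for (j in sort(unique(cl))) {
      rows[[paste0(ty, "#", j)]] <- colMeans(X[cl == j, , drop = FALSE])
      parent <- c(parent, ty)
    }
  }
  M <- do.call(rbind, rows)
  # gene selection on the parent-level means so sub-profiles share genes
  Mp <- .make_signatures(omega$profiles, omega$label, n_top_genes)
  attr(M, "genes") <- attr(Mp, "genes")
  attr(M, "parent") <- parent
  M
}

#' Signature matrix from a single-cell reference
#'
#' Same construction as [region_profiles()] but from labeled cells: mean
#' library-normalized expression per type (fine types, or fine types
#' grouped to region level), with the same marker-gene selection rule.
#'
#' @param ref a `single_cell_reference`.
#' @param level build signatures for `"region"`-level or `"fine"` types.
#' @param n_top_genes genes kept per type (default 200).
#' @param hierarchical if `TRUE` (only with `level = "fine"`), the
#'   signature matrix carries each fine type's region-level parent in
#'   attribute `"parent"`, so the solvers report region-level proportions
#'   from fine-type fits.
#' @return signature matrix, types by genes.
#' @export
signature_matrix <- function(ref, level = c("region", "fine"),
                             n_top_genes = 200L, hierarchical = FALSE) {
  level <- match.arg(level)
  labels <- if (level == "region") region_of_cells(ref) else ref$fine_type
  M <- .make_signatures(ref$counts, labels, n_top_genes)
  if (hierarchical) {
    if (level != "fine") .stopf("hierarchical signatures require level = 'fine'")
    attr(M, "parent") <- unname(ref$region_type_of[rownames(M)])
  }
  M
}

#' Append externally derived type profiles to a signature matrix
#'
#' Cell types that never form a spatial region (e.g. infiltrating immune
#' cells) cannot enter the pseudo-internal reference; their mean profiles
#' are taken from an external single-cell reference instead. The fitted
#' gene set is extended with the appended types' own top one-vs-rest
#' marker genes (computed within the external reference), without which
#' the appended types would be fitted blind to their markers.
#'
#' @param signatures signature matrix (types by genes), e.g. from
#'   [region_profiles()].
#' @param ref external `single_cell_reference` supplying the extra types.
#' @param types region-level types of `ref` to append.
#' @param n_top_genes marker genes added per appended type (default 200).
#' @return the extended signature matrix.
#' @export
augment_signatures <- function(signatures, ref, types, n_top_genes = 200L) {
  labels <- region_of_cells(ref)
  missing <- setdiff(types, unique(labels))
  if (length(missing))
    .stopf("reference has no cells of type(s): %s",
           paste(missing, collapse = ", "))
  full <- .make_signatures(ref$counts, labels, n_top_genes = ncol(ref$counts))
  genes <- intersect(colnames(signatures), colnames(full))
  if (!length(genes)) .stopf("signature gene sets do not intersect")
  out <- rbind(signatures[, genes, drop = FALSE],
               full[types, genes, drop = FALSE])
  extra <- .top_lfc_genes(full, n_top_genes,
                          rows = match(types, rownames(full)))
  sel <- attr(signatures, "genes")
  if (!is.null(sel) || !is.null(extra))
    attr(out, "genes") <- intersect(colnames(out),
                                    union(if (is.null(sel)) colnames(signatures) else sel,
                                          extra))
  parent <- attr(signatures, "parent")
  if (!is.null(parent)) attr(out, "parent") <- c(parent, types)
  out
}

.nnls_proportions <- function(counts, signatures, genes) {
  S <- t(signatures[, genes, drop = FALSE])
  Y <- matrix(0, nrow(counts), nrow(signatures),
              dimnames = list(rownames(counts), rownames(signatures)))
  lib <- rowSums(counts)
  degenerate <- character(0)
  for (s in seq_len(nrow(counts))) {
    if (lib[s] == 0) {
      degenerate <- c(degenerate, rownames(counts)[s])
      Y[s, ] <- 1 / ncol(Y)
      next
    }
    y <- counts[s, genes] / lib[s]
    x <- pracma::lsqnonneg(S, y)$x
    if (sum(x) == 0) {
      degenerate <- c(degenerate, rownames(counts)[s])
      Y[s, ] <- 1 / ncol(Y)
    } else {
      Y[s, ] <- x / sum(x)
    }
  }
  if (length(degenerate))
    .warnf("%d spot(s) had an all-zero solution; set to uniform proportions (%s%s)",
           length(degenerate), paste(utils::head(degenerate, 3), collapse = ", "),
           if (length(degenerate) > 3) ", ..." else "")
  Y
}

# Multinomial maximum-likelihood mixture weights via EM. Each spot's
# counts over the signature genes are modeled as Multinomial(L_s,
# sum_k p_k S_k). After convergence the estimate is shrunk toward the
# uniform composition by `prior_cells` cell equivalents: with c =
# cells_per_spot cells per spot, proportions below 1/c carry no
# information, so p <- (p + f) / (1 + K f) with f = prior_cells / (c K).
# This keeps every component strictly positive at about the spot's cell
# granularity instead of the exact zeros the boundary of the simplex
# would otherwise produce.
.mle_proportions <- function(counts, signatures, genes, max_iter = 1000L,
                             tol = 1e-9) {
  Sn <- signatures[, genes, drop = FALSE]
  Sn <- Sn / rowSums(Sn)
  K <- nrow(Sn)
  cnt <- counts[, genes, drop = FALSE]
  lib <- rowSums(cnt)
  zero <- lib == 0
  P <- matrix(1 / K, nrow(cnt), K,
              dimnames = list(rownames(counts), rownames(Sn)))
  tS <- t(Sn)
  for (i in seq_len(max_iter)) {
    denom <- P %*% Sn
    P_new <- P * ((cnt / pmax(denom, 1e-300)) %*% tS)
    P_new <- P_new / rowSums(P_new)
    if (any(zero)) P_new[zero, ] <- 1 / K
    if (max(abs(P_new - P)) < tol) {
      P <- P_new
      break
    }
    P <- P_new
  }
  if (any(zero))
    .warnf("%d spot(s) with zero library on the signature genes; set to uniform",
           sum(zero))
  P
}

# Sum proportion columns of sub-profiles into their parent types when the
# signature matrix carries a "parent" attribute (see region_profiles()).
.aggregate_parent <- function(Y, signatures) {
  parent <- attr(signatures, "parent")
  if (is.null(parent)) return(Y)
  out <- vapply(unique(parent), function(ty)
    rowSums(Y[, parent == ty, drop = FALSE]), numeric(nrow(Y)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(Y))
  dimnames(out) <- list(rownames(Y), unique(parent))
  out
}

.solve_proportions <- function(counts, signatures, level,
                               method = c("nnls", "mle"), prior_cells = 0.5,
                               cells_per_spot = 10L, ...) {
  method <- match.arg(method)
  genes <- intersect(signature_genes(signatures), colnames(counts))
  if (!length(genes))
    .stopf("no genes shared between the sample and the signatures")
  Y <- switch(method,
              nnls = .nnls_proportions(counts, signatures, genes),
              mle = .mle_proportions(counts, signatures, genes, ...))
  Y <- .aggregate_parent(Y, signatures)
  if (method == "mle") {
    f <- prior_cells / (cells_per_spot * ncol(Y))
    Y <- (Y + f) / (1 + ncol(Y) * f)
  }
  proportion_matrix(Y, level = level, tol = 1e-8)
}

#' Region-level deconvolution against a signature matrix
#'
#' For every spot, decomposes the expression profile over the signature
#' gene set into region-level type proportions. Two backends:
#'
#' * `"nnls"` (default): non-negative least squares on the
#'   library-normalized profile, coefficients renormalized to sum to one.
#'   Recovers noiseless signature mixtures exactly; on noisy counts it can
#'   return exact zeros for minor components.
#' * `"mle"`: multinomial maximum likelihood fitted by EM to convergence.
#'   The likelihood weighting suits sparse counts; afterwards the estimate
#'   is shrunk toward the uniform composition by `prior_cells` cell
#'   equivalents, acknowledging that proportions below one cell per spot
#'   (of `cells_per_spot`) are not identifiable. Estimates therefore stay
#'   strictly positive -- the appropriate backend when results are scored
#'   by divergence measures.
#'
#' If the signature matrix carries sub-profiles (attribute `"parent"`,
#' see [region_profiles()] with `k_sub > 1`), coefficients are estimated
#' per sub-profile and summed into parent types before any shrinkage.
#' Spots with an all-zero solution (or empty library) fall back to
#' uniform proportions with a warning.
#'
#' @param spatial a [spatial_counts()] object.
#' @param signatures signature matrix (region-level types by genes), e.g.
#'   from [region_profiles()] on the pseudo-internal reference.
#' @param method `"nnls"` or `"mle"`.
#' @param prior_cells shrinkage strength of the `"mle"` backend in cell
#'   equivalents (default 0.5; ignored by `"nnls"`).
#' @param cells_per_spot cell granularity of a spot used for the
#'   shrinkage (default 10).
#' @param ... passed to the `"mle"` backend: `max_iter` (1000), `tol`
#'   (1e-9).
#' @return a region-level [proportion_matrix()].
#' @export
deconvolve_regions <- function(spatial, signatures,
                               method = c("nnls", "mle"), prior_cells = 0.5,
                               cells_per_spot = 10L, ...) {
  if (nrow(signatures) < 2) .stopf("need at least 2 region-level types")
  .solve_proportions(as.matrix(spatial$counts), signatures, level = "region",
                     method = method, prior_cells = prior_cells,
                     cells_per_spot = cells_per_spot, ...)
}

#' Within-region fine-type proportions from an external reference
#'
#' For one region-level type `T`, estimates each spot's composition over
#' the fine types that map to `T`, using fine-type signatures built from
#' the external reference restricted to those types; proportions are
#' renormalized to sum to one within the block. With a single fine type
#' the block is the constant 1.
#'
#' @param spatial a [spatial_counts()] object.
#' @param ext_ref external `single_cell_reference` (the source of
#'   fine-type expression).
#' @param region_type the region-level type `T` whose subtypes are
#'   estimated.
#' @param n_top_genes marker genes per fine type (default 200).
#' @param method,... solver backend, as in [deconvolve_regions()].
#' @return a [proportion_matrix()] over the subtypes of `region_type`
#'   (level `"fine"`).
#' @export
within_region_proportions <- function(spatial, ext_ref, region_type,
                                      n_top_genes = 200L,
                                      method = c("nnls", "mle"), ...) {
  fine <- names(ext_ref$region_type_of)[ext_ref$region_type_of == region_type]
  fine <- intersect(fine, unique(ext_ref$fine_type))
  if (!length(fine))
    .stopf("external reference has no fine types mapping to '%s'", region_type)
  if (length(fine) == 1) {
    Y <- matrix(1, nrow(spatial$counts), 1,
                dimnames = list(spatial$spot_ids, fine))
    return(proportion_matrix(Y, level = "fine"))
  }
  cells <- ext_ref$fine_type %in% fine
  sig <- .make_signatures(ext_ref$counts[cells, , drop = FALSE],
                          ext_ref$fine_type[cells], n_top_genes)
  .solve_proportions(as.matrix(spatial$counts), sig, level = "fine",
                     method = method, ...)
}

#' Two-step fine-type proportions (product estimator)
#'
#' Combines region-level estimates with within-region fine-type estimates:
#' the proportion of fine type `t` with region-level parent `T` is the
#' product of the spot's region-level proportion of `T` and its
#' within-`T` proportion of `t`. Because both factors are row-normalized,
#' the full fine-level rows sum to one by construction.
#'
#' @param region_props region-level [proportion_matrix()].
#' @param within_props named list, one entry per region-level type, each a
#'   [proportion_matrix()] over that type's fine types (from
#'   [within_region_proportions()]). Region-level types absent from the
#'   list are carried through as a single fine type of the same name.
#' @return a fine-level [proportion_matrix()].
#' @export
deconvolve_fine <- function(region_props, within_props) {
  absent <- setdiff(names(within_props), colnames(region_props))
  if (length(absent))
    .stopf("fine-type blocks whose region-level parent is absent: %s",
           paste(absent, collapse = ", "))
  blocks <- lapply(colnames(region_props), function(ty) {
    w <- within_props[[ty]]
    if (is.null(w)) {
      w <- matrix(1, nrow(region_props), 1,
                  dimnames = list(rownames(region_props), ty))
    }
    wm <- unclass(w)
    if (!is.null(rownames(region_props)) && !is.null(rownames(wm)))
      wm <- wm[rownames(region_props), , drop = FALSE]
    wm * region_props[, ty]
  })
  Y <- do.call(cbind, blocks)
  proportion_matrix(Y, level = "fine", tol = 1e-8)
}

#' Export the pseudo-internal reference for external tools
#'
#' Writes the pseudo-internal reference as a labeled single-cell-style
#' reference (matrix + cell labels + identity grouping) in matrix-market
#' or CSV form, so that external deconvolution tools can consume it in
#' place of a single-cell reference. The written triplet round-trips
#' through [read_reference()].
#'
#' @param omega a `pseudo_reference`.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"csv"`.
#' @return invisibly, the paths written (`matrix`, `labels`, `grouping`).
#' @export
export_reference <- function(omega, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path_matrix <- file.path(dir, paste0("omega.", format))
  path_labels <- file.path(dir, "omega_labels.tsv")
  path_grouping <- file.path(dir, "omega_grouping.tsv")
  .write_matrix_auto(omega$profiles, path_matrix)
  utils::write.table(data.frame(cell_id = omega$spot_ids,
                                fine_type = omega$label),
                     path_labels, sep = "\t", quote = FALSE, row.names = FALSE)
  types <- unique(omega$label)
  utils::write.table(data.frame(fine_type = types, region_type = types),
                     path_grouping, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = path_matrix, labels = path_labels,
              grouping = path_grouping))
}

#' Map detected regions to region-level types via simulation ground truth
#'
#' In simulation studies the generating composition is known, so each
#' detected region can be annotated automatically with the majority
#' ground-truth type (argmax of the true proportions) of its spots. On
#' real data this mapping is supplied by the analyst instead.
#'
#' @param assignment a `region_assignment`.
#' @param truth ground-truth [proportion_matrix()] (region level).
#' @return named character vector mapping region labels to region-level
#'   types, suitable for [build_pseudo_reference()].
#' @export
map_regions_by_truth <- function(assignment, truth) {
  regions <- names(assignment$region_sizes)
  argmax <- colnames(truth)[max.col(unclass(truth), ties.method = "first")]
  names(argmax) <- rownames(truth)
  vapply(stats::setNames(regions, regions), function(r) {
    spots <- names(assignment$label)[assignment$label == r]
    names(which.max(table(argmax[spots])))
  }, character(1))
}
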