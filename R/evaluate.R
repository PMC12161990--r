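# Evaluation battery: per-spot Pearson correlation and KL divergence
# against ground truth, infiltration classification with weighted F1, and
# microenvironment stratification of mixture spots.

.align_props <- function(p_true, p_est) {
  if (!setequal(colnames(p_true), colnames(p_est)))
    .stopf("type sets differ: truth has {%s}, estimate has {%s}",
           paste(colnames(p_true), collapse = ", "),
           paste(colnames(p_est), collapse = ", "))
  if (nrow(p_true) != nrow(p_est)) .stopf("spot sets differ in size")
  p_est <- p_est[, colnames(p_true), drop = FALSE]
  if (!is.null(rownames(p_true)) && !is.null(rownames(p_est))) {
    if (!setequal(rownames(p_true), rownames(p_est)))
      .stopf("spot sets differ")
    p_est <- p_est[rownames(p_true), , drop = FALSE]
  }
  list(truth = unclass(p_true), est = unclass(p_est))
}

#' Per-spot Pearson correlation between proportion matrices
#'
#' The correlation of the true and estimated proportion vectors of each
#' spot. Spots whose true or estimated vector is constant have undefined
#' correlation and are returned as `NA` (excluded from summaries).
#'
#' @param p_true,p_est [proportion_matrix()] objects over the same spots
#'   and types (at least 2 types).
#' @return named numeric vector of per-spot correlations.
#' @export
pearson_per_spot <- function(p_true, p_est) {
  al <- .align_props(p_true, p_est)
  if (ncol(al$truth) < 2) .stopf("need at least 2 types for a correlation")
  ct <- al$truth - rowMeans(al$truth)
  ce <- al$est - rowMeans(al$est)
  st <- sqrt(rowSums(ct^2))
  se <- sqrt(rowSums(ce^2))
  rho <- rowSums(ct * ce) / (st * se)
  rho[st == 0 | se == 0] <- NA_real_
  stats::setNames(pmin(pmax(rho, -1), 1), rownames(al$truth))
}

#' Per-spot Kullback-Leibler divergence
#'
#' `KL(truth || estimate)` per spot, after adding a pseudo-count to every
#' entry of both rows and renormalizing, which keeps the divergence finite
#' when the estimate puts zero mass on a type the truth supports.
#'
#' @param p_true,p_est [proportion_matrix()] objects over the same spots
#'   and types.
#' @param pseudo pseudo-count added before renormalization (default 1e-9).
#' @return named numeric vector of per-spot divergences (natural log).
#' @export
kl_per_spot <- function(p_true, p_est, pseudo = 1e-9) {
  al <- .align_props(p_true, p_est)
  if (min(al$truth) < 0 || min(al$est) < 0)
    .stopf("proportions must be non-negative")
  p <- al$truth + pseudo
  q <- al$est + pseudo
  p <- p / rowSums(p)
  q <- q / rowSums(q)
  stats::setNames(rowSums(p * log(p / q)), rownames(al$truth))
}

#' Per-spot metric table
#'
#' Convenience wrapper computing both per-spot metrics and their
#' summaries.
#'
#' @inheritParams kl_per_spot
#' @return data.frame with columns `spot_id`, `pearson`, `kl`; summary
#'   statistics (means, medians, number of undefined correlations) are
#'   attached as attribute `"summary"`.
#' @export
spot_metrics <- function(p_true, p_est, pseudo = 1e-9) {
  rho <- pearson_per_spot(p_true, p_est)
  kl <- kl_per_spot(p_true, p_est, pseudo)
  out <- data.frame(spot_id = names(kl), pearson = unname(rho),
                    kl = unname(kl), stringsAsFactors = FALSE)
  attr(out, "summary") <- list(
    mean_pearson = mean(rho, na.rm = TRUE),
    median_pearson = stats::median(rho, na.rm = TRUE),
    mean_kl = mean(kl), median_kl = stats::median(kl),
    n_undefined_pearson = sum(is.na(rho)))
  out
}

.f1 <- function(tp, fp, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' Classify tumor spots as immune-infiltrated vs pure
#'
#' Within the tumor-region spots, a spot is called infiltrated when its
#' estimated immune proportion is at or above `threshold`. Per-class
#' precision, recall and F1 are computed for both classes, together with
#' the weighted F1 (class F1 scores weighted by their true relative
#' sizes), appropriate for the imbalanced two-class problem.
#'
#' @param p_est estimated [proportion_matrix()] containing an
#'   `immune_type` column.
#' @param immune_type name of the immune column.
#' @param truth_mask named logical vector: `TRUE` for truly infiltrated
#'   spots.
#' @param cancer_mask named logical vector: `TRUE` for spots in the tumor
#'   region (the classification universe).
#' @param threshold immune-proportion call threshold in (0, 1\]; default
#'   0.05, i.e. spots with less than 5% estimated immune content count as
#'   pure.
#' @return An object of class `infiltration_report`: list with the
#'   per-class table (`classes`), `weighted_f1`, `threshold` and the
#'   confusion counts.
#' @export
classify_infiltration <- function(p_est, immune_type, truth_mask,
                                  cancer_mask, threshold = 0.05) {
  if (!immune_type %in% colnames(p_est))
    .stopf("estimate has no '%s' column", immune_type)
  spots <- rownames(p_est)
  if (is.null(spots)) spots <- names(cancer_mask)
  universe <- spots[cancer_mask[spots]]
  if (!length(universe)) .stopf("cancer mask selects no spots")
  pred <- p_est[universe, immune_type] >= threshold
  truth <- truth_mask[universe]
  tab <- list(
    infiltrated = .f1(sum(pred & truth), sum(pred & !truth),
                      sum(!pred & truth)),
    pure = .f1(sum(!pred & !truth), sum(!pred & truth),
               sum(pred & !truth)))
  sizes <- c(infiltrated = sum(truth), pure = sum(!truth))
  weighted_f1 <- sum(vapply(names(tab), function(cl)
    tab[[cl]]["f1"] * sizes[cl] / length(universe), numeric(1)))
  structure(list(classes = do.call(rbind, tab), class_sizes = sizes,
                 weighted_f1 = unname(weighted_f1), threshold = threshold,
                 n = length(universe)),
            class = "infiltration_report")
}

#' @export
print.infiltration_report <- function(x, ...) {
  cat(sprintf("infiltration_report (threshold %.2f, n = %d):\n",
              x$threshold, x$n))
  print(round(x$classes, 4))
  cat(sprintf("weighted F1: %.4f\n", x$weighted_f1))
  invisible(x)
}

#' Stratify spots into pure and mixture categories
#'
#' A spot is `"pure-<type>"` when its largest proportion reaches
#' `pure_threshold`; otherwise, if its top two types both reach
#' `mix_threshold`, it is a `"<X>-<Y> mixture"` (types ordered by column
#' position); remaining spots are `"other"`.
#'
#' @param p_est a [proportion_matrix()].
#' @param pure_threshold minimum max-proportion for a pure call (default
#'   0.9).
#' @param mix_threshold minimum proportion for both partners of a mixture
#'   call (default 0.1).
#' @return named character vector of categories.
#' @export
stratify_spots <- function(p_est, pure_threshold = 0.9, mix_threshold = 0.1) {
  m <- unclass(p_est)
  out <- vapply(seq_len(nrow(m)), function(s) {
    v <- m[s, ]
    top <- order(v, decreasing = TRUE)[1:2]
    if (v[top[1]] >= pure_threshold) {
      paste0("pure-", colnames(m)[top[1]])
    } else if (v[top[2]] >= mix_threshold) {
      pair <- sort(top)
      sprintf("%s-%s mixture", colnames(m)[pair[1]], colnames(m)[pair[2]])
    } else {
      "other"
    }
  }, character(1))
  stats::setNames(out, rownames(m))
}

#' Split a mixture category by a region boundary
#'
#' Divides the spots of one stratification category into
#' `"infiltrated"` (inside the named region's spot set, i.e. within the
#' tumor boundary) and `"peripheral"` (outside); all other spots keep
#' their category.
#'
#' @param categories named character vector from [stratify_spots()].
#' @param category the mixture category to split.
#' @param inside_spots character vector of spot ids inside the region
#'   boundary (e.g. spots of the tumor region in a `region_assignment`).
#' @return updated named character vector.
#' @export
split_mixture <- function(categories, category, inside_spots) {
  if (!category %in% categories)
    .stopf("no spots in category '%s'", category)
  sel <- categories == category
  categories[sel] <- ifelse(names(categories)[sel] %in% inside_spots,
                            "infiltrated", "peripheral")
  categories
}
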