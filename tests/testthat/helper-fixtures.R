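# Shared fixtures and independent oracles used across the test files.

# Small deterministic single-cell reference: 3 fine types -> 2 region
# types, 60 genes, identical counts for every cell of a type when
# deterministic = TRUE (handy for exact expression checks).
tiny_ref <- function(cells_per_type = 8, n_genes = 60,
                     deterministic = FALSE, seed = 42) {
  set.seed(seed)
  grouping <- c(a1 = "A", a2 = "A", b1 = "B")
  fine <- rep(names(grouping), each = cells_per_type)
  if (deterministic) {
    base <- t(vapply(seq_along(grouping), function(i) {
      v <- rep(1L, n_genes)
      v[((i - 1) * 10 + 1):(i * 10)] <- 20L
      v
    }, integer(n_genes)))
    counts <- base[rep(seq_along(grouping), each = cells_per_type), ]
  } else {
    counts <- matrix(rpois(length(fine) * n_genes, 2),
                     nrow = length(fine))
    for (i in seq_along(grouping))
      counts[fine == names(grouping)[i], ((i - 1) * 10 + 1):(i * 10)] <-
        rpois(cells_per_type * 10, 20)
  }
  dimnames(counts) <- list(paste0("c", seq_along(fine)),
                           paste0("g", seq_len(n_genes)))
  single_cell_reference(counts, fine, grouping)
}

# Random small spatial_counts on a grid.
random_spatial <- function(n_rows = 4, n_cols = 5, n_genes = 7, seed = 1) {
  set.seed(seed)
  coords <- expand.grid(col = seq_len(n_cols) - 1L,
                        row = seq_len(n_rows) - 1L)
  coords <- data.frame(spot_id = sprintf("s%d_%d", coords$row, coords$col),
                       row = coords$row, col = coords$col)
  counts <- matrix(rpois(nrow(coords) * n_genes, 5), nrow = nrow(coords),
                   dimnames = list(coords$spot_id,
                                   paste0("g", seq_len(n_genes))))
  spatial_counts(counts, coords)
}

# Independent connected-components oracle: iterative flood fill over an
# adjacency list, no igraph involved.
flood_fill_components <- function(nodes, edges_u, edges_v) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_u)) {
    adj[[edges_u[i]]] <- c(adj[[edges_u[i]]], edges_v[i])
    adj[[edges_v[i]]] <- c(adj[[edges_v[i]]], edges_u[i])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(comp[nb])) {
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

# Partitions agree iff they induce the same grouping (up to label names).
same_partition <- function(a, b) {
  a <- as.integer(factor(a, levels = unique(a)))
  b <- as.integer(factor(b, levels = unique(b)))
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Confusion-matrix oracle for binary precision/recall/F1.
confusion_f1 <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
}
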