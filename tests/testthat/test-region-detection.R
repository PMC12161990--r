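test_that("normalization is library-size invariant and log-scaled", {
  # equal libraries across spots so the median scale stays fixed
  sp <- random_spatial(n_rows = 3, n_cols = 3, n_genes = 8)
  base <- as.integer(sp$counts[1, ])
  for (i in seq_len(9)) sp$counts[i, ] <- sample(base)
  norm <- normalize_log(sp)
  # tripling one spot's counts leaves its normalized profile unchanged
  sp2 <- sp
  sp2$counts[2, ] <- sp$counts[2, ] * 3L
  expect_equal(normalize_log(sp2)[2, ], norm[2, ])
  # all-equal counts across genes give an all-equal profile
  sp3 <- sp
  sp3$counts[1, ] <- 4L
  expect_equal(length(unique(normalize_log(sp3)[1, ])), 1L)
  sp$counts[5, ] <- 0L
  expect_error(normalize_log(sp), "zero library")
})

test_that("PCA embedding is deterministic, ordered, and faithful", {
  set.seed(8)
  base <- matrix(rnorm(30), 3, 10)
  expr <- base[rep(1:3, each = 4), ]   # rank 2 after centering
  emb <- pca_embed(expr, 2)
  expect_gte(var(emb[, 1]), var(emb[, 2]))
  # rank-2 data reconstructs exactly from 2 PCs
  rec <- emb %*% t(attr(emb, "rotation"))
  centered <- scale(expr, scale = FALSE)
  expect_lt(max(abs(rec - centered)), 1e-10)
  # duplicated rows embed identically
  emb2 <- pca_embed(expr, 2)
  expect_equal(emb2[1, ], emb2[2, ])
  expect_error(pca_embed(expr, 99), "k_pcs")
})

test_that("the spot graph connects neighbors with correlation weights", {
  coords <- expand.grid(col = 0:4, row = 0:4)
  coords <- data.frame(spot_id = sprintf("s%d_%d", coords$row, coords$col),
                       row = coords$row, col = coords$col)
  set.seed(3)
  emb <- matrix(rnorm(25 * 4), 25)
  g <- build_spot_graph(emb, coords, "grid4")
  deg <- table(c(g$edges$u, g$edges$v))
  expect_equal(unname(deg[["s2_2"]]), 4L)   # interior spot
  expect_equal(unname(deg[["s0_0"]]), 2L)   # corner spot
  expect_true(all(g$edges$weight >= -1 & g$edges$weight <= 1))
  g8 <- build_spot_graph(emb, coords, "grid8")
  deg8 <- table(c(g8$edges$u, g8$edges$v))
  expect_equal(unname(deg8[["s2_2"]]), 8L)

  # identical embeddings correlate at 1, opposite embeddings at -1
  emb2 <- emb
  emb2[2, ] <- emb2[1, ]
  emb2[6, ] <- -emb2[1, ]   # s1_0, below s0_0
  g2 <- build_spot_graph(emb2, coords, "grid4")
  w <- g2$edges$weight
  key <- paste(g2$edges$u, g2$edges$v)
  expect_equal(w[key == "s0_0 s0_1"], 1)
  expect_equal(w[key == "s0_0 s1_0"], -1)
})

test_that("hex adjacency yields six neighbors for interior spots", {
  coords <- expand.grid(col = 0:4, row = 0:4)
  coords <- data.frame(spot_id = sprintf("s%d_%d", coords$row, coords$col),
                       row = coords$row, col = coords$col)
  set.seed(4)
  g <- build_spot_graph(matrix(rnorm(50), 25), coords, "hex6")
  deg <- table(c(g$edges$u, g$edges$v))
  expect_equal(unname(deg[["s2_2"]]), 6L)
})

test_that("epsilon selection behaves on degenerate and structured graphs", {
  coords <- data.frame(spot_id = c("a", "b", "c"), row = 0:2, col = 0L)
  emb <- matrix(rep(c(1, 2, 3), 4), 3)
  g <- build_spot_graph(emb, coords, "grid4")
  expect_warning(eps <- select_epsilon(g, m = 1), "equal")
  expect_equal(eps, g$edges$weight[1])

  # retained edge count is non-increasing in epsilon
  set.seed(9)
  sp <- random_spatial(6, 6, 12, seed = 9)
  g2 <- build_spot_graph(pca_embed(normalize_log(sp), 4), sp$coords)
  kept <- vapply(seq(-1, 1, 0.1), function(e)
    sum(g2$edges$weight >= e), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("two orthogonal blocks are separated and fully recovered", {
  sc <- scenario("two-block-regions", n_rows = 10, n_cols = 10, seed = 5)
  cfg <- resort_config(min_region_size = 10)
  asn <- detect_regions(sc$noiseless_spatial, cfg)
  expect_equal(length(asn$region_sizes), 2L)
  expect_equal(sum(asn$label == "unassigned"), 0L)
  truth <- setNames(ifelse(sc$layout$masks$blockA, "A", "B"),
                    sc$layout$coords$spot_id)
  expect_equal(rand_index(asn$label, truth), 1)
})

test_that("extracted components match an independent flood fill", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    nodes <- paste0("n", seq_len(n))
    n_edges <- sample(5:80, 1)
    eu <- sample(nodes, n_edges, replace = TRUE)
    ev <- sample(nodes, n_edges, replace = TRUE)
    keep <- eu != ev
    g <- structure(list(spot_ids = nodes,
                        edges = data.frame(u = eu[keep], v = ev[keep],
                                           weight = 1)),
                   class = "spot_graph")
    asn <- extract_regions(g, epsilon = 0, m = 1)
    oracle <- flood_fill_components(nodes, eu[keep], ev[keep])
    expect_true(same_partition(asn$label[nodes], oracle[nodes]))
  }
})

test_that("the minimum-size rule controls which spots are assigned", {
  # a 39-spot clique and a 41-spot clique
  mk_clique <- function(tag, n) {
    nodes <- paste0(tag, seq_len(n))
    pairs <- t(combn(nodes, 2))
    list(nodes = nodes, u = pairs[, 1], v = pairs[, 2])
  }
  a <- mk_clique("a", 39)
  b <- mk_clique("b", 41)
  g <- structure(list(spot_ids = c(a$nodes, b$nodes),
                      edges = data.frame(u = c(a$u, b$u), v = c(a$v, b$v),
                                         weight = 0.9)),
                 class = "spot_graph")
  asn <- extract_regions(g, epsilon = 0.5, m = 40)
  expect_true(all(asn$label[a$nodes] == "unassigned"))
  expect_true(all(asn$label[b$nodes] == "R1"))
  asn1 <- extract_regions(g, epsilon = 0.5, m = 1)
  expect_true(all(asn1$label != "unassigned"))
  # raising m never increases the number of labeled spots
  n_labeled <- vapply(c(1, 10, 39, 40, 42), function(m)
    sum(extract_regions(g, 0.5, m)$label != "unassigned"), integer(1))
  expect_true(all(diff(n_labeled) <= 0))
})

test_that("region labels are stable under spot-row permutation", {
  sc <- scenario("two-block-regions", n_rows = 8, n_cols = 8, seed = 6)
  cfg <- resort_config(min_region_size = 5)
  asn <- detect_regions(sc$noiseless_spatial, cfg)
  perm <- sample(seq_len(64))
  sp2 <- spatial_counts(sc$noiseless_spatial$counts[perm, ],
                        sc$noiseless_spatial$coords[perm, ])
  asn2 <- detect_regions(sp2, cfg)
  common <- names(asn$label)
  expect_true(same_partition(asn$label[common], asn2$label[common]))
})

test_that("the Rand index counts pair agreements", {
  expect_equal(rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(rand_index(c("a", "a", "b", "b"), c("a", "b", "a", "b")),
               1 / 3)
  expect_equal(rand_index(rep("p", 5), rep("q", 5)), 1)
  # unassigned spots are excluded pairwise-consistently
  a <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "unassigned")
  b <- c(s1 = "x", s2 = "x", s3 = "y", s4 = "y")
  expect_equal(rand_index(a, b), 1)
  expect_error(rand_index(c(x = "a"), c(y = "b")), "share no spots")
})

test_that("the Rand index agrees with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (rep in 1:10) {
    a <- sample(letters[1:4], 30, replace = TRUE)
    b <- sample(letters[1:3], 30, replace = TRUE)
    expect_equal(rand_index(a, b),
                 e1071::classAgreement(table(a, b))$rand)
  }
})
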