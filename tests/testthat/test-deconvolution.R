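# A tiny two-region assignment over a random spatial sample.
toy_assignment <- function(sp, n_a = 6) {
  lab <- setNames(rep("unassigned", length(sp$spot_ids)), sp$spot_ids)
  lab[1:n_a] <- "R1"
  lab[(n_a + 1):(2 * n_a)] <- "R2"
  structure(list(label = lab,
                 region_sizes = c(R1 = n_a, R2 = n_a)),
            class = "region_assignment")
}

test_that("the pseudo-internal reference keeps only labeled region spots", {
  sp <- random_spatial(5, 5, 12, seed = 21)
  asn <- toy_assignment(sp, 6)
  omega <- build_pseudo_reference(sp, asn, c(R1 = "tumor", R2 = "stroma"))
  expect_equal(nrow(omega$profiles), 12)
  expect_identical(colnames(omega$profiles), sp$gene_ids)
  expect_identical(omega$source, "pseudo-internal")
  expect_setequal(unique(omega$label), c("tumor", "stroma"))

  # two regions mapping to one type carry the merged label
  omega2 <- build_pseudo_reference(sp, asn, c(R1 = "tumor", R2 = "tumor"))
  expect_true(all(omega2$label == "tumor"))

  expect_error(
    build_pseudo_reference(sp, asn,
                           c(R1 = "tumor", R2 = "stroma", R9 = "ghost")),
    "ghost")
})

test_that("signatures are normalized means with marker-driven gene choice", {
  prof <- rbind(a = c(10, 0, 10, 0), b = c(0, 10, 0, 10))
  colnames(prof) <- paste0("g", 1:4)
  omega <- structure(list(profiles = prof, label = c("A", "B"),
                          spot_ids = c("a", "b"),
                          source = "pseudo-internal"),
                     class = "pseudo_reference")
  sig <- region_profiles(omega)
  expect_equal(unname(sig["A", ]), c(0.5, 0, 0.5, 0))
  # duplicated rows leave the mean unchanged
  omega$profiles <- prof[c(1, 1, 2), ]
  omega$label <- c("A", "A", "B")
  omega$spot_ids <- c("a", "a2", "b")
  expect_equal(unname(region_profiles(omega)["A", ]), c(0.5, 0, 0.5, 0))

  # a planted marker lands in its own type's selected gene set
  ref <- tiny_ref()
  sig2 <- signature_matrix(ref, "fine", n_top_genes = 12)
  expect_true(all(paste0("g", 1:10) %in% signature_genes(sig2)))
})

test_that("noiseless signature mixtures are recovered exactly by NNLS", {
  set.seed(31)
  sig <- matrix(rexp(3 * 40), 3, dimnames = list(c("A", "B", "C"),
                                                 paste0("g", 1:40)))
  sig <- sig / rowSums(sig)
  mixes <- list(c(1, 0, 0), c(0.5, 0.5, 0), c(0.7, 0, 0.3))
  counts <- t(vapply(mixes, function(w) 1e6 * drop(w %*% sig),
                     numeric(40)))
  rownames(counts) <- paste0("s", 1:3)
  sp <- spatial_counts(counts,
                       data.frame(spot_id = rownames(counts),
                                  row = 0:2, col = 0L))
  est <- deconvolve_regions(sp, sig, method = "nnls")
  expect_lt(max(abs(unclass(est) - do.call(rbind, mixes))), 1e-6)
  expect_equal(rowSums(est), rep(1, 3), ignore_attr = TRUE)
})

test_that("the likelihood backend recovers mixtures up to its shrinkage", {
  set.seed(32)
  sig <- matrix(rexp(3 * 60), 3, dimnames = list(c("A", "B", "C"),
                                                 paste0("g", 1:60)))
  truth <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6))
  counts <- round(2e5 * truth %*% (sig / rowSums(sig)))
  rownames(counts) <- c("s1", "s2")
  sp <- spatial_counts(counts, data.frame(spot_id = c("s1", "s2"),
                                          row = 0:1, col = 0L))
  est <- deconvolve_regions(sp, sig, method = "mle", prior_cells = 0.5,
                            cells_per_spot = 10)
  f <- 0.5 / (10 * 3)
  expected <- (truth + f) / (1 + 3 * f)
  expect_lt(max(abs(unclass(est) - expected)), 0.01)
  expect_true(all(unclass(est) > 0))
})

test_that("estimated proportions are invariant to per-spot scaling", {
  sp <- random_spatial(4, 4, 30, seed = 33)
  set.seed(33)
  sig <- matrix(rexp(2 * 30), 2, dimnames = list(c("A", "B"),
                                                 paste0("g", 1:30)))
  est1 <- deconvolve_regions(sp, sig)
  sp$counts[3, ] <- sp$counts[3, ] * 17L
  est2 <- deconvolve_regions(sp, sig)
  expect_equal(unclass(est1)[3, ], unclass(est2)[3, ], tolerance = 1e-10)
})

test_that("within-region estimates renormalize over one type's subtypes", {
  ref <- tiny_ref(deterministic = TRUE)
  # region B has a single subtype: constant 1
  sp <- random_spatial(2, 2, 60, seed = 34)
  colnames(sp$counts) <- colnames(ref$counts)
  sp$gene_ids <- colnames(ref$counts)
  wB <- within_region_proportions(sp, ref, "B")
  expect_equal(unname(unclass(wB)), matrix(1, 4, 1), ignore_attr = TRUE)
  expect_error(within_region_proportions(sp, ref, "nope"), "no fine types")

  # region A: 70/30 mixture of its two subtype signatures
  sigA <- signature_matrix(ref, "fine", n_top_genes = 60)[c("a1", "a2"), ]
  counts <- round(1e6 * rbind(0.7 * sigA[1, ] + 0.3 * sigA[2, ],
                              0.4 * sigA[1, ] + 0.6 * sigA[2, ]))
  sp2 <- spatial_counts(counts, data.frame(spot_id = c("m1", "m2"),
                                           row = 0:1, col = 0L),
                        gene_ids = colnames(ref$counts),
                        spot_ids = c("m1", "m2"))
  wA <- within_region_proportions(sp2, ref, "A")
  expect_equal(unname(unclass(wA)),
               rbind(c(0.7, 0.3), c(0.4, 0.6)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the product estimator conserves row sums", {
  # direct product: 0.6 * 0.5 = 0.3
  region <- proportion_matrix(
    matrix(c(0.6, 0.4), 1, dimnames = list("s1", c("T1", "T2"))), "region")
  within <- list(
    T1 = proportion_matrix(
      matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("t1a", "t1b"))),
      "fine"),
    T2 = proportion_matrix(
      matrix(1, 1, dimnames = list("s1", "t2a")), "fine"))
  fine <- deconvolve_fine(region, within)
  expect_equal(unclass(fine)["s1", "t1a"], 0.3)
  expect_equal(unclass(fine)["s1", "t2a"], 0.4)

  # conservation on random row-normalized inputs
  set.seed(35)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    R <- matrix(rexp(n * 3), n)
    R <- R / rowSums(R)
    dimnames(R) <- list(paste0("s", 1:n), c("T1", "T2", "T3"))
    region <- proportion_matrix(R, "region")
    within <- lapply(setNames(colnames(R), colnames(R)), function(ty) {
      k <- sample(1:4, 1)
      W <- matrix(rexp(n * k), n)
      W <- W / rowSums(W)
      dimnames(W) <- list(rownames(R), paste0(ty, ".", 1:k))
      proportion_matrix(W, "fine")
    })
    fine <- deconvolve_fine(region, within)
    expect_equal(rowSums(fine), rep(1, n), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # a region at zero passes zero to all its subtypes
  region0 <- proportion_matrix(
    matrix(c(1, 0), 1, dimnames = list("s1", c("T1", "T2"))), "region")
  fine0 <- deconvolve_fine(region0, within["T2"])
  expect_true(all(unclass(fine0)[, grepl("^T2", colnames(fine0))] == 0))

  expect_error(deconvolve_fine(region0, list(T9 = within$T2)), "T9")
})

test_that("the exported reference round-trips as a labeled reference", {
  sp <- random_spatial(5, 5, 9, seed = 36)
  asn <- toy_assignment(sp, 5)
  omega <- build_pseudo_reference(sp, asn, c(R1 = "tumor", R2 = "stroma"))
  for (fmt in c("csv", "mtx")) {
    dir <- file.path(tempdir(), paste0("omega_", fmt))
    paths <- export_reference(omega, dir, fmt)
    back <- read_reference(paths["matrix"], paths["labels"],
                           paths["grouping"])
    expect_equal(sort(back$fine_type), sort(omega$label))
    expect_equal(nrow(back$counts), nrow(omega$profiles))
    expect_equal(unname(as.matrix(back$counts)[omega$spot_ids, ]),
                 unname(omega$profiles))
  }
  expect_error(export_reference(omega, tempdir(), "parquet"))
})

test_that("augmentation appends external profiles with their markers", {
  ref <- tiny_ref()
  sig <- signature_matrix(ref, "region", n_top_genes = 15)
  omega_sig <- sig["A", , drop = FALSE]
  attr(omega_sig, "genes") <- paste0("g", 1:15)
  out <- augment_signatures(omega_sig, ref, "B", n_top_genes = 10)
  expect_equal(rownames(out), c("A", "B"))
  # B's planted markers (genes 21-30) enter the fitted gene set
  expect_true(all(paste0("g", 21:30) %in% signature_genes(out)))
  expect_error(augment_signatures(omega_sig, ref, "Z"), "no cells")
})
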