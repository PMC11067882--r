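test_that("default normalization is per-cell CP10K then log1p", {
  counts <- matrix(c(1, 3, 0, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(norm <- normalize_counts(counts), "AllZeroCell")
  expect_equal(unname(norm[, "c1"]), log1p(c(2500, 7500)))
  expect_equal(unname(norm[, "c2"]), c(0, 0))
  expect_identical(attr(norm, "normalization"), "log1p_cp10k")
  # per-cell scaling is invariant to library depth
  c2 <- matrix(c(2, 6), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  expect_equal(unname(normalize_counts(c2)[, 1]), unname(norm[, "c1"]))
  # pluggable: a custom function and a passthrough
  expect_identical(attr(normalize_counts(counts, method = "none"),
                        "normalization"), "none")
  expect_equal(normalize_counts(counts, method = function(x) as.matrix(x) + 1)[1, 1],
               2)
})

test_that("PCA scores match the SVD oracle on toy matrices (both branches)", {
  withr::with_seed(30, {
    # p < n branch (gene-gene covariance eigendecomposition)
    norm <- matrix(rnorm(6 * 4), 4, 6,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
    pcs <- fit_pca(norm, n_pcs = 3)
    pr <- prcomp(t(norm), center = TRUE, scale. = FALSE)
    expect_equal(abs(unname(pcs$scores)), abs(unname(pr$x[, 1:3])),
                 tolerance = 1e-8)
    expect_equal(pcs$sdev, pr$sdev[1:3], tolerance = 1e-8)
    # p > n branch (cell-cell Gram trick)
    norm2 <- matrix(rnorm(5 * 20), 20, 5,
                    dimnames = list(paste0("g", 1:20), paste0("c", 1:5)))
    pcs2 <- fit_pca(norm2, n_pcs = 3)
    pr2 <- prcomp(t(norm2), center = TRUE, scale. = FALSE)
    expect_equal(abs(unname(pcs2$scores)), abs(unname(pr2$x[, 1:3])),
                 tolerance = 1e-8)
    # loadings are orthonormal in both branches
    expect_equal(crossprod(pcs$loadings), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(crossprod(pcs2$loadings), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
})

test_that("PCA respects gene exclusion, rank capping and degenerate variance", {
  withr::with_seed(31, {
    norm <- matrix(0, 5, 8, dimnames = list(paste0("g", 1:5),
                                            paste0("c", 1:8)))
    norm[2, ] <- rnorm(8)  # variance in exactly one gene
    pcs <- suppressWarnings(fit_pca(norm, n_pcs = 3))
    expect_equal(abs(pcs$loadings["g2", 1]), 1, tolerance = 1e-8)
    expect_warning(fit_pca(matrix(rnorm(12), 3,  4), n_pcs = 50),
                   "RankDeficient")
    norm2 <- matrix(rnorm(40), 5, 8,
                    dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
    pcs2 <- fit_pca(norm2, n_pcs = 2, exclude_genes = c("g1", "g2"))
    expect_identical(rownames(pcs2$loadings), c("g3", "g4", "g5"))
  })
})

test_that("the differentiation index is hand-computable in a 2-PC toy", {
  # controls at (+-1, 0), (0, +-2); query cells at (3, 0) and the centroid
  scores <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2), c(3, 0), c(0, 0))
  rownames(scores) <- c(paste0("ctrl", 1:4), "far", "at_centroid")
  pcs <- structure(list(scores = scores, n_pcs = 2), class = "pc_space")
  di <- differentiation_index(pcs, paste0("ctrl", 1:4))
  mu <- mean(c(1, 1, 2, 2))          # 1.5
  sigma <- sd(c(1, 1, 2, 2))         # sqrt(1/3)
  expect_equal(di$reference$mu, mu)
  expect_equal(di$reference$sigma, sigma)
  expect_equal(unname(di$index["far"]), (3 - mu) / sigma)
  # a cell exactly at the centroid scores -mu/sigma
  expect_equal(unname(di$index["at_centroid"]), -mu / sigma)
  # control indexes are standardized by construction
  expect_equal(mean(di$index[paste0("ctrl", 1:4)]), 0)
  expect_equal(sd(di$index[paste0("ctrl", 1:4)]), 1)
})

test_that("degenerate control configurations are rejected", {
  # all controls equidistant from their centroid: zero distance spread
  scores <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(3, 0))
  rownames(scores) <- c(paste0("ctrl", 1:4), "q")
  pcs <- structure(list(scores = scores, n_pcs = 2), class = "pc_space")
  expect_error(differentiation_index(pcs, paste0("ctrl", 1:4)),
               "DegenerateControls")
  expect_error(differentiation_index(pcs, c("ctrl1", "ctrl2")),
               "DegenerateControls")
})

test_that("the index is invariant under orthogonal rotations of PC space", {
  withr::with_seed(32, {
    scores <- matrix(rnorm(40 * 5), 40, 5)
    rownames(scores) <- paste0("c", 1:40)
    ctrl <- paste0("c", 1:15)
    q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))  # random orthogonal matrix
    p1 <- structure(list(scores = scores, n_pcs = 5), class = "pc_space")
    p2 <- structure(list(scores = scores %*% q, n_pcs = 5),
                    class = "pc_space")
    d1 <- differentiation_index(p1, ctrl)
    d2 <- differentiation_index(p2, ctrl)
    expect_equal(d1$index, d2$index, tolerance = 1e-10)
  })
})

test_that("adding a constant to every cell leaves the index unchanged", {
  withr::with_seed(33, {
    norm <- matrix(rnorm(30 * 12, 5), 30, 12,
                   dimnames = list(paste0("g", 1:30), paste0("c", 1:12)))
    ctrl <- paste0("c", 1:6)
    d1 <- differentiation_index(norm, ctrl, n_pcs = 5)
    d2 <- differentiation_index(norm + 2, ctrl, n_pcs = 5)
    expect_equal(d1$index, d2$index, tolerance = 1e-8)
  })
})

test_that("Mann-Whitney p-values equal exhaustive rank enumeration at n=3 vs 4", {
  withr::with_seed(34, {
    labels <- data.frame(
      cell_barcode = c(paste0("t", 1:3), paste0("c", 1:4)),
      label = c(rep("single", 3), rep("control", 4)),
      tf_name = c(rep("tfA", 3), rep(NA, 4)), stringsAsFactors = FALSE)
    for (i in 1:10) {
      idx <- stats::setNames(rnorm(7), labels$cell_barcode)
      res <- potency_test(idx, labels, min_cells = 3)
      p_oracle <- oracle_mw_greater(idx[1:3], idx[4:7])
      expect_equal(res$p, p_oracle, tolerance = 1e-12)
    }
  })
})

test_that("potency calls respect group size and the null case", {
  withr::with_seed(35, {
    # a TF population that IS a subsample of controls is not flagged
    idx <- stats::setNames(rnorm(120), paste0("c", 1:120))
    labels <- data.frame(
      cell_barcode = paste0("c", 1:120),
      label = c(rep("control", 100), rep("single", 20)),
      tf_name = c(rep(NA, 100), rep("tfNull", 20)),
      stringsAsFactors = FALSE)
    # tfNull indexes drawn from the same distribution as controls
    res <- potency_test(idx, labels)
    expect_false(res$potent[res$tf_name == "tfNull"])
    # groups under min_cells are reported untested
    labels$tf_name[101:118] <- "tfBig"
    labels$tf_name[119:120] <- "tfTiny"
    res2 <- potency_test(idx, labels, min_cells = 3)
    expect_false(res2$tested[res2$tf_name == "tfTiny"])
    expect_true(res2$tested[res2$tf_name == "tfBig"])
    expect_true(is.na(res2$p_adj[res2$tf_name == "tfTiny"]))
  })
})

test_that("percentile ranks match brute-force pairwise comparison", {
  m <- c(a = 3, b = 10, c = 7, d = 3, e = -1)
  r <- percentile_ranks(m)
  expect_equal(unname(r["b"]), 100)
  # brute force: for each TF count strictly smaller and tied others
  n <- length(m)
  for (i in seq_len(n)) {
    cnt <- sum(m < m[i]) + 0.5 * (sum(m == m[i]) - 1)
    expect_equal(unname(r[i]), 100 * cnt / (n - 1))
  }
  expect_equal(unname(percentile_ranks(c(x = 1, y = 1, z = 1))),
               rep(50, 3))
  # ranks are monotone in the median
  expect_true(all(diff(r[order(m)]) >= 0))
  expect_error(percentile_ranks(c(a = 1)), "at least 2")
})

test_that("type-I error is controlled on pure-null cohorts", {
  # 200 seeded replicates of a cohort whose perturbed populations are all
  # drawn from the control distribution; the flagged fraction at adjusted
  # p < 0.01 must stay within 0.01 + 3 SE
  n_rep <- 200
  pops <- cohort_populations(n_potent = 0, n_null = 5, n_cells = 20)
  flagged <- 0L; tested <- 0L
  for (r in seq_len(n_rep)) {
    sim <- simulate_expression_cohort(n_genes = 200, n_control = 150,
                                      populations = pops, seed = 5000 + r)
    norm <- normalize_counts(sim$counts)
    di <- differentiation_index(norm, sim$labels$cell_barcode[
      sim$labels$label == "control"], n_pcs = 20,
      exclude_genes = sim$itf_genes)
    res <- potency_test(di, sim$labels)
    flagged <- flagged + sum(res$potent)
    tested <- tested + sum(res$tested)
  }
  frac <- flagged / tested
  se <- sqrt(0.01 * 0.99 / tested)
  expect_lte(frac, 0.01 + 3 * se)
})

test_that("planted-shift populations outrank planted nulls by median index", {
  # criterion-scale effect (shift 2.0 on 50 of 2000 genes) at reduced cohort
  # size: every replicate must rank all shifted populations above all nulls
  n_rep <- 20
  pops <- cohort_populations(n_potent = 3, n_null = 3, n_cells = 40)
  for (r in seq_len(n_rep)) {
    sim <- simulate_expression_cohort(n_genes = 2000, n_control = 300,
                                      populations = pops, seed = 7000 + r)
    norm <- normalize_counts(sim$counts)
    di <- differentiation_index(norm, sim$labels$cell_barcode[
      sim$labels$label == "control"], n_pcs = 50,
      exclude_genes = sim$itf_genes)
    res <- potency_test(di, sim$labels)
    is_potent <- vapply(sim$truth, function(t) t$is_potent, logical(1))
    names(is_potent) <- vapply(sim$truth, function(t) t$name, character(1))
    med_potent <- res$median_index[is_potent[res$tf_name]]
    med_null <- res$median_index[!is_potent[res$tf_name]]
    expect_gt(min(med_potent), max(med_null))
  }
})
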