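test_that("binary similarity coefficients match direct enumeration", {
  m <- band_matrix(rbind(C1 = c(1, 1, 0), C2 = c(1, 1, 0), C3 = c(0, 1, 1)))
  d <- band_distance(m, "jaccard")
  expect_equal(d["C1", "C2"], 0)                    # identical profiles
  expect_equal(d["C1", "C3"], 1 - 1 / 3)            # a=1, b=1, c=1
  expect_equal(band_distance(m, "dice")["C1", "C3"], 1 - 1 / 2)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  disj <- band_matrix(rbind(C1 = c(1, 1, 0), C2 = c(0, 0, 1)))
  expect_equal(band_distance(disj, "jaccard")["C1", "C2"], 1)

  none <- band_matrix(rbind(C1 = c(1, 0), C2 = c(0, 1), C3 = c(0, 1)))
  # C2 vs C3 share a band; fine. Both-empty pair errors:
  empty <- band_matrix(rbind(C1 = c(1, 1), C2 = c(0, 0), C3 = c(0, 0)))
  expect_error(band_distance(empty, "jaccard"), "undefined")
  expect_silent(band_distance(empty, "simple_matching"))
})

test_that("UPGMA reproduces the analytically forced merge order", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  # (A,B) merge at height 1, C joins at height 3
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(d), colnames(d)], d)
  expect_true(ape::all.equal.phylo(tr,
    ape::read.tree(text = "((A:1,B:1):2,C:3);"),
    use.edge.length = TRUE))
  # the Newick serialization parses back to the identical tree
  expect_true(ape::all.equal.phylo(ape::read.tree(text = to_newick(tr)), tr,
                                   use.edge.length = TRUE))

  two <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- upgma(two)
  expect_equal(unname(t2$edge.length), c(2, 2))
})

test_that("UPGMA recovers random ultrametric matrices exactly", {
  set.seed(7)
  for (rep in 1:10) {
    # random ultrametric distances: cophenetic matrix of a random UPGMA tree
    n <- 5
    x <- matrix(rnorm(n * 3), n, dimnames = list(letters[1:n], NULL))
    hc <- hclust(dist(x), method = "average")
    dm <- as.matrix(cophenetic(hc))
    tr <- upgma(dm)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm)
    # ultrametricity: root-to-tip depths all equal
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
  }
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2)), "finite")
})

test_that("UPGMA heights are monotone along every root path", {
  set.seed(8)
  for (rep in 1:10) {
    n <- 6
    dm <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    rownames(dm) <- colnames(dm) <- paste0("L", 1:n)
    tr <- upgma(dm)
    depth <- ape::node.depth.edgelength(tr)
    h <- max(depth) - depth   # height above the leaves
    for (e in seq_len(nrow(tr$edge)))
      expect_gte(h[tr$edge[e, 1]], h[tr$edge[e, 2]] - 1e-12)
  }
})

test_that("band UPGMA groups the two similar accessions first", {
  # one accession carrying most unique bands splits off last
  prof <- study_profile()
  mats <- gen_band_study(prof, seed = 5, marker = "SCoT")
  d <- band_distance(mats, "jaccard")
  tr <- upgma(d)
  pair <- ape::prop.part(tr)
  clades <- lapply(ape::prop.part(tr), function(i) sort(tr$tip.label[i]))
  expect_true(list(c("C1", "C2")) %in% clades ||
              any(vapply(clades, identical, TRUE, c("C1", "C2"))))
})

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(3)
  x <- matrix(rnorm(12), 4, 3)
  res <- pca(x)
  # oracle: dense eigen-decomposition of the covariance matrix
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(res$eigenvalues, ev$values[seq_along(res$eigenvalues)],
               tolerance = 1e-9)
  sc_oracle <- scale(x, scale = FALSE) %*% ev$vectors
  for (j in seq_along(res$eigenvalues))
    expect_equal(abs(unname(res$scores[, j])), abs(sc_oracle[, j]),
                 tolerance = 1e-9)
  # sign convention: dominant loading positive
  for (j in seq_along(res$eigenvalues))
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
})

test_that("PCA degenerate geometry behaves as theory dictates", {
  # two perfectly collinear variables: PC1 explains 100%
  x <- cbind(a = 1:5, b = 2 * (1:5))
  expect_equal(pca(x)$explained_pct[1], 100)
  # any 3-sample matrix has rank <= 2 after centering: PC1+PC2 = 100%
  set.seed(9)
  for (rep in 1:5) {
    y <- matrix(rnorm(3 * 7), 3, 7)
    res <- pca(y)
    expect_equal(sum(res$explained_pct[1:min(2, length(res$explained_pct))]),
                 100, tolerance = 1e-9)
  }
  expect_error(pca(matrix(1:3, 1)), "2 samples")
  # translation invariance of scores, reorder invariance of explained %
  z <- matrix(rnorm(20), 5, 4)
  expect_equal(pca(z + 100)$scores, pca(z)$scores, tolerance = 1e-8)
  expect_equal(sort(pca(z[c(3, 1, 2, 5, 4), ])$explained_pct),
               sort(pca(z)$explained_pct), tolerance = 1e-8)
})

test_that("heatmap scaling maps extremes to -1/1 and orders by clustering", {
  x <- cbind(v1 = c(1, 2, 3), v2 = c(10, 10, 40), v3 = c(5, 5, 5))
  expect_warning(hp <- heatmap_prepare(x), "constant")
  expect_equal(unname(hp$scaled[, "v1"]), c(-1, 0, 1))
  expect_equal(unname(hp$scaled[, "v2"]), c(-1, -1, 1))
  expect_equal(unname(hp$scaled[, "v3"]), c(0, 0, 0))
  expect_setequal(hp$row_order, 1:3)
  # rows 1 and 2 are closer to each other than to row 3: adjacent in order
  expect_equal(abs(diff(match(1:2, hp$row_order))), 1)
  # z-score scaling
  hp2 <- heatmap_prepare(x[, 1:2], scale = "zscore")
  expect_equal(unname(colMeans(hp2$scaled)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(hp2$scaled, 2, sd)), c(1, 1))
})
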