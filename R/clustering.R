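#' Pairwise distance between binary band profiles
#'
#' Concatenates the band columns of one or more [band_matrix()] objects
#' into one profile per accession and computes pairwise similarity under
#' the chosen coefficient, returned as distance = 1 - similarity. With
#' per-pair counts a (shared bands), b and c (bands private to either) and
#' d (jointly absent): Jaccard = a/(a+b+c), Dice = 2a/(2a+b+c),
#' simple matching = (a+d)/(a+b+c+d). Jaccard is the default — joint
#' absence of a dominant-marker band carries no signal.
#'
#' @param profiles a [band_matrix()] or list of them (shared accessions).
#' @param metric `"jaccard"`, `"dice"` or `"simple_matching"`.
#' @return square symmetric numeric matrix of distances, zero diagonal,
#'   labelled by accession id.
#' @export
band_distance <- function(profiles,
                          metric = c("jaccard", "dice", "simple_matching")) {
  metric <- match.arg(metric)
  if (inherits(profiles, "band_matrix")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "band_matrix")))
  acc <- profiles[[1]]$accession_ids
  mats <- lapply(profiles, function(m) m$presence[acc, , drop = FALSE])
  X <- do.call(cbind, mats)
  A <- nrow(X)
  d <- matrix(0, A, A, dimnames = list(acc, acc))
  for (i in seq_len(A - 1)) for (j in (i + 1):A) {
    x <- X[i, ]; y <- X[j, ]
    a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
    cc <- sum(x == 0 & y == 1); dd <- sum(x == 0 & y == 0)
    s <- switch(metric,
      jaccard = {
        if (a + b + cc == 0)
          stop(sprintf(
            "jaccard undefined for '%s' vs '%s': no bands in either",
            acc[i], acc[j]))
        a / (a + b + cc)
      },
      dice = if (2 * a + b + cc == 0) 0 else 2 * a / (2 * a + b + cc),
      simple_matching = (a + dd) / (a + b + cc + dd))
    d[i, j] <- d[j, i] <- 1 - s
  }
  d
}

#' UPGMA dendrogram
#'
#' Unweighted pair-group average-linkage agglomeration of a distance
#' matrix: at each step the two closest clusters merge at a node whose
#' height is half their cluster-size-weighted average distance, producing
#' an ultrametric rooted tree. Ties are broken deterministically by
#' lexicographic label order (labels are sorted before clustering).
#'
#' @param d square symmetric distance matrix with labels, or a
#'   [stats::dist] object.
#' @return an ultrametric `ape::phylo` tree; leaf depths equal half the
#'   cophenetic distances, so [ape::cophenetic.phylo()] on the result of an
#'   ultrametric input reproduces that input exactly.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(d))
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (is.null(rownames(d))) rownames(d) <- colnames(d) %||%
        paste0("L", seq_len(nrow(d)))
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    ord <- order(rownames(d))
    d <- stats::as.dist(d[ord, ord])
  }
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distance")
  if (attr(d, "Size") < 2) stop("need at least 2 labels")
  if (attr(d, "Size") == 2) {
    labs <- attr(d, "Labels") %||% c("L1", "L2")
    txt <- sprintf("(%s:%g,%s:%g);", labs[1], d[1] / 2, labs[2], d[1] / 2)
    return(ape::read.tree(text = txt))
  }
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)   # divides merge heights by 2 -> ultrametric depths
}

#' Serialize a tree to Newick
#'
#' Branch lengths are parent height minus child height; bootstrap supports,
#' when present as node labels, are written as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string.
#' @export
to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  txt
}

#' Principal component analysis
#'
#' Centred (optionally unit-variance standardized) PCA via singular value
#' decomposition. Components are ordered by decreasing eigenvalue;
#' explained percentages are eigenvalue shares. Sign convention: each
#' component is flipped so its largest-magnitude loading is positive.
#' Zero-variance variables are dropped with a warning when standardizing.
#'
#' @param x numeric samples x variables matrix (>= 2 samples, no NA).
#' @param standardize divide each variable by its standard deviation.
#' @return object of class `pca_result`: list with `scores`
#'   (samples x components), `loadings` (variables x components),
#'   `eigenvalues` and `explained_pct`.
#' @export
pca <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (anyNA(x)) stop("missing values not supported")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    x <- sweep(x, 2, sds, "/")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1)
  d <- sv$d[seq_len(k)]
  eig <- d^2 / (nrow(x) - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  tot <- sum(sv$d^2) / (nrow(x) - 1)
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 explained_pct = 100 * eig / tot),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "components\n")
  print(round(rbind(eigenvalue = x$eigenvalues,
                    `explained %` = x$explained_pct), 3))
  invisible(x)
}

#' Scale a trait matrix and order it for a clustered heatmap
#'
#' Per-variable scaling to [-1, 1] (`"minus1_1"`: min maps to -1, max to 1)
#' or to z-scores, then UPGMA clustering of euclidean distances among the
#' scaled rows and columns to give display orders. Constant variables map
#' to 0 under `"minus1_1"` with a warning.
#'
#' @param x numeric samples x variables matrix.
#' @param scale `"minus1_1"` or `"zscore"`.
#' @return list with `scaled`, `row_order`, `col_order` (integer index
#'   vectors) and the two dendrograms (`row_tree`, `col_tree`, `phylo` or
#'   NULL when fewer than 2 rows/columns).
#' @export
heatmap_prepare <- function(x, scale = c("minus1_1", "zscore")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  scaled <- apply(x, 2, function(v) {
    rng <- range(v)
    if (scale == "minus1_1") {
      if (rng[1] == rng[2]) {
        warning("constant variable mapped to 0")
        rep(0, length(v))
      } else 2 * (v - rng[1]) / (rng[2] - rng[1]) - 1
    } else {
      s <- stats::sd(v)
      if (s == 0) { warning("constant variable mapped to 0"); rep(0, length(v)) }
      else (v - mean(v)) / s
    }
  })
  scaled <- matrix(scaled, nrow = nrow(x), dimnames = dimnames(x))
  order_of <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), tree = NULL))
    d <- as.matrix(stats::dist(m))
    tr <- upgma(d)
    ord <- match(tr$tip.label[ape::reorder.phylo(tr, "cladewise")$edge[
      ape::reorder.phylo(tr, "cladewise")$edge[, 2] <= ape::Ntip(tr), 2]],
      rownames(m))
    list(order = ord, tree = tr)
  }
  ro <- order_of(scaled)
  co <- order_of(t(scaled))
  list(scaled = scaled, row_order = ro$order, col_order = co$order,
       row_tree = ro$tree, col_tree = co$tree)
}
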