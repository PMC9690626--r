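#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within sum-of-squares
#' decomposition, equal variances) on replicate values grouped by
#' accession. When every group mean is equal and the within-group variance
#' is zero, F is defined as 0 (p = 1) rather than NaN.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), or a data frame with columns `value` and `group`.
#' @return list with `f`, `p`, `df_between`, `df_within`, `ms_error`,
#'   `group_means`, `n` (per-group sizes).
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs >= 2 replicate values")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, 0L)),
                  levels = names(groups))
  tab <- suppressWarnings(stats::anova(stats::lm(value ~ group)))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  # exact sums of squares to recognize the degenerate zero-variance cases
  # (lm's floating-point residuals can make 0/0 come out as a finite ratio)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  ssb <- sum(vapply(groups, function(v)
    length(v) * (mean(v) - mean(value))^2, 0))
  if (ssw == 0) {
    if (ssb == 0) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  }
  list(f = f, p = p,
       df_between = tab$Df[1], df_within = tab$Df[2],
       ms_error = tab$`Mean Sq`[2],
       group_means = vapply(groups, mean, 0),
       n = vapply(groups, length, 0L))
}

#' Duncan's multiple range test letter groups
#'
#' Post-hoc mean separation after one-way ANOVA. Means are sorted in
#' descending order; a stretch of k consecutive means is homogeneous when
#' the difference of its extremes is below the least significant range
#' R_k = q(alpha_k, k, df_error) * sqrt(MSE / n), where q is the upper
#' quantile of the studentized range (via [stats::qtukey()]) at Duncan's
#' protection level alpha_k = 1 - (1 - alpha)^(k - 1). Letters are
#' assigned to the maximal homogeneous stretches (the underlining
#' algorithm): accessions sharing any letter are not significantly
#' different at `alpha`. Unequal replicate counts are handled with the
#' harmonic mean n (with a warning).
#'
#' @inheritParams anova_oneway
#' @param alpha significance level in (0, 1); default 0.05.
#' @return object of class `duncan_groups`: data frame with `group`,
#'   `mean`, `n`, `letters`, ordered by descending mean; attributes
#'   `alpha` and `lsr` (least significant ranges by stretch size).
#' @examples
#' g <- list(C1 = c(10.1, 9.9, 10.0), C2 = c(50.2, 49.8, 50.1),
#'           C3 = c(90.0, 89.9, 90.1))
#' duncan_letters(g)
#' @export
duncan_letters <- function(groups, alpha = 0.05) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)")
  av <- anova_oneway(groups)
  means <- sort(av$group_means, decreasing = TRUE)
  g <- length(means)
  n <- av$n[names(means)]
  if (length(unique(n)) > 1) {
    warning("unequal replicate counts: using harmonic mean n")
    nh <- length(n) / sum(1 / n)
  } else nh <- n[1]
  df <- av$df_within
  mse <- av$ms_error
  # least significant range for a stretch of k means
  lsr <- vapply(2:max(2, g), function(k) {
    alpha_k <- 1 - (1 - alpha)^(k - 1)
    stats::qtukey(1 - alpha_k, k, df) * sqrt(mse / nh)
  }, 0)
  names(lsr) <- paste0("k", 2:max(2, g))
  homogeneous <- function(i, j) {
    d <- means[i] - means[j]          # lsr[k-1] is the k-stretch range
    d == 0 || d < lsr[j - i]          # exact ties always share a letter
  }
  # maximal homogeneous stretches
  stretches <- list()
  i <- 1
  while (i <= g) {
    j <- i
    while (j < g && homogeneous(i, j + 1)) j <- j + 1
    covered <- any(vapply(stretches, function(s)
      s[1] <= i && j <= s[2], TRUE))
    if (!covered) stretches[[length(stretches) + 1]] <- c(i, j)
    i <- i + 1
  }
  letters_per <- rep("", g)
  for (k in seq_along(stretches)) {
    s <- stretches[[k]]
    idx <- s[1]:s[2]
    letters_per[idx] <- paste0(letters_per[idx], letters[k])
  }
  out <- data.frame(group = names(means), mean = unname(means),
                    n = unname(n), letters = letters_per,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "lsr") <- lsr
  class(out) <- c("duncan_groups", "data.frame")
  out
}

#' Pearson correlation matrix of traits
#'
#' Correlates every pair of traits across accessions, either on replicate
#' level values (replicates paired by accession and replicate index) or on
#' accession means. With only three accessions the mean-level matrix rests
#' on n = 3 points per pair and is flagged with a `low_n` attribute.
#' Zero-variance traits yield NA for their pairs, with a warning, never a
#' silent 0.
#'
#' @param traits data frame with columns `accession`, `trait`,
#'   `replicate`, `value`.
#' @param aggregate `"replicate_level"` or `"mean_level"`.
#' @return symmetric correlation matrix (traits x traits, diagonal 1),
#'   attribute `n` = number of paired observations.
#' @export
pearson_matrix <- function(traits,
                           aggregate = c("replicate_level", "mean_level")) {
  aggregate <- match.arg(aggregate)
  need <- c("accession", "trait", "replicate", "value")
  if (!all(need %in% names(traits)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  if (aggregate == "mean_level") {
    agg <- stats::aggregate(value ~ accession + trait, traits, mean)
    wide <- stats::reshape(agg, idvar = "accession", timevar = "trait",
                           direction = "wide")
  } else {
    wide <- stats::reshape(traits[need], idvar = c("accession", "replicate"),
                           timevar = "trait", direction = "wide")
  }
  m <- as.matrix(wide[, grep("^value\\.", names(wide)), drop = FALSE])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  if (nrow(m) < 3)
    stop("need >= 3 paired observations per trait pair")
  constant <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (any(constant)) {
    warning("zero-variance trait(s), correlations undefined: ",
            paste(colnames(m)[constant], collapse = ", "))
    r[constant, ] <- NA; r[, constant] <- NA
  }
  diag(r) <- 1
  attr(r, "n") <- nrow(m)
  attr(r, "low_n") <- nrow(m) <= 3
  r
}

#' Compare accessions trait by trait
#'
#' Runs [anova_oneway()] and [duncan_letters()] for every trait of a
#' replicate trait table.
#'
#' @inheritParams pearson_matrix
#' @param alpha significance level for the letter groups.
#' @return data frame with one row per (trait, accession): `trait`,
#'   `accession`, `mean`, `sd`, `n`, `letters`, `f`, `p`.
#' @export
trait_compare <- function(traits, alpha = 0.05) {
  need <- c("accession", "trait", "value")
  if (!all(need %in% names(traits)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  do.call(rbind, lapply(split(traits, traits$trait), function(df) {
    groups <- split(df$value, df$accession)
    av <- anova_oneway(groups)
    dl <- duncan_letters(groups, alpha)
    data.frame(trait = df$trait[1], accession = dl$group, mean = dl$mean,
               sd = vapply(groups[dl$group], stats::sd, 0),
               n = dl$n, letters = dl$letters, f = av$f, p = av$p,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
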