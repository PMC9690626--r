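#' Polymorphism information content of a band matrix
#'
#' For dominant markers each band is treated as a biallelic locus with band
#' (presence) frequency p_b, so its informativeness is
#' 1 - p_b^2 - (1 - p_b)^2 = 2 p_b (1 - p_b), and the primer PIC is the mean
#' over all its bands (`method = "band_2pq_mean"`). This is bounded by 0.5,
#' the theoretical maximum for a dominant locus. Published PIC values
#' computed by other (often unstated) software conventions can be supplied
#' downstream via `pic_overrides` in [marker_summary()].
#'
#' @param m a [band_matrix()].
#' @param method PIC convention; only `"band_2pq_mean"` is computed.
#' @return PIC in [0, 0.5]; 0 when every band is monomorphic.
#' @export
pic <- function(m, method = "band_2pq_mean") {
  method <- match.arg(method, "band_2pq_mean")
  p <- classify_bands(m)$freq
  mean(2 * p * (1 - p))
}

#' Effective multiplex ratio
#'
#' EMR = PB * (PB / TB): the number of polymorphic bands weighted by the
#' polymorphic fraction of the assay. A primer whose bands are all
#' polymorphic has EMR = TB; an all-monomorphic primer has EMR = 0.
#'
#' @param counts a `band_class_counts` (from [classify_bands()]) or a
#'   [band_matrix()].
#' @return EMR >= 0.
#' @export
emr <- function(counts) {
  counts <- as_band_counts(counts)
  if (counts$tb < 1) stop("need at least one band")
  counts$pb^2 / counts$tb
}

#' Marker index
#'
#' MI = PIC x EMR, the composite primer-utility score.
#'
#' @param pic_value PIC (>= 0).
#' @param emr_value EMR (>= 0).
#' @return the product.
#' @export
mi <- function(pic_value, emr_value) {
  stopifnot(pic_value >= 0, emr_value >= 0)
  pic_value * emr_value
}

#' Resolving power
#'
#' RP = sum of per-band informativeness Ib over a primer's bands. Two
#' conventions are offered. `"doubled_frequency"` takes Ib = 2 p_b (band
#' informativeness proportional to how widely the band occurs); it is the
#' convention under which published RP columns of three-accession dominant
#' marker panels reproduce, and is the default. `"prevost"` takes
#' Ib = 1 - 2 |0.5 - p_b|, the Prevost & Wilkinson form in which bands at
#' intermediate frequency are the most discriminating.
#'
#' @param m a [band_matrix()].
#' @param convention `"doubled_frequency"` (default) or `"prevost"`.
#' @return RP >= 0.
#' @export
rp <- function(m, convention = c("doubled_frequency", "prevost")) {
  convention <- match.arg(convention)
  p <- classify_bands(m)$freq
  switch(convention,
         doubled_frequency = sum(2 * p),
         prevost = sum(1 - 2 * abs(0.5 - p)))
}

#' Percent polymorphism
#'
#' 100 * PB / TB, the share of a primer's (or a pooled panel's) bands that
#' are polymorphic.
#'
#' @inheritParams emr
#' @return percent in [0, 100].
#' @export
polymorphism_pct <- function(counts) {
  counts <- as_band_counts(counts)
  if (counts$tb < 1) stop("need at least one band")
  100 * counts$pb / counts$tb
}

as_band_counts <- function(x) {
  if (inherits(x, "band_matrix")) return(classify_bands(x))
  if (inherits(x, "band_class_counts")) return(x)
  stop("expected a band_matrix or band_class_counts")
}

#' Per-primer informativeness panel and marker-system summary
#'
#' Computes, for each primer's band matrix, the band-class counts and the
#' PIC / EMR / MI / RP / P% panel, plus the pooled summary: column totals,
#' per-primer averages, and the overall percent polymorphism computed from
#' pooled band counts (sum PB / sum TB), not as a mean of per-primer
#' percentages.
#'
#' Published PIC values can be injected per primer with `pic_overrides`
#' (a named numeric vector); MI is then computed from the override, and the
#' computed 2pq-mean PIC is kept alongside in `pic_computed`.
#'
#' @param matrices list of [band_matrix()] objects sharing accession ids.
#' @param pic_overrides optional named numeric vector (names = primer ids).
#' @param rp_convention RP convention, see [rp()].
#' @return An object of class `marker_summary`: list with `per_primer`
#'   (data frame: primer, marker_system, mb, ub, nb, pb, tb, pic,
#'   pic_computed, emr, mi, rp, p_pct), `totals`, `averages` (named
#'   vectors) and `overall_p_pct`.
#' @export
marker_summary <- function(matrices, pic_overrides = NULL,
                           rp_convention = "doubled_frequency") {
  if (inherits(matrices, "band_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "band_matrix")))
  acc <- matrices[[1]]$accession_ids
  for (m in matrices)
    if (!identical(sort(m$accession_ids), sort(acc)))
      stop("primer '", m$primer_id, "' has a different accession set")
  rows <- lapply(matrices, function(m) {
    ct <- classify_bands(m)
    pic_c <- pic(m)
    pic_used <- pic_overrides[m$primer_id]
    pic_used <- if (is.null(pic_overrides) || is.na(pic_used)) pic_c else
      unname(pic_used)
    e <- emr(ct)
    data.frame(primer = m$primer_id, marker_system = m$marker_system,
               mb = ct$mb, ub = ct$ub, nb = ct$nb, pb = ct$pb, tb = ct$tb,
               pic = pic_used, pic_computed = pic_c, emr = e,
               mi = mi(pic_used, e), rp = rp(m, rp_convention),
               p_pct = polymorphism_pct(ct), stringsAsFactors = FALSE)
  })
  per_primer <- do.call(rbind, rows)
  num <- c("mb", "ub", "nb", "pb", "tb", "pic", "emr", "mi", "rp", "p_pct")
  totals <- colSums(per_primer[num])
  averages <- colMeans(per_primer[num])
  structure(
    list(per_primer = per_primer, totals = totals, averages = averages,
         overall_p_pct = 100 * sum(per_primer$pb) / sum(per_primer$tb),
         rp_convention = rp_convention),
    class = "marker_summary")
}

#' @export
print.marker_summary <- function(x, digits = 2, ...) {
  df <- x$per_primer
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("pooled bands: %d of %d polymorphic (%.2f%%)\n",
              sum(x$per_primer$pb), sum(x$per_primer$tb), x$overall_p_pct))
  invisible(x)
}

#' Published band-class counts of the three-accession reference panel
#'
#' The band-class composition (MB, UB, NB) of the 10 ISSR primers, 11 SCoT
#' primers and the SDS-PAGE protein profile of a published three-accession
#' balsam (*Commiphora gileadensis*) diversity panel, together with the
#' published PIC value of each primer. These counts are the complete input
#' to every statistic in [marker_summary()]; the raw gel matrices were
#' never published, so matrices are reconstructed from the counts with
#' [matrix_from_composition()].
#'
#' @param marker optional filter: `"ISSR"`, `"SCoT"` or `"PROTEIN"`.
#' @return data frame: `marker`, `primer`, `mb`, `ub`, `nb`,
#'   `pic_published`.
#' @export
published_band_classes <- function(marker = NULL) {
  path <- system.file("extdata", "band_class_counts.csv",
                      package = "markerdiv", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(marker)) df <- df[df$marker %in% marker, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Reconstruct the reference panel's band matrices
#'
#' Builds one [band_matrix()] per primer of [published_band_classes()] via
#' [matrix_from_composition()].
#'
#' @inheritParams published_band_classes
#' @param seed integer seed controlling accession assignment of the
#'   polymorphic bands (the statistics do not depend on it).
#' @return named list of [band_matrix()] objects.
#' @export
reference_band_matrices <- function(marker = NULL, seed = 1) {
  df <- published_band_classes(marker)
  out <- lapply(seq_len(nrow(df)), function(i)
    matrix_from_composition(df$mb[i], df$ub[i], df$nb[i], n_accessions = 3,
                            seed = seed + i, primer_id = df$primer[i],
                            marker_system = df$marker[i]))
  names(out) <- df$primer
  out
}
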