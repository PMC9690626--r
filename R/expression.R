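#' Difference of cycle-threshold values
#'
#' Livak convention: dCt = Ct(target) - Ct(reference gene). Lower dCt
#' means more target transcript relative to the reference.
#'
#' @param ct_target,ct_ref finite Ct values (cycles).
#' @return dCt in cycles.
#' @export
delta_ct <- function(ct_target, ct_ref) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref)))
    stop("Ct values must be finite")
  ct_target - ct_ref
}

validate_ct_table <- function(ct, reference, calibrator) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0")
  if (!reference %in% ct$gene)
    stop("reference gene '", reference, "' not in table")
  if (!calibrator %in% ct$sample)
    stop("calibrator sample '", calibrator, "' not in table")
  for (s in unique(ct$sample))
    if (!any(ct$sample == s & ct$gene == reference))
      stop("sample '", s, "' has no measurements of the reference gene '",
           reference, "'")
  invisible(ct)
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' For every (sample, target gene) pair: replicate dCt values are formed by
#' pairing target and reference-gene Ct replicates by replicate index
#' (dCt = Ct_target - Ct_reference, averaged at the dCt level), then
#' ddCt = mean dCt(sample) - mean dCt(calibrator sample) and
#' fold = 2^-ddCt. The calibrator's fold is 1 for every gene by
#' construction. Replicate spread is propagated as a fold range:
#' `fold_lower`/`fold_upper` evaluate 2^-ddCt at mean dCt +/- SD(dCt).
#' Amplification efficiency is fixed at 2 (no efficiency correction).
#'
#' @param ct data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference reference (housekeeping) gene id.
#' @param calibrator calibrator sample id (fold = 1 baseline).
#' @return data frame: `sample`, `gene`, `n_reps`, `dct` (mean), `sd_dct`,
#'   `ddct`, `fold`, `fold_lower`, `fold_upper`.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("C1", "C3"), each = 4),
#'   gene = rep(c("PAL1", "PAL1", "ACT", "ACT"), 2),
#'   replicate = rep(1:2, 4),
#'   ct = c(28, 28, 20, 20, 24, 24, 20, 20))
#' fold_changes(ct, reference = "ACT", calibrator = "C1")
#' @export
fold_changes <- function(ct, reference, calibrator) {
  ct <- as.data.frame(ct)
  validate_ct_table(ct, reference, calibrator)
  samples <- unique(ct$sample)
  genes <- setdiff(unique(ct$gene), reference)
  dct_reps <- function(s, g) {
    tg <- ct[ct$sample == s & ct$gene == g, ]
    rf <- ct[ct$sample == s & ct$gene == reference, ]
    if (nrow(tg) == 0)
      stop("sample '", s, "' has no measurements of gene '", g, "'")
    idx <- intersect(tg$replicate, rf$replicate)
    if (length(idx) == 0)
      stop("sample '", s, "', gene '", g,
           "': no replicate indices shared with the reference gene")
    delta_ct(tg$ct[match(idx, tg$replicate)],
             rf$ct[match(idx, rf$replicate)])
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    cal <- dct_reps(calibrator, g)
    do.call(rbind, lapply(samples, function(s) {
      d <- dct_reps(s, g)
      ddct <- mean(d) - mean(cal)
      sdd <- if (length(d) > 1) stats::sd(d) else 0
      data.frame(sample = s, gene = g, n_reps = length(d),
                 dct = mean(d), sd_dct = sdd, ddct = ddct,
                 fold = 2^-ddct,
                 fold_lower = 2^-(ddct + sdd),
                 fold_upper = 2^-(ddct - sdd),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read a Ct table from CSV
#'
#' Expected columns: `sample`, `gene`, `replicate`, `ct`.
#'
#' @param path CSV file.
#' @return data frame suitable for [fold_changes()].
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
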