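#' Default study profile for the synthetic generators
#'
#' Encodes the structure of a three-accession diversity panel: the
#' published band-class composition of every ISSR/SCoT primer and the
#' protein gel ([published_band_classes()]), the per-accession unique-band
#' quotas (ISSR 8/4/12, SCoT 23/7/29, protein 2/0/0 for C1/C2/C3), barcode
#' divergences in which the first two accessions are close and the third
#' set apart (p-distance 0.01 within the close pair, 0.15 to the
#' outgroup, locus length 500 bp), expression truth with all three target
#' genes upregulated in the third accession relative to the first
#' (calibrator), and replicate trait means with the third accession
#' highest for most traits. Replicate noise: 0.2 cycles per Ct
#' measurement, 3 qPCR replicates; 3 trait replicates with a 5%
#' coefficient of variation.
#'
#' @param n_accessions panel size (default 3, accessions C1..C3).
#' @return nested list with elements `accessions`, `markers`, `barcode`,
#'   `expression`, `traits`; see the generator functions.
#' @export
study_profile <- function(n_accessions = 3) {
  acc <- paste0("C", seq_len(n_accessions))
  classes <- published_band_classes()
  ub_quota <- list(
    ISSR = c(C1 = 8, C2 = 4, C3 = 12),
    SCoT = c(C1 = 23, C2 = 7, C3 = 29),
    PROTEIN = c(C1 = 2, C2 = 0, C3 = 0))
  genes <- c("PAL1", "defensin", "AFPRT")
  folds <- rbind(C1 = c(1, 1, 1),
                 C2 = c(2.7, 3.8, 3.7),   # geometric midpoints
                 C3 = c(7.26, 14.60, 13.81))
  colnames(folds) <- genes
  trait_means <- rbind(
    C1 = c(TPC = 70.00, TFC = 55.00, alkaloids = 0.87, saponins = 35.00,
           tannins = 1.10, SOD = 10.00, POD = 40.00, CAT = 22.00,
           APX = 16.00),
    C2 = c(TPC = 80.00, TFC = 63.00, alkaloids = 0.70, saponins = 43.65,
           tannins = 1.43, SOD = 13.00, POD = 50.00, CAT = 28.00,
           APX = 21.00),
    C3 = c(TPC = 92.54, TFC = 77.13, alkaloids = 0.55, saponins = 49.67,
           tannins = 1.87, SOD = 16.87, POD = 60.87, CAT = 35.76,
           APX = 27.98))
  list(
    accessions = acc,
    markers = list(classes = classes, ub_quota = ub_quota,
                   close_pair = c("C1", "C2"), nb_close_share = 0.75),
    barcode = list(length = 500, close_pair = c("C1", "C2"),
                   outgroup = "C3", d_close = 0.01, d_far = 0.15),
    expression = list(genes = genes, samples = acc, reference = "ACT",
                      calibrator = "C1", folds = folds, base_dct = 3,
                      ref_ct = 20, sd_ct = 0.2, n_reps = 3),
    traits = list(means = trait_means, cv = 0.05, n_reps = 3))
}

#' Generate a panel of band matrices from a study profile
#'
#' Builds one [band_matrix()] per primer of the profile with exactly the
#' profile's (MB, UB, NB) composition. Within each marker system the
#' accession carrying each unique band is dealt from the per-accession
#' quota (e.g., 8/4/12 unique ISSR bands for C1/C2/C3) in a seeded random
#' order, so [classify_bands()] on every output matches the profile and
#' the marker-level unique-band totals match the quotas.
#'
#' @param profile a [study_profile()] (or any list with the same
#'   `markers` element).
#' @param seed integer seed; same seed, identical matrices.
#' @param marker optional marker-system filter (`"ISSR"`, `"SCoT"`,
#'   `"PROTEIN"`).
#' @return named list of [band_matrix()] objects.
#' @export
gen_band_study <- function(profile = study_profile(), seed = 1,
                           marker = NULL) {
  classes <- profile$markers$classes
  if (is.null(classes) || nrow(classes) == 0) stop("profile has no primers")
  if (!is.null(marker)) classes <- classes[classes$marker %in% marker, ]
  if (nrow(classes) == 0) stop("no primers for marker ", marker)
  acc <- profile$accessions
  # non-unique (shared-by-two) bands fall on the profile's close accession
  # pair with probability nb_close_share, uniformly on other pairs
  nb_w <- NULL
  cp <- profile$markers$close_pair
  if (!is.null(cp) && length(acc) == 3) {
    pairs <- utils::combn(length(acc), 2)
    share <- profile$markers$nb_close_share %||% 0.75
    nb_w <- rep((1 - share) / (ncol(pairs) - 1), ncol(pairs))
    hit <- which(apply(pairs, 2, function(p)
      setequal(acc[p], cp)))
    nb_w[hit] <- share
  }
  out <- list()
  with_rng(seed, {
    for (mk in unique(classes$marker)) {
      sub <- classes[classes$marker == mk, , drop = FALSE]
      quota <- profile$markers$ub_quota[[mk]]
      total_ub <- sum(sub$ub)
      if (!is.null(quota)) {
        if (sum(quota) != total_ub)
          stop(sprintf(
            "unique-band quota for %s sums to %d but composition has %d",
            mk, sum(quota), total_ub))
        owners <- sample(rep(names(quota), quota))
      } else owners <- NULL
      k <- 0
      for (i in seq_len(nrow(sub))) {
        ub_i <- sub$ub[i]
        own_i <- if (is.null(owners) || ub_i == 0) NULL else
          owners[(k + 1):(k + ub_i)]
        k <- k + ub_i
        out[[sub$primer[i]]] <- matrix_from_composition(
          sub$mb[i], ub_i, sub$nb[i], n_accessions = length(acc),
          seed = sample.int(2^30, 1), accession_ids = acc,
          ub_owners = own_i, nb_pair_weights = nb_w,
          primer_id = sub$primer[i], marker_system = mk)
      }
    }
  })
  out
}

# substitute `k` random sites of a sequence vector to a different base
mutate_seq <- function(x, rate) {
  k <- round(rate * length(x))
  if (k == 0) return(x)
  sites <- sample.int(length(x), k)
  for (s in sites)
    x[s] <- sample(setdiff(c("A", "C", "G", "T"), x[s]), 1)
  x
}

#' Generate an aligned set of barcode sequences
#'
#' Simulates i.i.d. substitutions from a random root sequence down an
#' ultrametric three-taxon topology: the close pair diverges at p-distance
#' `d_close`, the outgroup at `d_far` from both. Realized pairwise
#' p-distances fall within 3 * sqrt(d (1 - d) / L) of the targets (slight
#' downward bias from coincident substitutions at higher rates).
#'
#' @inheritParams gen_band_study
#' @return a [dna_alignment()] of the profile's accessions.
#' @export
gen_alignment <- function(profile = study_profile(), seed = 1) {
  bc <- profile$barcode
  L <- bc$length
  if (L < 50) stop("barcode length must be >= 50")
  if (any(c(bc$d_close, bc$d_far) < 0) || any(c(bc$d_close, bc$d_far) >= 0.75))
    stop("divergence rates must be in [0, 0.75)")
  with_rng(seed, {
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    anc_close <- mutate_seq(root, max(0, bc$d_far / 2 - bc$d_close / 2))
    tip <- list()
    tip[[bc$close_pair[1]]] <- mutate_seq(anc_close, bc$d_close / 2)
    tip[[bc$close_pair[2]]] <- mutate_seq(anc_close, bc$d_close / 2)
    tip[[bc$outgroup]] <- mutate_seq(root, bc$d_far / 2)
    seqs <- vapply(profile$accessions, function(a)
      paste(tip[[a]], collapse = ""), "")
    dna_alignment(seqs)
  })
}

#' Generate a replicate Ct table with known fold-change truth
#'
#' Reference-gene Ct replicates are drawn as `ref_ct` + noise; target-gene
#' Ct replicates as `ref_ct + base_dct - log2(fold)` + noise, with
#' independent N(0, sd_ct) noise per Ct measurement, so that
#' [fold_changes()] recovers the profile's fold truth (exactly when
#' `sd_ct = 0`).
#'
#' @inheritParams gen_band_study
#' @return data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(profile = study_profile(), seed = 1) {
  ex <- profile$expression
  if (ex$sd_ct < 0) stop("sd_ct must be >= 0")
  stopifnot(ex$n_reps >= 1)
  with_rng(seed, {
    rows <- list()
    for (s in ex$samples) {
      for (r in seq_len(ex$n_reps))
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, gene = ex$reference, replicate = r,
          ct = ex$ref_ct + stats::rnorm(1, 0, ex$sd_ct))
      for (g in ex$genes) for (r in seq_len(ex$n_reps))
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, gene = g, replicate = r,
          ct = ex$ref_ct + ex$base_dct - log2(ex$folds[s, g]) +
            stats::rnorm(1, 0, ex$sd_ct))
    }
    do.call(rbind, rows)
  })
}

#' Generate a replicate trait table with known means
#'
#' Normal replicate noise around the profile's per-accession trait means
#' with standard deviation `cv * |mean|` (coefficient of variation).
#'
#' @inheritParams gen_band_study
#' @return data frame with columns `accession`, `trait`, `replicate`,
#'   `value`.
#' @export
gen_trait_table <- function(profile = study_profile(), seed = 1) {
  tr <- profile$traits
  if (tr$cv < 0) stop("coefficient of variation must be >= 0")
  if (tr$n_reps < 2) stop("need >= 2 replicates per (accession, trait)")
  m <- tr$means
  with_rng(seed, {
    out <- expand.grid(accession = rownames(m), trait = colnames(m),
                       replicate = seq_len(tr$n_reps),
                       stringsAsFactors = FALSE)
    mu <- m[cbind(out$accession, out$trait)]
    out$value <- stats::rnorm(nrow(out), mu, tr$cv * abs(mu))
    out[order(out$trait, out$accession, out$replicate), ]
  })
}
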