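#' Binary band matrix for a dominant marker primer
#'
#' A `band_matrix` holds the presence/absence scores of the bands amplified
#' by one primer (or resolved on one protein gel) across a panel of
#' accessions. Dominant markers such as ISSR and SCoT are scored 1 for the
#' presence and 0 for the absence of a band; heterozygotes are
#' indistinguishable from dominant homozygotes, so the 0/1 matrix is the
#' complete data.
#'
#' Invariants enforced: every cell is 0 or 1; no band column is all zero
#' (a band that was never observed is a scoring artifact, not a band);
#' accession ids are unique; `band_sizes`, when given, has one positive
#' size per band (bp for DNA markers, kDa for protein).
#'
#' @param presence numeric/integer matrix of 0/1 with at least 2 rows
#'   (accessions) and 1 column (bands). Row names are accession ids;
#'   missing dimnames are filled in.
#' @param primer_id character scalar naming the primer/gel.
#' @param marker_system one of `"ISSR"`, `"SCoT"`, `"PROTEIN"`, `"OTHER"`.
#' @param band_sizes optional numeric vector of fragment sizes, one per band.
#' @return An object of class `band_matrix`: a list with elements
#'   `primer_id`, `marker_system`, `accession_ids`, `band_sizes`,
#'   `presence` (integer matrix with dimnames).
#' @examples
#' m <- band_matrix(rbind(C1 = c(1, 1, 0), C2 = c(1, 0, 0), C3 = c(1, 0, 1)),
#'                  primer_id = "ISSRx")
#' classify_bands(m)
#' @export
band_matrix <- function(presence, primer_id = "primer",
                        marker_system = c("OTHER", "ISSR", "SCoT", "PROTEIN"),
                        band_sizes = NULL) {
  marker_system <- match.arg(toupper(marker_system[1]),
                             c("OTHER", "ISSR", "SCOT", "PROTEIN"))
  if (marker_system == "SCOT") marker_system <- "SCoT"
  presence <- as.matrix(presence)
  if (nrow(presence) < 2) stop("a band matrix needs at least 2 accessions")
  if (ncol(presence) < 1) stop("a band matrix needs at least 1 band")
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("C", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("B", seq_len(ncol(presence)))
  bad <- which(!(presence %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(presence)) + 1
    j <- ((bad[1] - 1) %/% nrow(presence)) + 1
    stop(sprintf("non-binary cell at accession '%s', band '%s': %s",
                 rownames(presence)[i], colnames(presence)[j],
                 format(presence[i, j])))
  }
  storage.mode(presence) <- "integer"
  if (anyDuplicated(rownames(presence)))
    stop("duplicate accession id: ",
         rownames(presence)[duplicated(rownames(presence))][1])
  zero <- colSums(presence) == 0
  if (any(zero))
    stop("all-zero band column(s): ",
         paste(colnames(presence)[zero], collapse = ", "),
         " (a never-observed band is not a band)")
  if (!is.null(band_sizes)) {
    if (length(band_sizes) != ncol(presence))
      stop("band_sizes must have one entry per band")
    if (any(!is.finite(band_sizes)) || any(band_sizes <= 0))
      stop("band_sizes must all be positive")
  }
  structure(
    list(primer_id = as.character(primer_id), marker_system = marker_system,
         accession_ids = rownames(presence), band_sizes = band_sizes,
         presence = presence),
    class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix '%s' (%s): %d accessions x %d bands\n",
              x$primer_id, x$marker_system,
              nrow(x$presence), ncol(x$presence)))
  print(x$presence)
  invisible(x)
}

#' Read a scored band matrix from CSV
#'
#' Fixed dialect: comma-separated UTF-8, header row of band labels, first
#' column of accession ids, cells 0/1. [write_band_csv()] emits the same
#' dialect, so write/read round-trips are bit-exact.
#'
#' @param path CSV file path.
#' @param primer_id primer label; default the file name without extension.
#' @param marker_system marker system label, see [band_matrix()].
#' @return A [band_matrix()].
#' @export
read_band_csv <- function(path, primer_id = NULL, marker_system = "OTHER") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (ncol(df) < 2) stop("band CSV needs an accession column plus >=1 band")
  acc <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    i <- ((bad - 1) %% nrow(cells)) + 1
    j <- ((bad - 1) %/% nrow(cells)) + 1
    stop(sprintf("cell for accession '%s', band '%s' is not 0/1: '%s'",
                 acc[i], colnames(cells)[j], cells[i, j]))
  }
  m <- matrix(as.integer(cells), nrow = nrow(cells),
              dimnames = list(acc, colnames(cells)))
  band_matrix(m, primer_id = primer_id %||%
                sub("\\.[^.]*$", "", basename(path)),
              marker_system = marker_system)
}

#' Write a band matrix to CSV
#'
#' @param m a [band_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @rdname read_band_csv
#' @export
write_band_csv <- function(m, path) {
  stopifnot(inherits(m, "band_matrix"))
  df <- data.frame(accession = rownames(m$presence), m$presence,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify bands as monomorphic, unique or non-unique polymorphic
#'
#' A band present in every accession is monomorphic (MB); present in exactly
#' one accession, unique (UB); present in more than one but not all,
#' non-unique polymorphic (NB). Polymorphic bands PB = UB + NB and total
#' bands TB = MB + PB. Classes are derived from band frequencies, so any
#' panel size works.
#'
#' @param m a [band_matrix()].
#' @return An object of class `band_class_counts`: list with integer counts
#'   `mb`, `ub`, `nb`, `pb`, `tb` and `freq`, the per-band presence
#'   frequencies p_b = (accessions carrying band b) / A.
#' @export
classify_bands <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  A <- nrow(m$presence)
  n_present <- colSums(m$presence)
  counts <- list(
    mb = sum(n_present == A),
    ub = sum(n_present == 1 & A > 1),
    nb = sum(n_present > 1 & n_present < A),
    freq = n_present / A)
  counts$pb <- counts$ub + counts$nb
  counts$tb <- counts$mb + counts$pb
  structure(counts, class = "band_class_counts")
}

#' @export
print.band_class_counts <- function(x, ...) {
  cat(sprintf("bands: %d total = %d monomorphic + %d unique + %d non-unique\n",
              x$tb, x$mb, x$ub, x$nb))
  invisible(x)
}

#' Reconstruct a band matrix from published band-class counts
#'
#' Diversity papers typically publish only the per-primer counts of
#' monomorphic (MB), unique (UB) and non-unique polymorphic (NB) bands, not
#' the raw 0/1 matrix. Every marker statistic in this package depends on the
#' band frequency spectrum alone, and for a panel of A accessions the class
#' counts fix that spectrum up to the (irrelevant) assignment of bands to
#' accessions; for A = 3 every unique band has frequency 1/3 and every
#' non-unique band exactly 2/3. This builder realizes one matrix with the
#' requested composition, drawing the accession assignment of UB/NB bands
#' from a seeded RNG (or honouring explicit quotas via `ub_owners`).
#'
#' @param mb,ub,nb non-negative counts of monomorphic, unique and non-unique
#'   polymorphic bands; `mb + ub + nb >= 1`.
#' @param n_accessions panel size A (>= 2; >= 3 when `nb > 0`).
#' @param seed integer seed for the accession assignment.
#' @param accession_ids optional accession labels (default C1..CA).
#' @param ub_owners optional character vector of length `ub` naming the
#'   accession carrying each unique band (overrides random placement).
#' @param nb_pair_weights optional sampling weights for which accession
#'   subset carries each non-unique band; a numeric vector over the
#'   columns of `utils::combn(n_accessions, 2)` (only meaningful when the
#'   non-unique bands are pairs, i.e. A = 3). Default: uniform.
#' @param primer_id,marker_system,band_sizes passed to [band_matrix()].
#' @return A [band_matrix()] whose [classify_bands()] equals the request.
#' @examples
#' m <- matrix_from_composition(4, 4, 1, seed = 1, primer_id = "ISSR1")
#' classify_bands(m)
#' @export
matrix_from_composition <- function(mb, ub, nb, n_accessions = 3, seed = 1,
                                    accession_ids = NULL, ub_owners = NULL,
                                    nb_pair_weights = NULL,
                                    primer_id = "primer",
                                    marker_system = "OTHER",
                                    band_sizes = NULL) {
  mb <- as.integer(mb); ub <- as.integer(ub); nb <- as.integer(nb)
  A <- as.integer(n_accessions)
  if (any(c(mb, ub, nb) < 0)) stop("band-class counts must be >= 0")
  if (mb + ub + nb < 1) stop("composition needs at least one band")
  if (A < 2) stop("need at least 2 accessions")
  if (nb > 0 && A < 3)
    stop("infeasible composition: a non-unique polymorphic band needs ",
         "presence in >1 but not all accessions, impossible with A = ", A)
  acc <- accession_ids %||% paste0("C", seq_len(A))
  if (length(acc) != A) stop("accession_ids must have length n_accessions")
  if (!is.null(ub_owners)) {
    if (length(ub_owners) != ub) stop("ub_owners must have length ub")
    if (!all(ub_owners %in% acc)) stop("unknown accession in ub_owners")
  }
  with_rng(seed, {
    cols <- vector("list", mb + ub + nb)
    k <- 0
    for (i in seq_len(mb)) cols[[k <- k + 1]] <- rep(1L, A)
    for (i in seq_len(ub)) {
      v <- rep(0L, A)
      owner <- if (is.null(ub_owners)) sample.int(A, 1) else
        match(ub_owners[i], acc)
      v[owner] <- 1L
      cols[[k <- k + 1]] <- v
    }
    pairs <- utils::combn(A, 2)
    if (!is.null(nb_pair_weights) && length(nb_pair_weights) != ncol(pairs))
      stop("nb_pair_weights needs one weight per accession pair")
    for (i in seq_len(nb)) {
      v <- rep(0L, A)
      size <- if (A == 3) 2L else sample(2:(A - 1), 1)
      if (size == 2) {
        pick <- sample.int(ncol(pairs), 1, prob = nb_pair_weights)
        v[pairs[, pick]] <- 1L
      } else v[sample.int(A, size)] <- 1L
      cols[[k <- k + 1]] <- v
    }
    m <- do.call(cbind, cols)
    rownames(m) <- acc
    colnames(m) <- paste0("B", seq_len(ncol(m)))
    band_matrix(m, primer_id = primer_id, marker_system = marker_system,
                band_sizes = band_sizes)
  })
}
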