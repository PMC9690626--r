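#' Run the full characterization pipeline
#'
#' Orchestrates every analysis stage from a single configuration: dominant
#' marker statistics and UPGMA clustering from a directory of band CSVs,
#' barcode descriptive statistics and a bootstrapped UPGMA tree from an
#' aligned FASTA, 2^-ddCt fold changes from a Ct CSV, and trait
#' ANOVA/Duncan/Pearson from a replicate trait CSV. Stages whose inputs
#' are absent from the config are skipped. Numeric outputs are written at
#' full precision as CSV (plus Newick trees), and a `manifest.csv` listing
#' every output with its MD5 hash is written last; reruns with the same
#' inputs and seed reproduce the hashes.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure. Recognized entries:
#'   \describe{
#'     \item{bands}{list: `dir` (directory of band CSVs) or `files`;
#'       optional `marker_system`, `metric` (default jaccard),
#'       `rp_convention` (default doubled_frequency), `pic_overrides`
#'       (CSV path with columns primer, pic).}
#'     \item{barcode}{list: `fasta` (aligned FASTA), optional `bootstrap`
#'       (default 200), `gap_policy`.}
#'     \item{expression}{list: `ct_csv`, `reference`, `calibrator`.}
#'     \item{traits}{list: `csv`, optional `alpha` (default 0.05),
#'       `aggregate`.}
#'     \item{seed}{integer seed for the bootstrap stage (default 1).}
#'   }
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of the stage results plus
#'   `manifest` (data frame: file, md5).
#' @export
run_characterization <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  results <- list()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs[[length(outputs) + 1]] <<- path
    path
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] started", name))
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  if (!is.null(config$bands)) {
    results$markers <- stage("markers", {
      bc <- config$bands
      files <- bc$files %||%
        list.files(bc$dir, pattern = "\\.csv$", full.names = TRUE)
      if (length(files) == 0) stop("no band CSV files found")
      mats <- lapply(sort(files), read_band_csv,
                     marker_system = bc$marker_system %||% "OTHER")
      overrides <- NULL
      if (!is.null(bc$pic_overrides)) {
        ov <- utils::read.csv(bc$pic_overrides, stringsAsFactors = FALSE)
        overrides <- stats::setNames(ov$pic, ov$primer)
      }
      ms <- marker_summary(mats, pic_overrides = overrides,
                           rp_convention = bc$rp_convention %||%
                             "doubled_frequency")
      emit(ms$per_primer, "markers_per_primer.csv")
      emit(data.frame(statistic = c(names(ms$totals), "overall_p_pct"),
                      total = c(unname(ms$totals), NA),
                      average = c(unname(ms$averages), NA),
                      value = c(rep(NA, length(ms$totals)),
                                ms$overall_p_pct)),
           "markers_summary.csv")
      d <- band_distance(mats, metric = bc$metric %||% "jaccard")
      emit(data.frame(accession = rownames(d), d, check.names = FALSE),
           "bands_distance.csv")
      nwk <- file.path(out_dir, "bands_upgma.nwk")
      to_newick(upgma(d), file = nwk)
      outputs[[length(outputs) + 1]] <- nwk
      ms
    })
  }

  if (!is.null(config$barcode)) {
    results$barcode <- stage("barcode", {
      bc <- config$barcode
      seqs <- read_fasta(bc$fasta)
      emit(barcode_stats(seqs), "barcode_stats.csv")
      al <- dna_alignment(seqs)
      tr <- bootstrap_tree(al, n_reps = bc$bootstrap %||% 200, seed = seed,
                           gap_policy = bc$gap_policy %||%
                             "pairwise_deletion")
      nwk <- file.path(out_dir, "barcode_tree.nwk")
      to_newick(tr, file = nwk)
      outputs[[length(outputs) + 1]] <- nwk
      d <- p_distance(al)
      emit(data.frame(id = rownames(d), d, check.names = FALSE),
           "barcode_pdistance.csv")
      tr
    })
  }

  if (!is.null(config$expression)) {
    results$expression <- stage("expression", {
      ec <- config$expression
      fc <- fold_changes(read_ct_csv(ec$ct_csv),
                         reference = ec$reference,
                         calibrator = ec$calibrator)
      emit(fc, "expression_folds.csv")
      fc
    })
  }

  if (!is.null(config$traits)) {
    results$traits <- stage("traits", {
      tc <- config$traits
      traits <- utils::read.csv(tc$csv, stringsAsFactors = FALSE)
      cmp <- trait_compare(traits, alpha = tc$alpha %||% 0.05)
      emit(cmp, "traits_compare.csv")
      r <- pearson_matrix(traits,
                          aggregate = tc$aggregate %||% "replicate_level")
      emit(data.frame(trait = rownames(r), r, check.names = FALSE),
           "traits_pearson.csv")
      cmp
    })
  }

  if (length(outputs) == 0) stop("empty config: no stage inputs given")
  manifest <- data.frame(file = basename(unlist(outputs)),
                         md5 = unname(tools::md5sum(unlist(outputs))),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  results$manifest <- manifest
  invisible(results)
}
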