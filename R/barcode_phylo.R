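IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Read / write FASTA sequences
#'
#' Thin wrappers over `ape`'s FASTA I/O returning sequences as a named
#' uppercase character vector (one string per record), the representation
#' the barcode functions in this package use. Alphabet is IUPAC DNA plus
#' the gap character `-`.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bin <- ape::read.FASTA(path)
  out <- vapply(as.character(bin), function(s)
    paste(toupper(s), collapse = ""), "")
  check_dna(out)
  out
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  check_dna(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i] %||% paste0("seq", i)), con)
    writeLines(seqs[[i]], con)
  }
  invisible(path)
}

check_dna <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences")
  if (any(!nzchar(seqs))) stop("empty sequence")
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(toupper(seqs[[i]]), "")[[1]])
    bad <- setdiff(ch, IUPAC_DNA)
    if (length(bad))
      stop(sprintf("sequence '%s' has non-IUPAC character(s): %s",
                   names(seqs)[i] %||% i, paste(bad, collapse = "")))
  }
  invisible(seqs)
}

#' GC content of a DNA sequence
#'
#' 100 * (G + C) / counted bases. Gaps are never counted.
#' `ambiguity = "exclude"` (default) drops N and all other ambiguity codes
#' from the denominator; `"count_S"` additionally counts the S (G or C)
#' code as G+C and keeps the unambiguous denominator plus S.
#'
#' @param s a DNA string (IUPAC).
#' @param ambiguity `"exclude"` or `"count_S"`.
#' @return percent in [0, 100].
#' @export
gc_content <- function(s, ambiguity = c("exclude", "count_S")) {
  ambiguity <- match.arg(ambiguity)
  check_dna(s[1])
  ch <- strsplit(toupper(s[1]), "")[[1]]
  gc <- sum(ch %in% c("G", "C"))
  denom <- sum(ch %in% c("A", "C", "G", "T", "U"))
  if (ambiguity == "count_S") {
    gc <- gc + sum(ch == "S")
    denom <- denom + sum(ch == "S")
  }
  if (denom == 0) stop("no countable bases")
  100 * gc / denom
}

# semi-global Needleman-Wunsch: match +1, mismatch -1, linear gap -2,
# terminal gaps free. Among co-optimal alignments the identity is made
# well-defined (and symmetric in the two sequences) by maximizing the
# number of matched columns, then minimizing aligned columns, over all
# score-optimal paths — never by an arbitrary traceback tie-break.
nw_overlap <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("empty sequence")
  S <- matrix(0, n + 1, m + 1)     # free leading gaps
  for (i in seq_len(n)) {
    sub <- ifelse(y == x[i], 1, -1)
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] - 2,
                             S[i + 1, j] - 2)
  }
  # second pass over "tight" edges (those achieving the DP maximum): every
  # path of tight edges from the free start boundary is score-optimal, so
  # maximizing (matches, -columns) over them ranges over optimal alignments
  M <- matrix(-Inf, n + 1, m + 1)  # max matches on an optimal prefix
  Cl <- matrix(Inf, n + 1, m + 1)  # columns of that prefix (lexicographic)
  M[, 1] <- 0; Cl[, 1] <- 0; M[1, ] <- 0; Cl[1, ] <- 0
  for (i in seq_len(n)) {
    sub <- ifelse(y == x[i], 1, -1)
    for (j in seq_len(m)) {
      s <- S[i + 1, j + 1]
      bm <- -Inf; bc <- Inf
      consider <- function(pm, pc, add_match) {
        pm <- pm + add_match; pc <- pc + 1
        if (pm > bm || (pm == bm && pc < bc)) { bm <<- pm; bc <<- pc }
      }
      if (s == S[i, j] + sub[j] && is.finite(M[i, j]))
        consider(M[i, j], Cl[i, j], as.integer(sub[j] == 1))
      if (s == S[i, j + 1] - 2 && is.finite(M[i, j + 1]))
        consider(M[i, j + 1], Cl[i, j + 1], 0L)
      if (s == S[i + 1, j] - 2 && is.finite(M[i + 1, j]))
        consider(M[i + 1, j], Cl[i + 1, j], 0L)
      M[i + 1, j + 1] <- bm; Cl[i + 1, j + 1] <- bc
    }
  }
  ends <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n), m + 1))
  sc <- S[ends]
  best <- max(sc)
  cand <- ends[sc == best & is.finite(M[ends]), , drop = FALSE]
  if (nrow(cand) == 0)  # optimum is the empty overlap
    return(list(score = best, matches = 0L, columns = 0L))
  mm <- M[cand]; cc <- Cl[cand]
  ord <- order(-mm, cc)
  list(score = best, matches = mm[ord[1]], columns = cc[ord[1]])
}

#' Percent pairwise identity of two DNA sequences
#'
#' Globally aligns the two (unaligned) sequences with match +1,
#' mismatch -1, linear gap -2 and free terminal gaps (semi-global), then
#' returns 100 * matches / aligned columns, terminal-gap columns excluded.
#' Identical sequences give exactly 100.
#'
#' @param a,b DNA strings.
#' @return percent in [0, 100].
#' @export
pairwise_identity <- function(a, b) {
  check_dna(a[1]); check_dna(b[1])
  al <- nw_overlap(a[1], b[1])
  if (al$columns == 0) return(0)  # optimal alignment is the empty overlap
  100 * al$matches / al$columns
}

#' Multiple sequence alignment container
#'
#' Validates >= 2 equal-length IUPAC DNA sequences (gap `-` allowed) with
#' at least one column that is not all-gap, and stores them as an
#' uppercase character matrix (rows = sequences, columns = sites).
#'
#' @param seqs named character vector of aligned sequences.
#' @return object of class `dna_alignment`: the character matrix.
#' @export
dna_alignment <- function(seqs) {
  check_dna(seqs)
  if (length(seqs) < 2) stop("an alignment needs >= 2 sequences")
  L <- nchar(seqs)
  if (length(unique(L)) != 1) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  if (!any(colSums(m != "-") > 0))
    stop("alignment has no non-gap column")
  structure(m, class = c("dna_alignment", class(m)))
}

#' p-distance matrix of an alignment
#'
#' Proportion of differing sites per pair. Gaps and ambiguity codes are
#' treated as missing: under `"pairwise_deletion"` each pair uses its own
#' set of jointly resolved sites; `"complete_deletion"` first drops every
#' column with any missing state. Distances computed with
#' [ape::dist.dna()] (model `"raw"`).
#'
#' @param al a [dna_alignment()] (or named character vector of aligned
#'   sequences).
#' @param gap_policy `"pairwise_deletion"` or `"complete_deletion"`.
#' @return square symmetric matrix of distances in [0, 1].
#' @export
p_distance <- function(al,
                       gap_policy = c("pairwise_deletion",
                                      "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  if (!inherits(al, "dna_alignment")) al <- dna_alignment(al)
  bin <- ape::as.DNAbin(unclass(al))
  d <- ape::dist.dna(bin, model = "raw",
                     pairwise.deletion = gap_policy == "pairwise_deletion")
  dm <- as.matrix(d)
  if (anyNA(dm) || any(!is.finite(dm)))
    stop("a sequence pair has zero comparable sites")
  dm
}

#' Bootstrap-supported UPGMA tree from an alignment
#'
#' Builds the UPGMA tree of the alignment's p-distance matrix, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds
#' the tree per replicate, and reports for each internal node the percent
#' of replicates containing the same leaf bipartition (clade of the rooted
#' tree, which is rotation-invariant). Supports are stored as node labels
#' and appear in the Newick output of [to_newick()].
#'
#' A degenerate alignment whose columns are all identical yields a tree
#' with all supports 0 and a warning (no information to resample).
#'
#' @param al a [dna_alignment()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; same seed, same supports.
#' @param gap_policy passed to [p_distance()].
#' @return an `ape::phylo` with `node.label` = percent support (root
#'   label NA).
#' @export
bootstrap_tree <- function(al, n_reps = 2000, seed = 1,
                           gap_policy = "pairwise_deletion") {
  if (!inherits(al, "dna_alignment")) al <- dna_alignment(al)
  if (nrow(al) < 3) stop("bootstrap tree needs >= 3 sequences")
  stopifnot(n_reps >= 1)
  main <- upgma(p_distance(al, gap_policy))
  degenerate <- all(apply(unclass(al), 2, function(col)
    length(unique(col)) == 1))
  if (degenerate)
    warning("all alignment columns identical: supports carry no information")
  L <- ncol(al)
  reps <- with_rng(seed, lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- unclass(al)[, cols, drop = FALSE]
    d <- tryCatch(
      p_distance(structure(boot, class = c("dna_alignment", "matrix")),
                 gap_policy),
      error = function(e) NULL)
    if (is.null(d)) NULL else upgma(d)
  }))
  reps <- Filter(Negate(is.null), reps)
  supports <- clade_support(main, reps)
  main$node.label <- supports
  main
}

# percent of replicate rooted trees containing each internal clade of `main`
clade_support <- function(main, reps) {
  ntip <- ape::Ntip(main)
  nnode <- main$Nnode
  main_clades <- lapply(seq_len(nnode) + ntip, function(nd)
    sort(main$tip.label[unlist(tips_under(main, nd))]))
  counts <- integer(nnode)
  for (tr in reps) {
    tr_clades <- lapply(seq_len(tr$Nnode) + ape::Ntip(tr), function(nd)
      sort(tr$tip.label[unlist(tips_under(tr, nd))]))
    keys <- vapply(tr_clades, paste, "", collapse = "\r")
    for (k in seq_len(nnode))
      if (paste(main_clades[[k]], collapse = "\r") %in% keys)
        counts[k] <- counts[k] + 1L
  }
  if (length(reps) == 0) rep(0, nnode) else
    round(100 * counts / length(reps), 1)
}

# tips descending from an internal node (no phangorn dependency)
tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Descriptive statistics of barcode sequences
#'
#' Length (bp, gaps excluded) and GC% per record.
#'
#' @param seqs named character vector of sequences.
#' @param ambiguity passed to [gc_content()].
#' @return data frame: `id`, `length_bp`, `gc_pct`.
#' @export
barcode_stats <- function(seqs, ambiguity = "exclude") {
  check_dna(seqs)
  data.frame(
    id = names(seqs) %||% paste0("seq", seq_along(seqs)),
    length_bp = vapply(seqs, function(s)
      sum(strsplit(s, "")[[1]] != "-"), 0L),
    gc_pct = vapply(seqs, gc_content, 0, ambiguity = ambiguity),
    row.names = NULL, stringsAsFactors = FALSE)
}
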