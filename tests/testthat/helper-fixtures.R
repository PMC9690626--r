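# shared fixtures, built in code

issr1_matrix <- function(seed = 1)
  matrix_from_composition(4, 4, 1, n_accessions = 3, seed = seed,
                          primer_id = "ISSR1", marker_system = "ISSR")

# brute-force marker statistics recomputed from raw matrix cells,
# independent of classify_bands()/emr()/rp()
brute_stats <- function(m) {
  X <- m$presence
  A <- nrow(X)
  p <- colSums(X) / A
  pb <- sum(p < 1)
  tb <- ncol(X)
  list(pb = pb, tb = tb,
       emr = pb * (pb / tb),
       p_pct = 100 * pb / tb,
       rp_doubled = sum(2 * p),
       rp_prevost = sum(1 - 2 * abs(0.5 - p)),
       pic = mean(1 - p^2 - (1 - p)^2))
}

# published per-primer PIC values keyed by primer id
published_pic <- function() {
  df <- published_band_classes()
  stats::setNames(df$pic_published, df$primer)
}
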