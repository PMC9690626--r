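test_that("PIC under the per-band 2pq mean matches hand values", {
  mono <- band_matrix(matrix(1, 3, 4))
  expect_equal(pic(mono), 0)
  # single band carried by 1 of 3 accessions: 2 * (1/3) * (2/3)
  one <- band_matrix(rbind(C1 = 1, C2 = 0, C3 = 0))
  expect_equal(pic(one), 4 / 9)
  # ISSR1 composition: 5 polymorphic bands at 2pq = 4/9 averaged over 9
  expect_equal(pic(issr1_matrix()), (5 * 4 / 9) / 9)
  expect_equal(round(pic(issr1_matrix()), 4), 0.2469)
  expect_error(pic(issr1_matrix(), method = "nonsense"))
})

test_that("EMR is the squared polymorphic count over total bands", {
  expect_equal(round(emr(issr1_matrix()), 2), 2.78)          # PB=5, TB=9
  mono <- band_matrix(matrix(1, 3, 6))
  expect_equal(emr(mono), 0)                                  # PB=0
  all_poly <- matrix_from_composition(0, 12, 7, seed = 2)     # PB=TB=19
  expect_equal(emr(all_poly), 19)
})

test_that("MI is the PIC x EMR product", {
  expect_equal(round(mi(0.72, 64 / 9), 2), 5.12)
  expect_equal(round(mi(0.77, 19), 2), 14.63)
  expect_equal(mi(0, 7), 0)
  expect_error(mi(-1, 2))
})

test_that("RP conventions match hand sums", {
  m <- issr1_matrix()
  # doubled frequency: 4 bands at p=1, 4 at p=1/3, 1 at p=2/3
  expect_equal(rp(m), 4 * 2 + 4 * (2 / 3) + 1 * (4 / 3))
  expect_equal(rp(m), 12)
  mono <- band_matrix(matrix(1, 3, 7))
  expect_equal(rp(mono), 14)                      # 2n for n monomorphic
  # Prevost form: monomorphic bands contribute 0, others 1 - 2|0.5 - p|
  expect_equal(rp(m, "prevost"), 5 * (2 / 3))
  expect_equal(round(rp(m, "prevost"), 2), 3.33)
  expect_error(rp(m, "nonsense"))
})

test_that("percent polymorphism comes from the polymorphic fraction", {
  expect_equal(round(polymorphism_pct(issr1_matrix()), 2), 55.56)
  expect_equal(polymorphism_pct(band_matrix(matrix(1, 3, 5))), 0)
  expect_equal(polymorphism_pct(matrix_from_composition(0, 12, 7, seed = 1)),
               100)
})

test_that("EMR <= TB with equality iff fully polymorphic (exhaustive)", {
  # enumerate all compositions with TB <= 12 at A = 3 and compare with a
  # brute-force oracle recomputed from raw matrix cells
  for (tb in 1:12) for (mb in 0:tb) for (ub in 0:(tb - mb)) {
    nb <- tb - mb - ub
    m <- matrix_from_composition(mb, ub, nb, seed = tb * 100 + mb * 10 + ub)
    o <- brute_stats(m)
    expect_equal(emr(m), o$emr)
    expect_equal(rp(m), o$rp_doubled)
    expect_equal(polymorphism_pct(m), o$p_pct)
    expect_lte(emr(m), o$tb)
    if (o$pb == o$tb) expect_equal(emr(m), o$tb)
    if (o$pb < o$tb) expect_lt(emr(m), o$tb)
  }
})

test_that("marker_summary reproduces the published 21-primer panel", {
  ov <- published_pic()
  ref <- published_band_classes()

  issr <- marker_summary(reference_band_matrices("ISSR", seed = 3),
                         pic_overrides = ov)
  expect_equal(sum(issr$per_primer$tb), 70)
  expect_equal(round(issr$overall_p_pct, 2), 55.71)

  scot <- marker_summary(reference_band_matrices("SCoT", seed = 4),
                         pic_overrides = ov)
  expect_equal(sum(scot$per_primer$tb), 138)
  expect_equal(sum(scot$per_primer$ub), 59)
  expect_equal(round(scot$overall_p_pct, 2), 75.36)

  # published per-primer EMR / P% / MI-with-published-PIC, to 2 decimals
  printed <- data.frame(
    primer = c("ISSR1", "ISSR2", "ISSR3", "ISSR4", "ISSR5", "ISSR6",
               "ISSR7", "ISSR8", "ISSR9", "ISSR10",
               "SCoT1", "SCoT2", "SCoT3", "SCoT4", "SCoT5", "SCoT6",
               "SCoT7", "SCoT8", "SCoT9", "SCoT10", "SCoT11"),
    emr = c(2.78, 1.78, 0.14, 0.25, 4.45, 1.80, 1.33, 2.29, 2.67, 7.11,
            1.00, 9.31, 2.29, 0.80, 11.25, 12.07, 19.00, 11.53, 5.33,
            4.08, 6.40),
    mi = c(1.28, 0.64, 0.01, 0.04, 2.09, 0.59, 0.79, 0.94, 1.44, 5.12,
           0.19, 6.98, 0.94, 0.23, 5.96, 8.57, 14.63, 7.61, 2.40, 1.67,
           3.46),
    p_pct = c(55.56, 44.44, 14.29, 25.00, 63.64, 60.00, 66.67, 57.14,
              66.67, 88.89, 33.33, 84.62, 57.14, 40.00, 75.00, 92.86,
              100.00, 82.35, 66.67, 58.33, 80.00))
  per <- rbind(issr$per_primer, scot$per_primer)
  per <- per[match(printed$primer, per$primer), ]
  expect_equal(round(per$emr, 2), printed$emr)
  expect_equal(round(per$mi, 2), printed$mi)
  expect_equal(round(per$p_pct, 2), printed$p_pct)

  # ISSR RP column as printed (doubled-frequency convention)
  printed_rp <- c(12.00, 13.33, 13.33, 7.33, 14.67, 8.00, 3.33, 10.00,
                  7.33, 8.67)
  expect_equal(round(per$rp[1:10], 2), printed_rp)
  # SCoT RP values reported in the text (table column is garbled)
  expect_equal(round(per$rp[per$primer == "SCoT5"], 2), 25.33)
  expect_equal(round(per$rp[per$primer == "SCoT4"], 2), 8.00)

  # MI = PIC x EMR bit-consistently across all rows
  expect_equal(per$mi, per$pic * per$emr)
})

test_that("summary totals and pooled polymorphism behave correctly", {
  mono <- band_matrix(matrix(1, 3, 5), primer_id = "M1")
  s <- marker_summary(list(mono))
  expect_equal(unname(s$totals["tb"]), 5)
  expect_equal(unname(s$totals["pb"]), 0)
  expect_equal(s$overall_p_pct, 0)

  # overall P% depends only on pooled counts, not the split across primers
  a <- matrix_from_composition(2, 2, 0, seed = 1, primer_id = "A")
  b <- matrix_from_composition(4, 0, 2, seed = 2, primer_id = "B")
  ab <- matrix_from_composition(6, 2, 2, seed = 3, primer_id = "AB")
  expect_equal(marker_summary(list(a, b))$overall_p_pct,
               marker_summary(list(ab))$overall_p_pct)

  # inconsistent accession sets rejected
  other <- band_matrix(rbind(X1 = c(1, 0), X2 = c(1, 1)), primer_id = "X")
  expect_error(marker_summary(list(a, other)), "accession set")
})
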