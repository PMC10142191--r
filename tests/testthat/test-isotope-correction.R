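test_that("shift_distribution matches direct lookups and binomial algebra", {
  expect_equal(shift_distribution("Si", window = 2), c(0.9223, 0.0467, 0.0310))
  # excluding the only carbon leaves nothing to convolve
  expect_equal(shift_distribution("C", exclude_backbone_c = 1), 1)
  # two carbons: binomial expansion in the 13C abundance
  expect_equal(shift_distribution(c(C = 2L), window = 2),
               c(0.989^2, 2 * 0.989 * 0.011, 0.011^2))
  expect_error(shift_distribution("C", window = -1), "window")
  expect_error(shift_distribution("C", exclude_backbone_c = 2), "exclude")
})

test_that("shift_distribution equals multinomial enumeration on every registry formula", {
  table <- isotope_table()
  for (frag in load_fragment_table()) {
    for (excl in unique(c(0L, frag$n_backbone))) {
      got <- shift_distribution(frag$formula, excl, table)
      want <- oracle_shift_distribution(frag$formula, excl, table)
      len <- max(length(got), length(want))
      pad <- function(v) c(v, numeric(len - length(v)))
      expect_lt(max(abs(pad(got) - pad(want))), 1e-12)
    }
  }
})

test_that("correction matrix reduces to identity and to binomial columns", {
  frag <- load_fragment_table()[["Alanine_C2C3_116"]] # n = 2
  M0 <- build_correction_matrix(frag, monoisotopic_table(),
                                correction_options(FALSE))
  expect_equal(unclass(M0), diag(3), ignore_attr = TRUE)
  # purity binomial on the fully labeled column, monoisotopic non-backbone
  p <- 0.97
  M <- build_correction_matrix(frag, monoisotopic_table(),
                               correction_options(TRUE, tracer_purity = p))
  expect_equal(unname(M[, 3]), c((1 - p)^2, 2 * p * (1 - p), p^2))
})

test_that("unlabeled column matches the enumeration oracle (glycine m/z 86)", {
  frag <- load_fragment_table()[["Glycine_C2_86"]]
  M <- build_correction_matrix(frag, opts = correction_options(FALSE))
  # column 0: natural pattern of C2H8NSi (non-backbone) truncated to M0..M1
  want <- oracle_shift_distribution(c(C = 2L, H = 8L, N = 1L, Si = 1L))
  expect_equal(unname(M[, 1]), want[1:2], tolerance = 1e-12)
  expect_equal(unname(M[1, ]), c(want[1], 0)) # lower-triangular
})

test_that("correction-matrix columns sum to 1 before truncation", {
  for (frag in load_fragment_table()) {
    for (opts in list(correction_options(FALSE), correction_options(TRUE))) {
      for (j in c(0L, frag$n_backbone)) {
        pat <- posenrich:::isotopologue_pattern(frag, j, isotope_table(), opts)
        expect_equal(sum(pat), 1, tolerance = 1e-12,
                     info = paste(frag$id, j, opts$correct_backbone))
      }
    }
  }
})

test_that("correct_areas recovers constructed CIDs and validates input", {
  frag <- load_fragment_table()[["Serine_C1C2C3_306"]]
  M <- build_correction_matrix(frag)
  raw <- as.numeric(unclass(M) %*% c(1, 0, 0, 0))
  expect_equal(unname(correct_areas(raw, M)$fractions), c(1, 0, 0, 0))
  raw2 <- as.numeric(unclass(M) %*% c(0.25, 0.5, 0.25, 0))
  expect_equal(unname(correct_areas(raw2, M)$fractions), c(0.25, 0.5, 0.25, 0),
               tolerance = 1e-6)
  expect_error(correct_areas(c(1, 2), M), "exactly 4")
  expect_error(correct_areas(numeric(4), M), "all zero")
  expect_error(correct_areas(c(-1, 1, 1, 1), M), "non-negative")
})

test_that("simulate -> correct roundtrip recovers random CIDs for every fragment", {
  set.seed(101)
  table <- isotope_table()
  for (frag in load_fragment_table()) {
    for (opts in list(correction_options(FALSE),
                      correction_options(TRUE, 0.99))) {
      n <- frag$n_backbone
      cid <- rexp(n + 1)
      cid <- cid / sum(cid)
      raw <- simulate_fragment_areas(frag, cid, table, opts)
      got <- correct_areas(raw, build_correction_matrix(frag, table, opts))
      expect_lt(max(abs(got$fractions - cid)), 1e-6)
      expect_lt(got$residual, 1e-9)
    }
  }
})

test_that("full correction pins natural abundance at 0% and full labeling at 100%", {
  opts <- correction_options(TRUE, tracer_purity = 0.99)
  for (frag in load_fragment_table()) {
    n <- frag$n_backbone
    M <- build_correction_matrix(frag, opts = opts)
    nat <- simulate_fragment_areas(frag, c(1, numeric(n)), opts = opts)
    expect_lt(abs(mean_enrichment(correct_areas(nat, M))), 1e-6)
    lab <- simulate_fragment_areas(frag, c(numeric(n), 1), opts = opts)
    expect_lt(abs(mean_enrichment(correct_areas(lab, M)) - 1), 1e-6)
  }
})

test_that("mean_enrichment is the average labeled fraction per carbon", {
  expect_equal(mean_enrichment(c(0.25, 0.5, 0.25)), 0.5)
  expect_equal(mean_enrichment(c(1, 0, 0)), 0)
  expect_equal(mean_enrichment(c(0, 0, 1)), 1)
  expect_error(mean_enrichment(c(1), n = 0), "n must be")
  expect_error(mean_enrichment(c(0.5, 0.5), n = 2), "length")
})
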