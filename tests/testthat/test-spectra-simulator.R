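test_that("fragment CID follows the labeling state", {
  frags <- load_fragment_table()
  ala23 <- frags[["Alanine_C2C3_116"]]
  expect_equal(unname(fragment_cid_from_positions(
    label_state("Alanine", p = c(0, 0.5, 0.5)), ala23)), c(0.25, 0.5, 0.25))
  gly12 <- frags[["Glycine_C1C2_276"]]
  expect_equal(unname(fragment_cid_from_positions(
    label_state("Glycine", p = c(1, 0)), gly12)), c(0, 1, 0))
  e <- 0.8
  ser23 <- frags[["Serine_C2C3_204"]]
  expect_equal(unname(fragment_cid_from_positions(
    label_state("Serine", p = c(0, e, 0)), ser23)), c(1 - e, e, 0))
  expect_error(fragment_cid_from_positions(
    label_state("Serine", p = c(0, e, 0)), gly12), "labeling state is for")
})

test_that("Poisson-binomial CID matches isotopomer enumeration", {
  set.seed(41)
  frags <- load_fragment_table()
  for (id in c("Glutamate_C2C3C4C5_246", "Malate_C2C3_189", "Serine_C1C2_218")) {
    frag <- frags[[id]]
    n <- metabolite_carbons()[[frag$metabolite]]
    p <- runif(n)
    got <- fragment_cid_from_positions(label_state(frag$metabolite, p = p), frag)
    want <- oracle_cid_enumeration(p, frag$backbone)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("explicit isotopomer distributions are marginalized correctly", {
  # PT-standard serine as an explicit uniform isotopomer distribution
  pats <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  st <- label_state("Serine", isotopomers = setNames(rep(1 / 8, 8), pats))
  frag <- load_fragment_table()[["Serine_C2C3_204"]]
  expect_equal(unname(fragment_cid_from_positions(st, frag)),
               c(0.25, 0.5, 0.25))
})

test_that("unlabeled limit reproduces the natural-abundance cluster", {
  frag <- load_fragment_table()[["Proline_C2C3C4C5_142"]]
  areas <- simulate_fragment_areas(frag, c(1, 0, 0, 0, 0), total_area = 1e6,
                                   truncate = FALSE)
  want <- 1e6 * shift_distribution(frag$formula,
                                   exclude_backbone_c = frag$n_backbone)
  len <- max(length(areas), length(want))
  pad <- function(v) c(v, numeric(len - length(v)))
  expect_equal(pad(as.numeric(areas)), pad(want), tolerance = 1e-12)
})

test_that("untruncated cluster areas are conserved (incl. contaminants), pre-noise", {
  frag <- load_fragment_table()[["Proline_C2C3C4C5_216"]]
  ct <- contaminant_spec("Proline_C2C3C4C5_216", offset = 2, intensity = 0.3,
                         formula = "C9H24NSi2")
  for (opts in list(correction_options(FALSE), correction_options(TRUE))) {
    cid <- c(0.2, 0.2, 0.2, 0.2, 0.2)
    full <- simulate_fragment_areas(frag, cid, opts = opts,
                                    contaminants = list(ct),
                                    total_area = 1e6, truncate = FALSE)
    expect_equal(sum(full), 1e6 * 1.3, tolerance = 1e-9)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_pt_standard_dataset(c("Glycine", "Serine"), n_replicates = 2,
                                    noise_cv = 0.05, seed = 99)
  b <- simulate_pt_standard_dataset(c("Glycine", "Serine"), n_replicates = 2,
                                    noise_cv = 0.05, seed = 99)
  expect_identical(lapply(a, `[[`, "areas"), lapply(b, `[[`, "areas"))
  kin1 <- simulate_labeling_kinetics(n_replicates = 2, noise_cv = 0.05, seed = 7)
  kin2 <- simulate_labeling_kinetics(n_replicates = 2, noise_cv = 0.05, seed = 7)
  expect_identical(lapply(kin1, `[[`, "areas"), lapply(kin2, `[[`, "areas"))
})

test_that("a +2 co-eluting contaminant biases proline 216 enrichment upward", {
  frag <- load_fragment_table()[["Proline_C2C3C4C5_216"]]
  cid <- dbinom(0:4, 4, 0.5) # PT truth: enrichment 0.5
  M <- build_correction_matrix(frag)
  clean <- mean_enrichment(correct_areas(
    simulate_fragment_areas(frag, cid), M))
  ct <- contaminant_spec(frag$id, offset = 2, intensity = 0.2,
                         formula = "C9H24NSi2")
  biased <- mean_enrichment(correct_areas(
    simulate_fragment_areas(frag, cid, contaminants = list(ct)), M))
  expect_equal(clean, 0.5, tolerance = 1e-9)
  # the contaminant inflates M2 and its isotopic tail: enrichment reads high
  expect_gt(biased, clean + 1e-4)
})

test_that("PT dataset yields binomial CIDs; whole-molecule Pascal row for alanine", {
  samples <- simulate_pt_standard_dataset("Alanine", n_replicates = 1,
                                          noise_cv = 0)
  s <- samples[[1]]
  # no 3-carbon alanine fragment exists; check the CID the PT design implies
  st <- pt_label_state("Alanine")
  frag <- fragment_definition("Alanine", "Alanine_2TMS", "none",
                              "C3H7NO2", 89, 1:3)
  cid <- fragment_cid_from_positions(st, frag)
  expect_equal(unname(cid * 2^3), c(1, 3, 3, 1))
  # and each simulated fragment corrects back to enrichment 0.5
  cfg <- pipeline_config(correct_backbone = FALSE, compare = FALSE)
  res <- run_pipeline(samples, cfg)
  expect_lt(max(abs(res$enrichments$mean_enrichment - 0.5)), 1e-9)
})

test_that("default kinetics scenario encodes the stated biology", {
  scen <- default_kinetics_scenario()
  get_state <- function(cond, t, met) {
    scen$state[scen$condition == cond & scen$time_h == t &
                 scen$metabolite == met][[1]]
  }
  ser_l6 <- get_state("light", 6, "Serine")
  expect_gt(ser_l6$p[2], 0)
  expect_identical(ser_l6$p[c(1, 3)], c(0, 0))
  expect_identical(get_state("dark", 6, "Serine")$p, rep(0, 3))
  expect_gt(get_state("dark", 4, "Glutamate")$p[1],
            get_state("light", 4, "Glutamate")$p[1])
  for (met in c("Glycine", "Serine", "Glutamate", "Malate")) {
    expect_identical(get_state("light", 0, met)$p,
                     rep(0, metabolite_carbons()[[met]]))
  }
})

test_that("t = 0 samples correct to zero enrichment under full correction", {
  scen <- default_kinetics_scenario()
  scen0 <- scen[scen$time_h == 0 & scen$condition == "light", ]
  samples <- simulate_labeling_kinetics(scen0, n_replicates = 1, noise_cv = 0)
  res <- run_pipeline(samples, pipeline_config(correct_backbone = TRUE,
                                               compare = FALSE))
  expect_lt(max(abs(res$enrichments$mean_enrichment)), 1e-6)
})

test_that("sample tables and ground truth serialize to TSV", {
  samples <- simulate_pt_standard_dataset("Glycine", n_replicates = 2,
                                          noise_cv = 0)
  dir <- withr::local_tempdir()
  paths <- write_sample_tables(samples, dir)
  expect_true(all(file.exists(paths)))
  truth <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                           show_col_types = FALSE)
  expect_setequal(unique(truth$p), 0.5)
})
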