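enrichments_from_positions <- function(p_by_met, registry = load_fragment_table()) {
  vapply(registry[vapply(registry, function(f)
    f$metabolite %in% names(p_by_met), logical(1))],
    function(f) fragment_mean_from_positions(p_by_met[[f$metabolite]], f),
    numeric(1))
}

test_that("fragment mean is the arithmetic mean of member positions", {
  frags <- load_fragment_table()
  expect_equal(fragment_mean_from_positions(c(0.5, 0.5, 0.5),
                                            frags[["Serine_C1C2C3_306"]]), 0.5)
  expect_equal(fragment_mean_from_positions(c(0.9, 0.6, 0.3),
                                            frags[["Serine_C2C3_204"]]), 0.45)
  expect_error(fragment_mean_from_positions(c(0.5, NA, 0.2),
                                            frags[["Serine_C2C3_204"]]),
               "missing")
})

test_that("every published combination is a symbolic identity (random positions)", {
  set.seed(11)
  registry <- load_fragment_table()
  specs <- published_combinations(registry)
  nc <- metabolite_carbons()
  for (rep in 1:20) {
    p_by_met <- lapply(nc, function(n) runif(n))
    enr <- enrichments_from_positions(p_by_met, registry)
    for (spec in specs) {
      got <- apply_combination(spec, enr)$value
      want <- mean(p_by_met[[spec$metabolite]][spec$target])
      expect_lt(abs(got - want), 1e-12)
    }
  }
})

test_that("combination construction rejects weights that are not identities", {
  expect_error(combination_spec("Glycine", 1L,
                                c(Glycine_C1C2_276 = 2, Glycine_C2_100 = -2)),
               "not a symbolic identity")
  expect_error(combination_spec("Glycine", 1L, c(Serine_C2_100 = 1)),
               "does not belong")
})

test_that("apply_combination computes weighted sums and flags out-of-range values", {
  specs <- published_combinations()
  glu <- specs[["Glutamate_C1_via_246"]]
  expect_equal(glu$weights,
               c(Glutamate_C1C2C3C4C5_348 = 5, Glutamate_C2C3C4C5_246 = -4))
  mal <- specs[["Malate_C1_via_245"]]
  expect_equal(mal$weights,
               c(Malate_C1C2C3C4_245 = 4, Malate_C2C3C4_233 = -3))
  gly <- specs[["Glycine_C1_via_100"]]
  r1 <- apply_combination(gly, c(Glycine_C1C2_276 = 0.3, Glycine_C2_100 = 0.2))
  expect_equal(r1$value, 0.4)
  expect_false(r1$out_of_range)
  r2 <- apply_combination(gly, c(Glycine_C1C2_276 = 0.1, Glycine_C2_100 = 0.3))
  expect_equal(r2$value, -0.1)
  expect_true(r2$out_of_range)
  expect_error(apply_combination(gly, c(Glycine_C1C2_276 = 0.3)), "missing")
})

test_that("serine methods A and B agree noiselessly, as do the malate C3 routes", {
  set.seed(21)
  registry <- load_fragment_table()
  specs <- published_combinations(registry)
  for (rep in 1:10) {
    p_by_met <- lapply(metabolite_carbons(), function(n) runif(n))
    enr <- enrichments_from_positions(p_by_met, registry)
    for (pos in c("C1", "C2", "C3")) {
      a <- apply_combination(specs[[paste0("Serine_", pos, "_A")]], enr)$value
      b <- apply_combination(specs[[paste0("Serine_", pos, "_B")]], enr)$value
      expect_lt(abs(a - b), 1e-12)
    }
    m1 <- apply_combination(specs[["Malate_C3_fromC2C3"]], enr)$value
    m2 <- apply_combination(specs[["Malate_C3_fromC3C4"]], enr)$value
    expect_lt(abs(m1 - m2), 1e-12)
  }
})

test_that("uniform fragment enrichments are a fixed point of every combination", {
  registry <- load_fragment_table()
  specs <- published_combinations(registry)
  for (e in c(0, 0.37, 1)) {
    enr <- setNames(rep(e, length(registry)), names(registry))
    for (spec in specs) {
      expect_equal(apply_combination(spec, enr)$value, e, tolerance = 1e-12)
    }
  }
})

test_that("generic least-squares solver recovers positions and reports identifiability", {
  # serine with C2, C1C2, C2C3: exactly determined
  enr <- c(Serine_C2_100 = 0.5, Serine_C1C2_218 = 0.5, Serine_C2C3_204 = 0.5)
  res <- solve_positions_generic(enr)
  expect_equal(res$estimate, rep(0.5, 3))
  expect_true(all(res$identifiable))
  # noiseless forward model with p = (0, 0.8, 0)
  p <- c(0, 0.8, 0)
  frags <- load_fragment_table("Serine")
  enr2 <- vapply(frags, function(f) fragment_mean_from_positions(p, f),
                 numeric(1))
  res2 <- solve_positions_generic(enr2)
  expect_lt(max(abs(res2$estimate - p)), 1e-9)
  expect_true(all(res2$identifiable))
  # single multi-carbon fragment: positions not individually identifiable
  res3 <- solve_positions_generic(c(Glutamate_C2C3C4C5_246 = 0.4))
  expect_false(any(res3$identifiable[2:5]))
  expect_equal(attr(res3, "rank"), 1L)
  # agreement with a published combination on an exactly determined subset
  set.seed(31)
  pg <- runif(5)
  reg <- load_fragment_table()
  eg <- c(Glutamate_C1C2C3C4C5_348 = mean(pg),
          Glutamate_C2C3C4C5_246 = mean(pg[2:5]))
  gen <- solve_positions_generic(eg)
  pub <- apply_combination(published_combinations(reg)[["Glutamate_C1_via_246"]], eg)
  expect_lt(abs(gen$estimate[1] - pub$value), 1e-9)
  expect_true(gen$identifiable[1])
  expect_error(solve_positions_generic(c()), "at least one")
})
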