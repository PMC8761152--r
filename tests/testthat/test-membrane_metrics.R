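test_that("mean pLDDT is the arithmetic mean over (region) residues", {
  s <- load_structure(extdata("mini.pdb"))
  expect_equal(as.numeric(mean_plddt(s)), mean(c(90, 85.5, 70)))
  expect_equal(as.numeric(mean_plddt(s, region = 1:2)), mean(c(90, 85.5)))
  expect_error(mean_plddt(s, region = 99:100), "does not intersect")

  all90 <- generate_bundle(bundle_spec(seed = 1, plddt_tm = 90,
                                       plddt_loop = 90))$structure
  expect_equal(as.numeric(mean_plddt(all90)), 90)

  ## residues without confidence are excluded and counted
  gap <- load_structure(extdata("mini_missing_ca.pdb"))
  m <- mean_plddt(gap)
  expect_equal(as.numeric(m), mean(c(90, 70)))
  expect_equal(attr(m, "n_missing"), 1L)
})

test_that("per-region means reflect the painted fixture values", {
  b <- generate_bundle(bundle_spec(seed = 2, plddt_tm = 80, plddt_loop = 60))
  ps <- plddt_summary(b$structure, b$topology)
  expect_equal(ps$mean_tm, 80)
  expect_equal(ps$mean_non_tm, 60)
  expect_true(ps$mean_non_tm < ps$mean_all && ps$mean_all < ps$mean_tm)
})

test_that("reliability bins use half-open intervals with a closed top bin", {
  fr <- plddt_bins(c(95, 95, 45, 75))
  expect_equal(unname(fr), c(0.25, 0, 0.25, 0.5))
  expect_named(fr, c("very_low", "low", "confident", "very_high"))
  expect_equal(unname(plddt_bins(90)["very_high"]), 1)   # boundary joins upper bin
  expect_equal(unname(plddt_bins(100)["very_high"]), 1)  # top edge closed
  expect_equal(sum(plddt_bins(runif(100, 0, 100))), 1)
  expect_error(plddt_bins(c(50, 101)), "outside")
  expect_error(plddt_bins(numeric()), "no values")
})

test_that("bin fractions on uniform draws match bin widths within binomial error", {
  vals <- local({
    set.seed(321)
    runif(1e4, 0, 100)
  })
  fr <- plddt_bins(vals)
  widths <- c(50, 20, 20, 10) / 100
  sigma <- sqrt(widths * (1 - widths) / 1e4)
  expect_true(all(abs(fr - widths) < 3 * sigma))
})

test_that("hydrophobic thickness recovers the constructed centroid distance", {
  b <- generate_bundle(bundle_spec(n_helices = 4, target_thickness = 30,
                                   tilt_deg = 0, noise_sigma = 0, seed = 3))
  th <- hydrophobic_thickness(b$structure, b$topology)
  expect_equal(th$thickness, 30.0)
  expect_equal(th$flag, "ok")
  expect_equal(th$n_side1, 4)
  expect_equal(th$n_side2, 4)
})

test_that("thickness is invariant under rigid transforms", {
  b <- generate_bundle(bundle_spec(seed = 4, noise_sigma = 0.3))
  t0 <- hydrophobic_thickness(b$structure, b$topology)$thickness
  for (seed in 1:20) {
    p <- perturb_structure(b$structure, seed)
    expect_equal(hydrophobic_thickness(p, b$topology)$thickness, t0,
                 tolerance = 1e-6)
  }
})

test_that("thickness equals an independent brute-force centroid computation", {
  for (seed in 1:5) {
    b <- generate_bundle(bundle_spec(n_helices = 3 + seed %% 3, radius = 10,
                                     seed = seed, noise_sigma = 0.5))
    expect_equal(hydrophobic_thickness(b$structure, b$topology)$thickness,
                 oracle_thickness(b$structure, b$topology), tolerance = 1e-12)
  }
})

test_that("an inverted helix shortens the side1-side2 distance", {
  b <- generate_bundle(bundle_spec(seed = 6))
  good <- hydrophobic_thickness(b$structure, b$topology)$thickness
  bad <- hydrophobic_thickness(make_decoy(b$structure, b$topology, "invert_helix"),
                               b$topology)$thickness
  expect_lt(bad, good)
})

test_that("confidence classes split suspects by topology reliability", {
  expect_equal(classify_confidence(30, 99), "consistent")
  expect_equal(classify_confidence(10, 99), "likely_af2_error")
  expect_equal(classify_confidence(10, 40), "twilight")
  ## band boundaries are ok-inclusive
  expect_equal(classify_confidence(15, 99), "consistent")
  expect_equal(classify_confidence(35, 99), "consistent")
  expect_equal(classify_confidence(14.999, 95), "likely_af2_error")
  expect_equal(classify_confidence(35.001, 20), "twilight")
})

test_that("flag and confidence class agree: suspect iff not consistent", {
  grid <- expand.grid(th = c(5, 14.9, 15, 25, 35, 35.1, 50),
                      rel = c(40, 89.9, 90, 99))
  for (i in seq_len(nrow(grid))) {
    flag_suspect <- grid$th[i] < 15 || grid$th[i] > 35
    cls <- classify_confidence(grid$th[i], grid$rel[i])
    expect_equal(flag_suspect, cls != "consistent",
                 info = paste(grid$th[i], grid$rel[i]))
  }
})
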