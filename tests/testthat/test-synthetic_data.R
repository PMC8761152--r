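test_that("zero-noise bundles recover the target thickness exactly", {
  for (T in c(15, 20, 25, 30, 35, 40)) {
    b <- generate_bundle(bundle_spec(helix_length = 31, target_thickness = T,
                                     seed = 1))
    expect_equal(hydrophobic_thickness(b$structure, b$topology)$thickness, T,
                 info = paste("thickness", T))
  }
  ## and with tilt, where the azimuth spread cancels the endpoint offsets
  bt <- generate_bundle(bundle_spec(helix_length = 31, target_thickness = 30,
                                    tilt_deg = 25, seed = 2))
  expect_equal(hydrophobic_thickness(bt$structure, bt$topology)$thickness, 30)
})

test_that("unachievable bundle specs are rejected", {
  expect_error(bundle_spec(helix_length = 15, target_thickness = 30),
               "unachievable")
  expect_error(bundle_spec(helix_length = 31, target_thickness = 40,
                           tilt_deg = 45), "unachievable")
})

test_that("painted confidences land on their regions", {
  b <- generate_bundle(bundle_spec(seed = 3, plddt_tm = 92, plddt_loop = 55))
  ps <- plddt_summary(b$structure, b$topology)
  expect_equal(ps$mean_tm, 92)
  expect_equal(ps$mean_non_tm, 55)
})

test_that("generation is deterministic per seed and varies across seeds", {
  a1 <- generate_bundle(bundle_spec(seed = 9, noise_sigma = 0.5))
  a2 <- generate_bundle(bundle_spec(seed = 9, noise_sigma = 0.5))
  b <- generate_bundle(bundle_spec(seed = 10, noise_sigma = 0.5))
  expect_identical(as.data.frame(a1$structure), as.data.frame(a2$structure))
  expect_false(identical(as.data.frame(a1$structure), as.data.frame(b$structure)))
})

test_that("decoy modes distort thickness as constructed", {
  b <- generate_bundle(bundle_spec(target_thickness = 30, seed = 11))
  col <- make_decoy(b$structure, b$topology, "collapse")
  tc <- hydrophobic_thickness(col, b$topology)
  expect_equal(tc$thickness, 12)
  expect_equal(tc$flag, "suspect")

  inv <- make_decoy(b$structure, b$topology, "invert_helix")
  expect_lt(hydrophobic_thickness(inv, b$topology)$thickness, 30)

  sheared0 <- make_decoy(b$structure, b$topology, "shear", shear_dz = 0)
  expect_equal(hydrophobic_thickness(sheared0, b$topology)$flag, "ok")

  expect_error(make_decoy(b$structure, b$topology, "melt"), "arg")
})

test_that("rigid perturbation is exactly removable at zero noise", {
  b <- generate_bundle(bundle_spec(seed = 12))$structure
  for (seed in c(1, 2, 3)) {
    p <- perturb_structure(b, seed)
    expect_lt(kabsch_superpose(ca_coords(p), ca_coords(b))$rmsd, 1e-6)
  }
  p1 <- perturb_structure(b, 1)
  p2 <- perturb_structure(b, 2)
  expect_false(isTRUE(all.equal(as.data.frame(p1), as.data.frame(p2))))
})

test_that("post-fit RMSD under coordinate noise matches the Monte-Carlo expectation", {
  b <- generate_bundle(bundle_spec(n_helices = 5, seed = 13))$structure  # L = 125
  sigma <- 0.5
  rmsds <- vapply(1:10, function(seed) {
    p <- perturb_structure(b, seed, noise_sigma = sigma)
    kabsch_superpose(ca_coords(p), ca_coords(b))$rmsd
  }, numeric(1))
  expect_equal(mean(rmsds), sigma * sqrt(3), tolerance = 0.2)
})

test_that("the generated-file loop closes: write, reload, recover ground truth", {
  dir <- tempfile(); dir.create(dir)
  for (seed in 1:3) {
    b <- generate_bundle(bundle_spec(seed = seed))
    pdb <- file.path(dir, paste0(attr(b$structure, "id"), ".pdb"))
    xml <- file.path(dir, paste0(attr(b$structure, "id"), ".xml"))
    write_structure(b$structure, pdb)
    write_topology_xml(b$topology, xml)
    s <- load_structure(pdb)
    ann <- parse_topology_xml(xml)[[1]]
    expect_equal(hydrophobic_thickness(s, ann)$thickness, 30, tolerance = 1e-3)
  }
})

test_that("noisy ground-truth recovery stays within the endpoint-count bound", {
  sigma <- 0.5
  errs <- vapply(1:20, function(seed) {
    b <- generate_bundle(bundle_spec(n_helices = 4, target_thickness = 30,
                                     noise_sigma = sigma, seed = seed))
    abs(hydrophobic_thickness(b$structure, b$topology)$thickness - 30)
  }, numeric(1))
  expect_lt(mean(errs), 3 * sigma / sqrt(4))
})

test_that("fabricated domain tables survive formatting round-trips", {
  hits <- data.frame(target_id = "Q1", hmm_name = "ABC_membrane",
                     hmm_length = 275L, e_value = 1e-5,
                     hmm_from = 3L, hmm_to = 270L, stringsAsFactors = FALSE)
  f <- tempfile()
  write_fixture_domtbl(hits, f)
  back <- parse_domtbl(f)
  expect_equal(back$e_value, 1e-5)
  expect_equal(back$hmm_from, 3L)
  expect_equal(back$hmm_to, 270L)
})
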