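test_that("Kabsch fit is exact on self and on rigidly moved copies", {
  x <- random_cloud(10, seed = 1)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  for (seed in 1:5) {
    rot <- local({ set.seed(seed); memqa:::random_rotation() })
    moved <- memqa:::transform_coords(x, rot, c(3, -7, 11))
    fit <- kabsch_superpose(x, moved)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(fit$rotation, rot, tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD matches the quaternion/rotation-sampling minimizer", {
  for (seed in 1:10) {
    q <- random_cloud(10, seed = seed)
    r <- q + random_cloud(10, seed = 1000 + seed) * 0.2
    fit <- kabsch_superpose(q, r)
    expect_equal(fit$rmsd, oracle_min_rmsd(q, r, n_sample = 500),
                 tolerance = 1e-3)
  }
})

test_that("degenerate inputs are rejected as underdetermined", {
  expect_error(kabsch_superpose(random_cloud(2, 1), random_cloud(2, 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("d0 follows the closed form with its small-length floor", {
  expect_equal(d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(d0(15), 0.5)
  expect_equal(d0(20), 0.5)   # raw formula below the floor here
  L <- 1:1000
  expect_true(all(diff(d0(L)) >= 0))
  expect_true(all(d0(L) >= 0.5))
})

test_that("TM-score is 1 on self and 0.5 on the all-pairs-at-d0 construction", {
  b <- generate_bundle(bundle_spec(seed = 1))$structure
  corr <- identity_correspondence(b)
  expect_equal(tm_score(b, b, corr, compute_gdt = FALSE)$tm_score, 1.0,
               tolerance = 1e-12)

  at_d0 <- balanced_offset_pair(24, delta = d0(24))
  res <- tm_score(at_d0$query, at_d0$reference,
                  identity_correspondence(at_d0$reference),
                  compute_gdt = FALSE,
                  superposition = list(rotation = diag(3),
                                       translation = c(0, 0, 0)))
  expect_equal(res$tm_score, 0.5, tolerance = 1e-9)
})

test_that("TM-score equals the exhaustive-seed oracle on small pairs", {
  base <- generate_bundle(bundle_spec(n_helices = 1, helix_length = 21,
                                      target_thickness = 30, seed = 3))$structure
  small <- new_structure(as.data.frame(base)[3:27, ], id = "frag25")
  for (seed in 1:5) {
    q <- perturb_structure(small, seed, noise_sigma = 0.7)
    corr <- identity_correspondence(small)
    prod <- tm_score(q, small, corr, compute_gdt = FALSE)
    cc <- memqa:::corr_coords(q, small, corr)
    expect_equal(prod$tm_score,
                 oracle_tm_exhaustive(cc$q, cc$r, prod$d0,
                                      prod$normalization_length),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("GDT_TS is 100 on self and 50 at a uniform 3 A offset", {
  b <- generate_bundle(bundle_spec(seed = 2))$structure
  corr <- identity_correspondence(b)
  expect_equal(gdt_ts(b, b, corr), 100)

  at3 <- balanced_offset_pair(24, delta = 3)
  expect_equal(gdt_ts(at3$query, at3$reference,
                      identity_correspondence(at3$reference),
                      superposition = list(rotation = diag(3),
                                           translation = c(0, 0, 0))),
               50)
})

test_that("TM-score and GDT_TS are invariant under rigid transforms of either input", {
  b <- generate_bundle(bundle_spec(n_helices = 2, seed = 3,
                                   noise_sigma = 0.4))$structure
  corr <- identity_correspondence(b)
  q <- perturb_structure(b, 11, noise_sigma = 0.6)
  ref <- tm_score(q, b, corr)
  for (seed in c(21, 22)) {
    q2 <- perturb_structure(q, seed)
    b2 <- perturb_structure(b, seed + 100)
    r1 <- tm_score(q2, b, corr)
    r2 <- tm_score(q, b2, corr)
    expect_equal(r1$tm_score, ref$tm_score, tolerance = 1e-9)
    expect_equal(r2$tm_score, ref$tm_score, tolerance = 1e-9)
    expect_equal(r1$gdt_ts, ref$gdt_ts, tolerance = 1e-9)
    expect_equal(r2$gdt_ts, ref$gdt_ts, tolerance = 1e-9)
  }
})

test_that("normalization choice rescales by L_ref/L_query at fixed d0", {
  b <- generate_bundle(bundle_spec(seed = 4))$structure
  frag <- new_structure(as.data.frame(b)[1:60, ], id = "frag")
  corr <- identity_correspondence(frag)
  d0fix <- d0(n_residues(b))
  r_ref <- tm_score(frag, b, corr, normalization = "reference",
                    d0_value = d0fix, compute_gdt = FALSE)
  r_qry <- tm_score(frag, b, corr, normalization = "query",
                    d0_value = d0fix, compute_gdt = FALSE)
  expect_equal(r_ref$tm_score * n_residues(b),
               r_qry$tm_score * n_residues(frag), tolerance = 1e-9)
})

test_that("structural alignment recovers identity and offset correspondences", {
  b <- generate_bundle(bundle_spec(seed = 5))$structure
  a <- structural_align(b, b)
  expect_equal(a$qpos, a$rpos)
  expect_equal(tm_score(b, b, a, compute_gdt = FALSE)$tm_score, 1.0,
               tolerance = 1e-12)

  ## 5 N-terminal residues deleted and renumbered from 1: maps i -> i + 5
  df <- as.data.frame(b)[-(1:5), ]
  df$resno <- seq_len(nrow(df))
  q <- new_structure(df, id = "del5")
  a2 <- structural_align(q, b)
  expect_true(all(a2$rpos - a2$qpos == 5))
  expect_gt(tm_score(q, b, a2, compute_gdt = FALSE)$tm_score, 0.9)
})

test_that("independently generated random coils align below the 0.3 unrelated line", {
  scores <- vapply(1:10, function(seed) {
    c1 <- generate_coil(60, seed)
    c2 <- generate_coil(60, 500 + seed)
    a <- structural_align(c1, c2)
    tm_score(c1, c2, a, compute_gdt = FALSE)$tm_score
  }, numeric(1))
  expect_true(all(scores < 0.3))
})

test_that("empty or invalid correspondences are rejected", {
  b <- generate_bundle(bundle_spec(seed = 6))$structure
  empty <- new_correspondence(integer(), integer())
  expect_error(tm_score(b, b, empty), "empty correspondence")
  expect_error(gdt_ts(b, b, empty), "empty correspondence")
  expect_error(new_correspondence(c(1, 3, 2), c(1, 2, 3)), "increasing")
  expect_error(new_correspondence(1:3, c(2, 2, 3)), "increasing")
})
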