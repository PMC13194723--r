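test_that("Kabsch superposition recovers translations and rotations", {
  set.seed(21)
  ref <- matrix(stats::rnorm(30, sd = 4), 10, 3)

  shifted <- sweep(ref, 2, c(5, -2, 7), "+")
  fit <- kabsch_superpose(shifted, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  ang <- 30 * pi / 180
  rot30 <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
                 c(0, 0, 1))
  fit2 <- kabsch_superpose(ref %*% t(rot30), ref)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit2$rotation %*% rot30, diag(3), tolerance = 1e-6)

  # mirror image of a chiral set cannot be superposed by a proper rotation
  mirror <- ref
  mirror[, 1] <- -mirror[, 1]
  expect_gt(kabsch_superpose(mirror, ref)$rmsd, 0.1)
  expect_equal(det(kabsch_superpose(mirror, ref)$rotation), 1,
               tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), ">= 3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "rank-deficient")
})

test_that("fitted RMSD is symmetric and agrees with bio3d", {
  set.seed(22)
  for (k in 1:5) {
    a <- matrix(stats::rnorm(24, sd = 3), 8, 3)
    b <- a + matrix(stats::rnorm(24, sd = 0.5), 8, 3)
    ab <- rmsd_pair(a, b)
    expect_equal(ab, rmsd_pair(b, a), tolerance = 1e-9)
    ref_rmsd <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
    expect_equal(ab, ref_rmsd, tolerance = 1e-3)  # bio3d prints 3 decimals
  }
})

test_that("pooled PCA has a valid spectrum and finds the flip mode", {
  spec <- loopflip_spec(50, 10, 8, rep(c(0, 1), 250), noise_sigma = 0.3,
                        seed = 1)
  ens <- generate_loop_flip_ensemble(spec, 2)
  dec <- pooled_pca(ens, superpose_resno = 1:50)
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(dec$eigenvalues) <= 1e-9))
  expect_true(all(dec$eigenvalues >= -1e-12))
  expect_gte(dec$variance_fraction[1], 0.8)
  gram <- t(dec$rotation) %*% dec$rotation
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("isotropic noise yields no dominant component", {
  hits <- 0L
  for (s in 1:5) {
    spec <- loopflip_spec(30, 5, 0, rep(c(0, 1), 300), noise_sigma = 0.3,
                          seed = 100 + s)
    dec <- pooled_pca(generate_loop_flip_ensemble(spec, 1),
                      superpose_resno = 1:30)
    if (dec$variance_fraction[1] <= 3 * mean(dec$variance_fraction))
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("loop-state labels match the generating schedule", {
  sched <- rep(c(0, 1), 200)
  spec <- loopflip_spec(50, 10, 8, sched, noise_sigma = 0.3, seed = 9)
  ens <- generate_loop_flip_ensemble(spec, 1)
  dec <- pooled_pca(ens, superpose_resno = 1:50)
  lab <- classify_loop_state(dec)
  acc <- max(mean((lab == "flipped_out") == (sched == 1)),
             mean((lab == "flipped_in") == (sched == 1)))
  expect_gte(acc, 0.99)

  # unimodal projections: warning and a single label
  null_spec <- loopflip_spec(30, 5, 0, rep(0, 50), noise_sigma = 0.2,
                             seed = 2)
  dec0 <- pooled_pca(generate_loop_flip_ensemble(null_spec, 1),
                     superpose_resno = 1:30)
  expect_warning(lab0 <- classify_loop_state(dec0), "unimodal")
  expect_equal(length(unique(lab0)), 1)

  # threshold at +Inf puts every frame on one side
  lab_inf <- classify_loop_state(dec, threshold = Inf)
  expect_equal(unique(as.character(lab_inf)), "flipped_in")
  expect_error(classify_loop_state(dec, component = 10000), "does not exist")
})

test_that("gromos clustering matches exhaustive brute force on small fixtures", {
  traj <- two_group_traj(c(7, 3), sep = 25, jitter = 0.05, seed = 41)
  res <- cluster_gromos(traj, cutoff = 1.0)
  expect_equal(res$sizes, c(7, 3))
  expect_equal(sum(res$sizes), 10)
  oracle <- oracle_gromos(oracle_rmsd_matrix(traj), cutoff = 1.0)
  expect_equal(res$assignments, oracle$assignments)
  expect_equal(res$representative_frame, oracle$representative_frame)

  for (s in 1:4) {
    set.seed(s)
    nf <- sample(8:12, 1)
    sizes <- c(sample(3:6, 1))
    sizes <- c(sizes, nf - sizes)
    tr <- two_group_traj(sizes, sep = sample(c(0.5, 3, 25), 1),
                         jitter = 0.3, seed = 50 + s)
    got <- cluster_gromos(tr, cutoff = 1.0)
    want <- oracle_gromos(oracle_rmsd_matrix(tr), cutoff = 1.0)
    expect_equal(got$assignments, want$assignments)
    expect_equal(got$representative_frame, want$representative_frame)
  }
})

test_that("gromos boundary cases behave deterministically", {
  # identical frames: one cluster, representative is the lowest index
  top <- make_toy_topology(5)
  one <- matrix(stats::rnorm(15), 5, 3)
  coords <- array(rep(one, 6), c(5, 3, 6))
  same <- trajectory(top, coords, times = 1)
  res <- cluster_gromos(same, cutoff = 1.0)
  expect_equal(length(res$sizes), 1)
  expect_equal(res$representative_frame, 1)

  # cutoff below all pairwise RMSDs: one cluster per frame
  spread <- two_group_traj(c(1, 1, 1, 1), sep = 10, jitter = 0, seed = 3)
  res2 <- cluster_gromos(spread, cutoff = 1e-6)
  expect_equal(res2$sizes, rep(1, 4))
})
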