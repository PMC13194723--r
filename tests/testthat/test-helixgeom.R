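test_that("local twist equals the generative rotation of a circular helix", {
  for (tau in c(100, 87, 60, 140)) {
    xyz <- build_ideal_helix(helix_spec(6, base_twist = tau))
    expect_equal(local_twist(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]), tau,
                 tolerance = 1e-9)
  }
})

test_that("local twist rejects degenerate windows and survives rigid motion", {
  p <- lapply(0:3, function(k) c(k, 0, 0))
  expect_error(local_twist(p[[1]], p[[2]], p[[3]], p[[4]]), "degenerate")

  xyz <- build_ideal_helix(helix_spec(6, base_twist = 93))
  ref <- local_twist(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  set.seed(11)
  for (k in 1:5) {
    rot <- random_rotation()
    shift <- stats::rnorm(3, sd = 20)
    m <- sweep(xyz %*% t(rot), 2, shift, "+")
    expect_equal(local_twist(m[1, ], m[2, ], m[3, ], m[4, ]), ref,
                 tolerance = 1e-9)
  }
})

test_that("twist map is flat for an ideal helix and localises a seeded event", {
  spec <- helix_spec(20, n_frames = 10, noise_sigma = 0)
  tm <- twist_map(generate_helix_trajectory(spec))
  expect_lt(max(abs(tm$delta_theta), na.rm = TRUE), 1e-6)
  # edge residues of the selection carry no value
  expect_true(all(is.na(tm$theta[c(1, 20), ])))

  spec2 <- helix_spec(30, n_frames = 300, noise_sigma = 0)
  traj <- generate_helix_trajectory(spec2, list(unwind_event(10:12, 87, 100, 249)))
  tm2 <- twist_map(traj)
  expect_equal(unname(tm2$delta_theta["11", 150]), -13, tolerance = 1e-9)
  expect_equal(unname(tm2$delta_theta["11", 50]), 0, tolerance = 1e-9)
  expect_equal(unname(tm2$delta_theta["20", 150]), 0, tolerance = 1e-9)

  # 4-residue selection: exactly one residue carries values
  tm3 <- twist_map(generate_helix_trajectory(helix_spec(8, n_frames = 2)),
                   resno = 3:6)
  expect_equal(sum(!is.na(tm3$theta[, 1])), 1)

  # alternative window-to-residue assignment shifts the carrier by one
  tm4 <- twist_map(traj, assign = "third")
  expect_equal(unname(tm4$delta_theta["12", 150]),
               unname(tm2$delta_theta["11", 150]))
})

test_that("twist map validates its selection", {
  traj <- generate_helix_trajectory(helix_spec(10, n_frames = 2))
  expect_error(twist_map(traj, resno = 3:5), ">= 4 residues")
  expect_error(twist_map(traj, resno = c(1, 2, 4, 5)), "consecutive")
  expect_error(twist_map(traj, resno = 8:11), "exactly one C-alpha")
})

test_that("integrated deviation follows the rectangle rule in deg.us", {
  # constant delta of -13 deg over 0.5 us (10000 frames at 50 ps)
  spec <- helix_spec(10, n_frames = 10000, noise_sigma = 0)
  traj <- generate_helix_trajectory(spec, list(unwind_event(1:9, 87, 1, 10000)))
  intd <- integrate_deviation(twist_map(traj))
  expect_equal(intd$value[intd$residue_ids == 5], 6.5, tolerance = 1e-9)
  expect_equal(intd$total_time, 0.5, tolerance = 1e-12)

  flat <- integrate_deviation(twist_map(generate_helix_trajectory(
    helix_spec(10, n_frames = 10))))
  expect_lt(max(flat$value, na.rm = TRUE), 1e-12)
})

test_that("a seeded 0.2 us event integrates to duration x deviation at its argmax", {
  # 4000 frames at 50 ps = 0.2 us event on an otherwise ideal helix
  spec <- helix_spec(20, n_frames = 5000, noise_sigma = 0)
  traj <- generate_helix_trajectory(spec, list(unwind_event(8:11, 87, 501, 4500)))
  intd <- integrate_deviation(twist_map(traj))
  peak <- intd$residue_ids[which.max(intd$value)]
  expect_true(peak %in% 8:12)
  expect_equal(max(intd$value, na.rm = TRUE), 13 * 0.2, tolerance = 1e-6)
})

test_that("integration is additive over disjoint intervals and linear in duration", {
  base <- function(frames) {
    spec <- helix_spec(16, n_frames = 1200, noise_sigma = 0)
    evs <- lapply(frames, function(w) unwind_event(6:9, 88, w[1], w[2]))
    intd <- integrate_deviation(twist_map(generate_helix_trajectory(spec, evs)))
    max(intd$value, na.rm = TRUE)
  }
  # two disjoint pulses equal the sum of the single pulses
  expect_equal(base(list(c(100, 299), c(600, 799))),
               base(list(c(100, 299))) + base(list(c(600, 799))),
               tolerance = 1e-9)
  # linear scaling across three durations
  v <- vapply(c(200, 400, 800), function(d) base(list(c(1, d))), numeric(1))
  expect_equal(v[2] / v[1], 2, tolerance = 1e-9)
  expect_equal(v[3] / v[1], 4, tolerance = 1e-9)
  expect_true(all(v >= 0))
})

test_that("non-uniform frame times are rejected", {
  traj <- generate_helix_trajectory(helix_spec(8, n_frames = 5))
  traj$times[4] <- traj$times[4] + 10
  expect_error(integrate_deviation(twist_map(traj)), "uniform")
})

test_that("RMSF is zero for a static trajectory and sigma*sqrt(3) under noise", {
  static <- generate_helix_trajectory(helix_spec(15, n_frames = 4))
  prof <- rmsf_profile(static)
  expect_true(all(prof$rmsf < 1e-9))

  noisy <- generate_helix_trajectory(
    helix_spec(100, n_frames = 300, noise_sigma = 0.3, seed = 7))
  prof2 <- rmsf_profile(noisy)
  expect_equal(mean(prof2$rmsf), 0.3 * sqrt(3), tolerance = 0.05)
})

test_that("a flipping loop is more mobile than its rigid core", {
  spec <- loopflip_spec(20, 5, 6, rep(c(0, 1), 50), noise_sigma = 0.3, seed = 3)
  traj <- generate_loop_flip_ensemble(spec, 1)[[1]]
  prof <- rmsf_profile(traj, superpose_resno = 1:20)
  core <- mean(prof$rmsf[prof$residue_ids <= 20])
  loop <- mean(prof$rmsf[prof$residue_ids > 20])
  expect_gt(loop, core)
})

test_that("argmax of integrated deviation recovers seeded spans at sigma 0.2", {
  ok <- 0L
  set.seed(202)
  for (k in 1:20) {
    width <- sample(3:5, 1)
    start <- sample(5:(29 - width), 1)
    tw <- stats::runif(1, 80, 90)
    dur <- round(stats::runif(1, 0.5, 0.9) * 300)
    st <- sample.int(300 - dur + 1, 1)
    spec <- helix_spec(30, n_frames = 300, noise_sigma = 0.2, seed = 500 + k)
    traj <- generate_helix_trajectory(
      spec, list(unwind_event(start:(start + width - 1), tw, st, st + dur - 1)))
    intd <- integrate_deviation(twist_map(traj))
    am <- intd$residue_ids[which.max(intd$value)]
    if (am >= start && am <= start + width - 1) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})
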