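test_that("salt bridges and pi-cation contacts obey their cutoffs", {
  fx <- binding_site_frame(ne_to_od1 = 3.5)
  traj <- trajectory(fx$top, fx$xyz, 0)
  lig <- select_atoms(traj, entity = "ligand")
  fp <- frame_fingerprint(traj, 1, lig, c(10L, 20L))
  expect_true(any(fp$resno == 10 & fp$type == "salt_bridge"))

  far <- binding_site_frame(ne_to_od1 = 6.0)
  fp2 <- frame_fingerprint(trajectory(far$top, far$xyz, 0), 1, lig,
                           c(10L, 20L))
  expect_false(any(fp2$resno == 10 & fp2$type == "salt_bridge"))

  # cationic NE 4 A above the TYR ring centroid: pi-cation present
  xyz3 <- fx$xyz
  xyz3[nrow(xyz3), ] <- fx$ring_centroid + c(0, 0, 4)
  fp3 <- frame_fingerprint(trajectory(fx$top, xyz3, 0), 1, lig, c(10L, 20L))
  expect_true(any(fp3$resno == 20 & fp3$type == "pi_cation"))
  # at 8 A: absent
  xyz4 <- fx$xyz
  xyz4[nrow(xyz4), ] <- fx$ring_centroid + c(0, 0, 8)
  fp4 <- frame_fingerprint(trajectory(fx$top, xyz4, 0), 1, lig, c(10L, 20L))
  expect_false(any(fp4$type == "pi_cation"))
})

test_that("hydrophobic contacts pair apolar carbons within the cutoff", {
  top <- data.frame(
    chain = c(rep("A", 2), rep("L", 2)),
    resno = c(30L, 30L, 1L, 1L),
    resname = c("LEU", "LEU", "LIG", "LIG"),
    name = c("CB", "CD1", "CA", "CD1"),
    element = "C",
    entity = c("protein", "protein", "ligand", "ligand"))
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(10, 0, 0), c(5.5, 0, 0))
  traj <- trajectory(top, xyz, 0)
  lig <- select_atoms(traj, entity = "ligand")
  expect_equal(nrow(frame_fingerprint(traj, 1, lig, 30L)), 1)  # CD1-CD1 4.0 A
  xyz[4, 1] <- 7
  expect_equal(nrow(frame_fingerprint(trajectory(top, xyz, 0), 1, lig, 30L)), 0)
})

test_that("fingerprints are invariant to rigid motion and atom order", {
  fx <- binding_site_frame(3.2)
  traj <- trajectory(fx$top, fx$xyz, 0)
  lig <- select_atoms(traj, entity = "ligand")
  fp_ref <- frame_fingerprint(traj, 1, lig, c(10L, 20L))

  set.seed(5)
  rot <- random_rotation()
  moved <- sweep(fx$xyz %*% t(rot), 2, c(10, -4, 2), "+")
  fp_rot <- frame_fingerprint(trajectory(fx$top, moved, 0), 1, lig,
                              c(10L, 20L))
  expect_equal(fp_ref[order(fp_ref$resno, fp_ref$type), ],
               fp_rot[order(fp_rot$resno, fp_rot$type), ], ignore_attr = TRUE)

  perm <- sample(nrow(fx$top))
  traj_p <- trajectory(fx$top[perm, ], fx$xyz[perm, ], 0)
  fp_perm <- frame_fingerprint(traj_p, 1,
                               select_atoms(traj_p, entity = "ligand"),
                               c(10L, 20L))
  expect_equal(fp_ref[order(fp_ref$resno, fp_ref$type), ],
               fp_perm[order(fp_perm$resno, fp_perm$type), ],
               ignore_attr = TRUE)
})

test_that("relaxing a threshold never removes an interaction row", {
  fx <- binding_site_frame(4.4)
  traj <- trajectory(fx$top, fx$xyz, 0)
  lig <- select_atoms(traj, entity = "ligand")
  tight <- frame_fingerprint(traj, 1, lig, c(10L, 20L))
  loose <- frame_fingerprint(traj, 1, lig, c(10L, 20L),
                             interaction_rules(hbond = hbond_criteria(4.5, 110),
                                               salt_bridge_distance = 6,
                                               pi_cation_distance = 6,
                                               hydrophobic_distance = 6))
  key <- function(x) paste(x$resno, x$type)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("replicate frequencies equal brute-force per-frame re-evaluation", {
  motif <- c(14L, 15L)
  set.seed(17)
  sched <- sample(c("engaged", "disengaged_in_site"), 10, replace = TRUE)
  traj <- generate_engagement_trajectory(engagement_spec(motif, sched),
                                         helix_spec(30))
  lig <- select_atoms(traj, entity = "ligand")
  rep1 <- fingerprint_replicate(traj, lig, motif)
  # oracle: independent frame loop and explicit counting
  counts <- list()
  for (f in 1:10) {
    fp <- frame_fingerprint(traj, f, lig, motif)
    for (r in seq_len(nrow(fp))) {
      k <- paste(fp$resno[r], fp$type[r])
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  for (r in seq_len(nrow(rep1))) {
    k <- paste(rep1$resno[r], rep1$type[r])
    expect_equal(rep1$frequency[r], counts[[k]] / 10)
  }
})

test_that("aggregation reports the two-point mean and sample deviation", {
  r1 <- data.frame(resno = 10L, type = "salt_bridge", frequency = 0.4)
  r2 <- data.frame(resno = 10L, type = "salt_bridge", frequency = 0.6)
  attr(r1, "universe") <- attr(r2, "universe") <- 10L
  agg <- aggregate_fingerprints(list(r1, r2))
  expect_equal(agg$mean, 0.5)
  expect_equal(agg$sd, sd(c(0.4, 0.6)), tolerance = 1e-12)
  expect_equal(agg$sd, 0.1414, tolerance = 1e-3)

  agg_same <- aggregate_fingerprints(list(r1, r1, r1))
  expect_equal(agg_same$sd, 0)

  r3 <- data.frame(resno = 11L, type = "salt_bridge", frequency = 0.2)
  attr(r3, "universe") <- 11L
  expect_error(aggregate_fingerprints(list(r1, r3)), "universe")
})

test_that("scheduled contacts aggregate to the expected mean and deviation", {
  motif <- 14L
  make_rep <- function(n_on) {
    sched <- c(rep("engaged", n_on), rep("escaped", 100 - n_on))
    traj <- generate_engagement_trajectory(engagement_spec(motif, sched),
                                           helix_spec(30))
    fingerprint_replicate(traj, select_atoms(traj, entity = "ligand"), motif)
  }
  reps <- lapply(c(100, 100, 97), make_rep)
  agg <- aggregate_fingerprints(reps)
  hb <- agg[agg$type == "hydrogen_bond" & agg$resno == motif, ]
  expect_equal(hb$mean, mean(c(1, 1, 0.97)), tolerance = 1e-9)
  expect_equal(hb$sd, sd(c(1, 1, 0.97)), tolerance = 1e-9)
  expect_equal(round(hb$sd, 3), 0.017)
})
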