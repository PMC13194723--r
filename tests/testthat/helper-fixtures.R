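# Shared fixture builders and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random proper rotation matrix
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# trajectory whose frames fall into tight conformational groups:
# `sizes[k]` frames near the k-th template; templates differ by an
# internal deformation (a third of the atoms displaced by `sep`
# Angstrom), which per-pair superposition cannot remove
two_group_traj <- function(sizes, sep = 20, jitter = 0.05, n_atoms = 8,
                           seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n_atoms * 3, sd = 3), n_atoms, 3)
  moved <- seq_len(max(1L, n_atoms %/% 3))
  nf <- sum(sizes)
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  f <- 0L
  for (g in seq_along(sizes)) {
    template <- base
    template[moved, 1] <- template[moved, 1] + (g - 1) * sep
    for (k in seq_len(sizes[g])) {
      f <- f + 1L
      coords[, , f] <- template +
        matrix(stats::rnorm(n_atoms * 3, sd = jitter), n_atoms, 3)
    }
  }
  trajectory(make_toy_topology(n_atoms), coords, times = 1)
}

make_toy_topology <- function(n_atoms) {
  data.frame(chain = "A", resno = seq_len(n_atoms), resname = "GLY",
             name = "CA", element = "C", entity = "protein",
             stringsAsFactors = FALSE)
}

# independent gromos oracle: exhaustive neighbour counting on a
# precomputed RMSD matrix (bio3d superposition, not the package's)
oracle_rmsd_matrix <- function(traj, atom_idx = NULL) {
  if (is.null(atom_idx)) atom_idx <- seq_len(n_atoms(traj))
  nf <- n_frames(traj)
  dm <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in seq_len(nf)) {
      if (i >= j) next
      a <- as.numeric(t(traj$coords[atom_idx, , i]))
      b <- as.numeric(t(traj$coords[atom_idx, , j]))
      d <- bio3d::rmsd(a, b, fit = TRUE)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

oracle_gromos <- function(dm, cutoff) {
  nf <- nrow(dm)
  remaining <- seq_len(nf)
  assignments <- rep(NA_integer_, nf)
  cl <- 0L
  while (length(remaining)) {
    best <- remaining[1]
    best_n <- -1L
    for (i in remaining) {                      # lowest index wins ties
      ni <- sum(dm[i, remaining] <= cutoff)
      if (ni > best_n) { best <- i; best_n <- ni }
    }
    members <- remaining[dm[best, remaining] <= cutoff]
    cl <- cl + 1L
    assignments[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(assignments, cl)
  ord <- order(-sizes, seq_len(cl))
  assignments <- match(assignments, ord)
  big <- which(assignments == 1L)
  rep_frame <- if (length(big) == 1L) big else {
    means <- vapply(big, function(i) mean(dm[i, setdiff(big, i)]), numeric(1))
    big[which.min(means)]
  }
  list(assignments = assignments, sizes = sort(tabulate(assignments, cl),
                                               decreasing = TRUE),
       representative_frame = rep_frame)
}

# ligand-engagement fixture with a random schedule that ends in a fixed
# state; returns trajectory and the expected fate label
random_fate_fixture <- function(end_label, seed, n_frames = 120,
                                motif = c(14L, 15L, 16L)) {
  set.seed(seed)
  n_end <- ceiling(0.3 * n_frames)
  sched <- c(sample(c("engaged", "disengaged_in_site"), n_frames - n_end,
                    replace = TRUE),
             rep(end_label, n_end))
  spec <- engagement_spec(motif, sched, seed = seed)
  traj <- generate_engagement_trajectory(spec, helix_spec(30))
  want <- c(engaged = "bound", disengaged_in_site = "disengaged_in_site",
            escaped = "diffused_out")[[end_label]]
  list(traj = traj, expected_fate = want, motif = motif)
}

classify_fixture_fate <- function(fx) {
  ser <- engagement_series(
    fx$traj, select_atoms(fx$traj, entity = "ligand"),
    select_atoms(fx$traj, resno = fx$motif, entity = "protein"))
  ser <- classify_binding_fate(ser, attr(fx$traj, "site_center"),
                               ligand_com_series(fx$traj))
  ser$fate
}

# minimal binding-site structure: an ASP side chain, a TYR ring and an
# ornithine-like ligand placed at controlled distances
binding_site_frame <- function(ne_to_od1 = 3.5, cation_ring_height = 4.0) {
  ring <- t(sapply(0:5, function(k)
    c(1.4 * cos(k * pi / 3), 8 + 1.4 * sin(k * pi / 3), 0)))
  top <- data.frame(
    chain = c(rep("A", 4), rep("A", 7), rep("L", 5)),
    resno = c(rep(10L, 4), rep(20L, 7), rep(1L, 5)),
    resname = c(rep("ASP", 4), rep("TYR", 7), rep("ORN", 5)),
    name = c("CB", "CG", "OD1", "OD2",
             "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH",
             "N", "CA", "CB", "CD", "NE"),
    element = c("C", "C", "O", "O", rep("C", 6), "O",
                "N", "C", "C", "C", "N"),
    entity = c(rep("protein", 11), rep("ligand", 5)),
    stringsAsFactors = FALSE)
  xyz <- rbind(
    c(-2, 1, 0), c(-1, 0.5, 0), c(0, 0, 0), c(1.5, 0.8, 0),  # ASP, OD1 at origin
    ring,                                                     # TYR ring, centroid (0,8,0)
    c(-3, 8, 0),                                              # TYR OH
    c(20, 0, 0), c(21, 0, 0), c(22, 0, 0),                    # ligand N, CA, CB (parked)
    c(23, 0, 0),                                              # CD
    c(0, 0, ne_to_od1))                                       # NE above OD1
  xyz[nrow(xyz), ] <- c(0, 0, ne_to_od1)
  list(top = top, xyz = xyz, ring_centroid = c(0, 8, 0))
}
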