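#' Geometric hydrogen-bond criteria
#'
#' Defaults (donor-acceptor <= 3.5 A, D-H...A angle >= 130 degrees) are
#' the widely used geometric thresholds of interaction-fingerprinting
#' tools; both are configurable.
#'
#' @param max_donor_acceptor_distance Angstrom (> 0).
#' @param min_dha_angle degrees, in `[0, 180]`; ignored for donors with
#'   no attached hydrogen (distance-only criterion).
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5,
                           min_dha_angle = 130) {
  if (max_donor_acceptor_distance <= 0)
    stop("hbond_criteria: distance cutoff must be > 0", call. = FALSE)
  if (min_dha_angle < 0 || min_dha_angle > 180)
    stop("hbond_criteria: angle must lie in [0, 180]", call. = FALSE)
  structure(list(max_donor_acceptor_distance = max_donor_acceptor_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' A (donor, acceptor) pair is reported when the donor-acceptor distance
#' is within the cutoff and, for donors that carry a hydrogen, the
#' D-H...A angle meets the threshold. Donors without a hydrogen (e.g.
#' water oxygens in hydrogen-free topologies) are evaluated on distance
#' alone.
#'
#' @param xyz `n x 3` coordinate matrix of the frame.
#' @param donors integer atom indices of donor heavy atoms.
#' @param acceptors integer atom indices of acceptor heavy atoms.
#' @param donor_h optional integer vector, parallel to `donors`, giving
#'   the attached hydrogen's atom index (NA = no hydrogen).
#' @param criteria an [hbond_criteria()].
#' @return data frame with columns `donor`, `acceptor`, `distance`,
#'   `angle` (NA without hydrogen); zero rows when nothing bonds.
#' @export
detect_hbonds_frame <- function(xyz, donors, acceptors, donor_h = NULL,
                                criteria = hbond_criteria()) {
  if (!length(donors)) stop("empty donor set", call. = FALSE)
  if (!length(acceptors)) stop("empty acceptor set", call. = FALSE)
  if (is.null(donor_h)) donor_h <- rep(NA_integer_, length(donors))
  stopifnot(length(donor_h) == length(donors))
  out <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    dist <- sqrt(colSums((t(xyz[acceptors, , drop = FALSE]) - xyz[d, ])^2))
    hit <- which(dist <= criteria$max_donor_acceptor_distance)
    if (!length(hit)) next
    ang <- rep(NA_real_, length(hit))
    if (!is.na(donor_h[k])) {
      h <- xyz[donor_h[k], ]
      v1 <- xyz[d, ] - h
      for (m in seq_along(hit)) {
        v2 <- xyz[acceptors[hit[m]], ] - h
        ang[m] <- acos(min(1, max(-1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }
      keep <- ang >= criteria$min_dha_angle
      hit <- hit[keep]
      ang <- ang[keep]
      if (!length(hit)) next
    }
    out[[length(out) + 1L]] <- data.frame(donor = d, acceptor = acceptors[hit],
                                          distance = dist[hit], angle = ang)
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric()))
  }
  do.call(rbind, out)
}

#' Per-frame ligand-motif engagement series
#'
#' For every frame: the number of hydrogen bonds between the ligand's
#' donor atoms and the motif's acceptor atoms, and the minimum
#' heavy-atom distance between ligand and motif. Occupancy is the
#' percentage of frames with at least one hydrogen bond.
#'
#' @param traj an `"hg_traj"`.
#' @param ligand_idx atom indices of the ligand selection.
#' @param motif_idx atom indices of the target motif selection.
#' @param criteria an [hbond_criteria()].
#' @param donors donor atom indices (default: ligand N/O heavy atoms).
#' @param donor_h hydrogens attached to `donors` (default: for each
#'   donor, the first H atom of the same residue named like `H*`, if
#'   any).
#' @param acceptors acceptor atom indices (default: motif heavy atoms).
#' @return A list of class `"engagement_series"` with `frame_times`,
#'   `hbond_count`, `min_distance`, `occupancy_percent` and `fate`
#'   (unset, see [classify_binding_fate()]).
#' @export
engagement_series <- function(traj, ligand_idx, motif_idx,
                              criteria = hbond_criteria(),
                              donors = NULL, donor_h = NULL,
                              acceptors = NULL) {
  stopifnot(inherits(traj, "hg_traj"))
  top <- traj$topology
  if (!length(ligand_idx)) stop("ligand selection resolves to zero atoms",
                                call. = FALSE)
  if (!length(motif_idx)) stop("motif selection resolves to zero atoms",
                               call. = FALSE)
  lig_heavy <- heavy_only(top, ligand_idx)
  mot_heavy <- heavy_only(top, motif_idx)
  if (is.null(donors)) donors <- lig_heavy[top$element[lig_heavy] %in% c("N", "O")]
  if (!length(donors)) donors <- lig_heavy
  if (is.null(donor_h)) {
    donor_h <- vapply(donors, function(d) {
      h <- ligand_idx[top$element[ligand_idx] == "H" &
                      top$resno[ligand_idx] == top$resno[d] &
                      top$chain[ligand_idx] == top$chain[d]]
      if (length(h)) h[1L] else NA_integer_
    }, integer(1))
  }
  if (is.null(acceptors)) acceptors <- mot_heavy
  nf <- n_frames(traj)
  hb <- integer(nf)
  mind <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    hb[f] <- nrow(detect_hbonds_frame(xyz, donors, acceptors, donor_h, criteria))
    dmat <- pair_dist(xyz[lig_heavy, , drop = FALSE],
                      xyz[mot_heavy, , drop = FALSE])
    mind[f] <- min(dmat)
  }
  structure(list(frame_times = traj$times, hbond_count = hb,
                 min_distance = mind,
                 occupancy_percent = 100 * mean(hb >= 1L), fate = NA_character_),
            class = "engagement_series")
}

## full pairwise distance matrix between two coordinate sets
pair_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' @export
print.engagement_series <- function(x, ...) {
  cat(sprintf(
    "Engagement series: %d frames, occupancy %.1f%%, min distance %.2f-%.2f A\n",
    length(x$hbond_count), x$occupancy_percent,
    min(x$min_distance), max(x$min_distance)))
  if (!is.na(x$fate)) cat("  fate:", x$fate, "\n")
  invisible(x)
}

#' Classify a replica's binding fate
#'
#' End-state taxonomy of a ligand-binding replica, judged on the
#' trailing `terminal_fraction` of frames: `"bound"` when the terminal
#' hydrogen-bond occupancy stays at or above `bound_occupancy` percent;
#' otherwise `"diffused_out"` when the ligand centre of mass has left
#' the binding site (median terminal distance from `site_center` above
#' `escape_distance`); otherwise `"disengaged_in_site"`.
#'
#' @param series an [engagement_series()].
#' @param site_center xyz of the binding-site centre.
#' @param ligand_com `n_frames x 3` matrix of the ligand centre of mass
#'   per frame (see [ligand_com_series()]).
#' @param terminal_fraction trailing fraction of frames judged (default
#'   0.2).
#' @param bound_occupancy terminal occupancy threshold, percent
#'   (default 50).
#' @param escape_distance site-escape radius, Angstrom (default 10, the
#'   binding-site shell radius).
#' @return the input series with `fate` set.
#' @export
classify_binding_fate <- function(series, site_center, ligand_com,
                                  terminal_fraction = 0.2,
                                  bound_occupancy = 50,
                                  escape_distance = 10) {
  stopifnot(inherits(series, "engagement_series"))
  nf <- length(series$hbond_count)
  ligand_com <- as.matrix(ligand_com)
  if (nrow(ligand_com) != nf)
    stop("ligand_com has ", nrow(ligand_com), " rows but series has ", nf,
         " frames", call. = FALSE)
  tail_idx <- seq.int(max(1L, nf - ceiling(terminal_fraction * nf) + 1L), nf)
  occ <- 100 * mean(series$hbond_count[tail_idx] >= 1L)
  series$fate <- if (occ >= bound_occupancy) "bound" else {
    com_d <- sqrt(rowSums(sweep(ligand_com[tail_idx, , drop = FALSE], 2,
                                site_center)^2))
    if (stats::median(com_d) > escape_distance) "diffused_out"
    else "disengaged_in_site"
  }
  series
}

#' Ligand centre of mass per frame
#'
#' Unweighted centroid of the ligand's heavy atoms in each frame.
#'
#' @param traj an `"hg_traj"`.
#' @param ligand_idx ligand atom indices (default: `entity == "ligand"`).
#' @return `n_frames x 3` matrix.
#' @export
ligand_com_series <- function(traj, ligand_idx = NULL) {
  stopifnot(inherits(traj, "hg_traj"))
  if (is.null(ligand_idx)) ligand_idx <- select_atoms(traj, entity = "ligand")
  ligand_idx <- heavy_only(traj$topology, ligand_idx)
  if (!length(ligand_idx)) stop("no ligand heavy atoms", call. = FALSE)
  t(apply(traj$coords[ligand_idx, , , drop = FALSE], 3, colMeans))
}

#' Water-bridge occupancy
#'
#' Percentage of pooled frames in which at least one water oxygen sits
#' within hydrogen-bond geometry (distance criterion) of both a ligand
#' atom and a partner atom simultaneously -- the bridging-water measure
#' for a ligand--side-chain gap. Multiple replicas are concatenated
#' ("gross simulation time").
#'
#' @param trajs an `"hg_traj"` or list of them.
#' @param ligand_atom,partner_atom single atom indices.
#' @param water_idx water oxygen atom indices (default:
#'   `entity == "water"` oxygens); must be non-empty.
#' @param criteria an [hbond_criteria()]; only the distance cutoff is
#'   used (hydrogen-free water model).
#' @return occupancy percent over all pooled frames.
#' @export
water_bridge_occupancy <- function(trajs, ligand_atom, partner_atom,
                                   water_idx = NULL,
                                   criteria = hbond_criteria()) {
  if (inherits(trajs, "hg_traj")) trajs <- list(trajs)
  cut <- criteria$max_donor_acceptor_distance
  total <- 0L
  bridged <- 0L
  for (tr in trajs) {
    wi <- if (is.null(water_idx)) {
      w <- select_atoms(tr, entity = "water")
      w[tr$topology$element[w] == "O"]
    } else water_idx
    if (!length(wi)) stop("no water particles in topology", call. = FALSE)
    for (f in seq_len(n_frames(tr))) {
      xyz <- tr$coords[, , f, drop = TRUE]
      dl <- sqrt(colSums((t(xyz[wi, , drop = FALSE]) - xyz[ligand_atom, ])^2))
      dp <- sqrt(colSums((t(xyz[wi, , drop = FALSE]) - xyz[partner_atom, ])^2))
      bridged <- bridged + any(dl <= cut & dp <= cut)
      total <- total + 1L
    }
  }
  100 * bridged / total
}
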