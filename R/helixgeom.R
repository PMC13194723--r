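#' Local helical twist from a sliding 4-C-alpha window
#'
#' HELANAL-style local twist: for consecutive C-alpha positions p1..p4,
#' the angle between the two angle-bisector vectors
#' `b2 = (p1 - p2) + (p3 - p2)` and `b3 = (p2 - p3) + (p4 - p3)`,
#' in degrees. On an exact circular helix the bisectors are radial, so
#' the angle equals the per-residue rotation (100 degrees for an ideal
#' alpha-helix). The quantity depends only on inter-point geometry and is
#' invariant to rigid motions.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors of four consecutive C-alphas.
#' @param tol degeneracy tolerance on the bisector norms, Angstrom;
#'   collinear or coincident points give bisectors below it.
#' @return twist angle in degrees, in `[0, 180]`.
#' @export
local_twist <- function(p1, p2, p3, p4, tol = 1e-6) {
  b2 <- (p1 - p2) + (p3 - p2)
  b3 <- (p2 - p3) + (p4 - p3)
  n2 <- sqrt(sum(b2^2))
  n3 <- sqrt(sum(b3^2))
  if (n2 < tol || n3 < tol) {
    stop("degenerate 4-point window: bisector norm below ", tol,
         " A (collinear or coincident points)", call. = FALSE)
  }
  cosang <- sum(b2 * b3) / (n2 * n3)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Residues-by-frames local twist and deviation map
#'
#' Slides the 4-C-alpha window along a helix selection in every frame.
#' The angle from window `(i, i+1, i+2, i+3)` is assigned to residue
#' `i+1` by default (`assign = "second"`; set `"third"` for `i+2`), so
#' the first and last residues of the selection carry no value. The
#' deviation `delta_theta = theta - reference` is wrapped to
#' `(-180, 180]`.
#'
#' @param traj an [trajectory()].
#' @param resno residue numbers of the helix selection (>= 4 consecutive
#'   residues with one C-alpha each in every frame).
#' @param reference reference twist in degrees (ideal alpha-helix: 100).
#' @param assign which window residue carries the angle, `"second"` or
#'   `"third"`.
#' @param ca_name atom name of the C-alpha record in the topology.
#' @return A list of class `"twist_map"` with `residue_ids`,
#'   `frame_times` (ps), matrices `theta` and `delta_theta`
#'   (residues x frames, degrees; NA at the unassigned edge residues)
#'   and `reference_twist`.
#' @export
twist_map <- function(traj, resno = NULL, reference = 100,
                      assign = c("second", "third"), ca_name = "CA") {
  stopifnot(inherits(traj, "hg_traj"))
  assign <- match.arg(assign)
  top <- traj$topology
  if (is.null(resno)) {
    resno <- sort(unique(top$resno[top$entity == "protein" & top$name == ca_name]))
  }
  resno <- sort(as.integer(resno))
  if (length(resno) < 4) stop("selection needs >= 4 residues", call. = FALSE)
  if (!all(diff(resno) == 1L))
    stop("selection residues must be consecutive", call. = FALSE)
  idx <- vapply(resno, function(r) {
    hit <- which(top$resno == r & top$name == ca_name & top$entity == "protein")
    if (length(hit) != 1L)
      stop("residue ", r, ": expected exactly one C-alpha, found ",
           length(hit), call. = FALSE)
    hit
  }, integer(1))
  nf <- n_frames(traj)
  nr <- length(resno)
  off <- if (assign == "second") 1L else 2L
  theta <- matrix(NA_real_, nr, nf, dimnames = list(resno, NULL))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[idx, , f, drop = FALSE]
    if (any(!is.finite(xyz)))
      stop("missing C-alpha coordinates in frame ", f, call. = FALSE)
    for (i in seq_len(nr - 3L)) {
      theta[i + off, f] <- local_twist(xyz[i, , 1], xyz[i + 1, , 1],
                                       xyz[i + 2, , 1], xyz[i + 3, , 1])
    }
  }
  delta <- wrap_angle(theta - reference)
  structure(list(residue_ids = resno, frame_times = traj$times,
                 theta = theta, delta_theta = delta,
                 reference_twist = reference),
            class = "twist_map")
}

## wrap degrees into (-180, 180]
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' @export
print.twist_map <- function(x, ...) {
  cat("Twist map:", length(x$residue_ids), "residues x",
      ncol(x$theta), "frames; reference", x$reference_twist, "deg\n")
  dev <- abs(x$delta_theta)
  cat(sprintf("  mean |delta theta| %.2f deg, max %.2f deg\n",
              mean(dev, na.rm = TRUE), max(dev, na.rm = TRUE)))
  invisible(x)
}

#' Time-integrated twist deviation per residue
#'
#' Per residue, the rectangle-rule integral `sum |delta_theta| * dt`
#' over the trajectory, reported in degree-microseconds -- the summary
#' that localises and quantifies helix unwinding along the chain. Frame
#' times must be uniformly spaced.
#'
#' @param map a [twist_map()].
#' @param tol relative tolerance on frame-spacing uniformity.
#' @return A list of class `"integrated_deviation"` with `residue_ids`,
#'   `value` (deg us, NA-free residues only carry numbers) and
#'   `total_time` (us).
#' @export
integrate_deviation <- function(map, tol = 1e-6) {
  stopifnot(inherits(map, "twist_map"))
  tt <- map$frame_times
  if (length(tt) < 2) stop("need at least 2 frames to integrate", call. = FALSE)
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > tol * max(abs(dt[1]), 1))
    stop("frame times not uniformly spaced (tolerance ", tol, ")", call. = FALSE)
  dt_us <- dt[1] * 1e-6                     # ps -> us
  value <- rowSums(abs(map$delta_theta), na.rm = TRUE) * dt_us
  value[rowSums(!is.na(map$delta_theta)) == 0] <- NA  # unassigned edge residues
  structure(list(residue_ids = map$residue_ids, value = unname(value),
                 total_time = length(tt) * dt_us),
            class = "integrated_deviation")
}

#' @export
print.integrated_deviation <- function(x, ...) {
  ok <- !is.na(x$value)
  peak <- which.max(ifelse(ok, x$value, -Inf))
  cat(sprintf(
    "Integrated |delta theta| over %.4g us: peak %.3g deg.us at residue %d\n",
    x$total_time, x$value[peak], x$residue_ids[peak]))
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' Least-squares superposes every frame on `superpose_resno` (C-alpha
#' selection) against the mean structure, iterating the mean once, then
#' reports per-atom RMS deviation from the mean averaged within each
#' residue of `resno`. For isotropic Gaussian coordinate noise of s.d.
#' sigma the expected RMSF is `sigma * sqrt(3)`.
#'
#' @param traj an [trajectory()].
#' @param resno residues to report (default: all protein residues).
#' @param superpose_resno residues used for the fit (default: `resno`).
#' @param ca_name C-alpha atom name.
#' @return A list of class `"rmsf_profile"` with `residue_ids`, `rmsf`
#'   (Angstrom) and `superposition_selection`.
#' @export
rmsf_profile <- function(traj, resno = NULL, superpose_resno = NULL,
                         ca_name = "CA") {
  stopifnot(inherits(traj, "hg_traj"))
  if (n_frames(traj) < 2) stop("need >= 2 frames for RMSF", call. = FALSE)
  top <- traj$topology
  if (is.null(resno))
    resno <- sort(unique(top$resno[top$entity == "protein" & top$name == ca_name]))
  if (is.null(superpose_resno)) superpose_resno <- resno
  fit_idx <- select_atoms(traj, resno = superpose_resno, name = ca_name,
                          entity = "protein")
  if (!length(fit_idx)) stop("empty superposition selection", call. = FALSE)
  rep_idx <- select_atoms(traj, resno = resno, name = ca_name,
                          entity = "protein")
  if (!length(rep_idx)) stop("empty analysis selection", call. = FALSE)

  fitted <- superpose_frames(traj, fit_idx)
  nf <- n_frames(traj)
  mean_xyz <- apply(fitted, c(1, 2), mean)
  dev2 <- matrix(0, length(rep_idx), nf)
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((fitted[rep_idx, , f] - mean_xyz[rep_idx, ])^2)
  atom_rmsf <- sqrt(rowMeans(dev2))
  res_of <- top$resno[rep_idx]
  rmsf <- vapply(resno, function(r) mean(atom_rmsf[res_of == r]), numeric(1))
  structure(list(residue_ids = as.integer(resno), rmsf = rmsf,
                 superposition_selection = superpose_resno),
            class = "rmsf_profile")
}

## superpose all frames of traj onto the mean structure using atom
## indices fit_idx; returns the fitted coordinate array. Two passes:
## fit to frame 1, recompute mean, fit to mean.
superpose_frames <- function(traj, fit_idx) {
  coords <- traj$coords
  nf <- dim(coords)[3]
  ref <- coords[fit_idx, , 1, drop = TRUE]
  out <- coords
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      sp <- kabsch_superpose(out[fit_idx, , f, drop = TRUE], ref)
      out[, , f] <- apply_fit(out[, , f], sp)
    }
    ref <- apply(out[fit_idx, , , drop = FALSE], c(1, 2), mean)
  }
  out
}
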