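#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` in the least-squares sense, via SVD of the covariance of
#' the centred point sets with the usual determinant correction, so
#' reflections are never returned. The fitted coordinates are
#' `mobile %*% t(rotation) + translation` (rowwise).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom, after the fit, using the same weights).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference),
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3) stop("need >= 3 points to superpose", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("rank-deficient configuration: points are collinear or coincident",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- sweep(mobile %*% t(rot), 2, trans, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd)
}

## apply a kabsch fit to an n x 3 matrix
apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Pairwise C-alpha RMSD with optimal superposition
#'
#' @param a,b `n x 3` coordinate matrices.
#' @param fit superpose before measuring (default TRUE); FALSE gives the
#'   no-fit RMSD in the current frame of reference.
#' @return RMSD in Angstrom.
#' @export
rmsd_pair <- function(a, b, fit = TRUE) {
  if (fit) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Pooled-trajectory principal component analysis
#'
#' Concatenates the frames of one or more replicas, superposes every
#' frame on `superpose_resno` (two-pass fit to the pooled mean), and
#' eigendecomposes the covariance of the flattened C-alpha coordinates
#' of `resno` about the pooled mean. Variance fractions are
#' eigenvalue / trace and sum to one.
#'
#' @param trajs an `"hg_traj"` or a list of them (shared topology).
#' @param resno residues analysed (default: all protein C-alphas).
#' @param superpose_resno residues used for the fit (default: `resno`).
#' @param ca_name C-alpha atom name.
#' @return A list of class `"ensemble_pca"` with `eigenvalues`
#'   (descending), `variance_fraction`, `projections`
#'   (frames x components), `mean_structure`, `selection`, and
#'   `replica` (per-frame replica index).
#' @export
pooled_pca <- function(trajs, resno = NULL, superpose_resno = NULL,
                       ca_name = "CA") {
  if (inherits(trajs, "hg_traj")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, all(vapply(trajs, inherits, TRUE, "hg_traj")))
  top <- trajs[[1]]$topology
  if (is.null(resno))
    resno <- sort(unique(top$resno[top$entity == "protein" & top$name == ca_name]))
  if (is.null(superpose_resno)) superpose_resno <- resno
  sel <- select_atoms(top, resno = resno, name = ca_name, entity = "protein")
  fit_sel <- select_atoms(top, resno = superpose_resno, name = ca_name,
                          entity = "protein")
  if (!length(sel) || !length(fit_sel)) stop("empty selection", call. = FALSE)

  frames <- do.call(rbind, lapply(trajs, function(tr) {
    nf <- n_frames(tr)
    t(vapply(seq_len(nf),
             function(f) as.numeric(tr$coords[union(fit_sel, sel), , f]),
             numeric(length(union(fit_sel, sel)) * 3L)))
  }))
  n_pool <- nrow(frames)
  if (n_pool < 2) stop("pooled PCA needs >= 2 frames", call. = FALSE)
  replica <- rep(seq_along(trajs), vapply(trajs, n_frames, integer(1)))

  all_idx <- union(fit_sel, sel)
  fit_pos <- match(fit_sel, all_idx)
  sel_pos <- match(sel, all_idx)
  na3 <- length(all_idx)
  unflat <- function(v) matrix(v, na3, 3L)
  ## two-pass superposition on the pooled mean
  ref <- unflat(frames[1, ])[fit_pos, , drop = FALSE]
  for (pass in 1:2) {
    for (f in seq_len(n_pool)) {
      xyz <- unflat(frames[f, ])
      sp <- kabsch_superpose(xyz[fit_pos, , drop = FALSE], ref)
      frames[f, ] <- as.numeric(apply_fit(xyz, sp))
    }
    ref <- unflat(colMeans(frames))[fit_pos, , drop = FALSE]
  }

  sel_cols <- as.numeric(outer(sel_pos, (0:2) * na3, `+`))
  x <- frames[, sel_cols, drop = FALSE]
  mu <- colMeans(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, variance_fraction = ev / sum(ev),
                 projections = pc$x, mean_structure = matrix(mu, length(sel), 3L),
                 selection = resno, replica = replica,
                 rotation = pc$rotation),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  cat("Pooled PCA:", nrow(x$projections), "frames,",
      length(x$eigenvalues), "components\n")
  k <- min(3, length(x$variance_fraction))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Two-state loop classification from a principal component
#'
#' Labels each frame `"flipped_out"` or `"flipped_in"` by which side of
#' a threshold its projection on the chosen component falls. The default
#' threshold is the midpoint between the two largest modes of the
#' projection density; if the density is unimodal a warning is emitted
#' and all frames receive one label.
#'
#' @param decomposition an [pooled_pca()] result.
#' @param component component index (default 1).
#' @param threshold projection threshold; NULL = automatic.
#' @return character vector of per-frame labels, with the threshold as
#'   attribute `"threshold"` (NA when unimodal).
#' @export
classify_loop_state <- function(decomposition, component = 1L,
                                threshold = NULL) {
  stopifnot(inherits(decomposition, "ensemble_pca"))
  if (component < 1 || component > ncol(decomposition$projections))
    stop("component ", component, " does not exist", call. = FALSE)
  proj <- decomposition$projections[, component]
  if (is.null(threshold)) {
    modes <- density_modes(proj)
    if (length(modes) < 2) {
      warning("projection density is unimodal; labelling all frames as one state")
      lab <- rep("flipped_in", length(proj))
      attr(lab, "threshold") <- NA_real_
      return(lab)
    }
    threshold <- mean(modes[1:2])
  }
  lab <- ifelse(proj > threshold, "flipped_out", "flipped_in")
  attr(lab, "threshold") <- threshold
  lab
}

## locations of the two dominant modes of the kernel density, ordered by
## location; a single location is returned when the density is
## effectively unimodal (no clear dip between the two tallest maxima)
density_modes <- function(x) {
  d <- stats::density(x)
  y <- d$y
  ismax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(ismax) < 2) return(d$x[which.max(y)])
  ismax <- ismax[order(y[ismax], decreasing = TRUE)][1:2]
  m1 <- max(y[ismax])
  m2 <- min(y[ismax])
  between <- seq(min(ismax), max(ismax))
  dip <- min(y[between])
  ## modes count as separate only when the second is substantial and the
  ## density drops well below it in between
  if (m2 < 0.1 * m1 || dip > 0.5 * m2) return(d$x[which.max(y)])
  sort(d$x[ismax])
}

#' Gromos-style RMSD clustering of trajectory frames
#'
#' Greedy neighbour clustering: repeatedly take the unassigned frame
#' with the most unassigned neighbours within `cutoff` (pairwise RMSD
#' after per-pair superposition on the selection by default), make it a
#' cluster centre, assign and remove its neighbourhood. Ties in
#' neighbour counts break towards the lowest frame index. The
#' representative of the largest cluster is its median member: the frame
#' with minimal mean RMSD to the other members (again lowest index on
#' ties).
#'
#' @param traj an `"hg_traj"`.
#' @param atom_idx atom indices defining the clustered selection
#'   (default: all heavy atoms).
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @param fit per-pair Kabsch superposition before each RMSD (default
#'   TRUE); FALSE uses no-fit RMSD.
#' @return A list of class `"gromos_clust"`: `assignments` (per-frame
#'   cluster id, 1 = most populated), `sizes`, `representative_frame`,
#'   `cutoff`, `rmsd_matrix`.
#' @export
cluster_gromos <- function(traj, atom_idx = NULL, cutoff = 1.0, fit = TRUE) {
  stopifnot(inherits(traj, "hg_traj"))
  if (is.null(atom_idx))
    atom_idx <- heavy_only(traj$topology, seq_len(n_atoms(traj)))
  nf <- n_frames(traj)
  dm <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      a <- traj$coords[atom_idx, , i, drop = TRUE]
      for (j in (i + 1):nf) {
        d <- rmsd_pair(a, traj$coords[atom_idx, , j, drop = TRUE], fit = fit)
        dm[i, j] <- dm[j, i] <- d
      }
    }
  }
  if (any(!is.finite(dm))) stop("non-finite pairwise RMSD", call. = FALSE)

  assignments <- rep(NA_integer_, nf)
  centres <- integer()
  cl <- 0L
  remaining <- seq_len(nf)
  while (length(remaining)) {
    counts <- vapply(remaining,
                     function(i) sum(dm[i, remaining] <= cutoff), integer(1))
    centre <- remaining[which.max(counts)]       # which.max: lowest index on ties
    members <- remaining[dm[centre, remaining] <= cutoff]
    cl <- cl + 1L
    assignments[members] <- cl
    centres[cl] <- centre
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(assignments, nbins = cl)
  ## relabel clusters by decreasing size (stable: earlier centre wins ties)
  ord <- order(-sizes, seq_len(cl))
  relabel <- match(seq_len(cl), ord)
  assignments <- relabel[assignments]
  sizes <- sizes[ord]
  centres <- centres[ord]

  big <- which(assignments == 1L)
  rep_frame <- if (length(big) == 1L) big else {
    mean_rmsd <- vapply(big, function(i) mean(dm[i, setdiff(big, i)]), numeric(1))
    big[which.min(mean_rmsd)]
  }
  structure(list(assignments = assignments, sizes = sizes,
                 centres = centres, representative_frame = rep_frame,
                 cutoff = cutoff, rmsd_matrix = dm),
            class = "gromos_clust")
}

#' @export
print.gromos_clust <- function(x, ...) {
  cat("Gromos clustering at", x$cutoff, "A:", length(x$sizes),
      "cluster(s), sizes", paste(x$sizes, collapse = " "), "\n")
  cat("  representative frame of largest cluster:", x$representative_frame, "\n")
  invisible(x)
}
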