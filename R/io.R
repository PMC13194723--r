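#' Write a trajectory in the plain text fallback format
#'
#' Self-contained whitespace-separated format: comment header with
#' counts and frame spacing, one `@atom chain resno resname name element
#' entity` line per atom, then per frame a `@frame i` line followed by
#' one `x y z` line per atom (full precision). Round-trips coordinates
#' bit-identically through [read_trajectory()].
#'
#' @param traj an `"hg_traj"`.
#' @param path output file path.
#' @export
write_trajectory_txt <- function(traj, path) {
  stopifnot(inherits(traj, "hg_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  dt <- if (n_frames(traj) > 1) diff(traj$times)[1] else 0
  writeLines(c("# helixgate trajectory v1",
               sprintf("# n_atoms %d n_frames %d frame_spacing %.17g",
                       n_atoms(traj), n_frames(traj), dt)), con)
  writeLines(sprintf("@atom %s %d %s %s %s %s", top$chain, top$resno,
                     top$resname, top$name, top$element, top$entity), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("@frame %d", f), con)
    writeLines(sprintf("%.17g %.17g %.17g", traj$coords[, 1, f],
                       traj$coords[, 2, f], traj$coords[, 3, f]), con)
  }
  invisible(path)
}

read_trajectory_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# n_atoms", lines, value = TRUE)
  if (!length(hdr)) stop("not a helixgate trajectory file: ", path,
                         call. = FALSE)
  v <- as.numeric(strsplit(hdr, "\\s+")[[1]][c(3, 5, 7)])
  n_at <- as.integer(v[1]); nf <- as.integer(v[2]); dt <- v[3]
  at_lines <- grep("^@atom ", lines, value = TRUE)
  if (length(at_lines) != n_at)
    stop("header states ", n_at, " atoms but file has ", length(at_lines),
         call. = FALSE)
  parts <- do.call(rbind, strsplit(sub("^@atom ", "", at_lines), " "))
  top <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    resname = parts[, 3], name = parts[, 4],
                    element = parts[, 5], entity = parts[, 6],
                    stringsAsFactors = FALSE)
  fr_at <- grep("^@frame ", lines)
  if (length(fr_at) != nf) stop("header states ", nf, " frames but file has ",
                                length(fr_at), call. = FALSE)
  coords <- array(NA_real_, c(n_at, 3L, nf))
  for (f in seq_len(nf)) {
    block <- lines[(fr_at[f] + 1L):(fr_at[f] + n_at)]
    m <- matrix(as.numeric(unlist(strsplit(block, " "))), ncol = 3,
                byrow = TRUE)
    coords[, , f] <- m
  }
  trajectory(top, coords, times = if (nf > 1) dt else 0)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; frame spacing is recorded in a
#' REMARK so the file self-describes its time base (coordinates are
#' written at PDB precision, 0.001 A).
#'
#' @param traj an `"hg_traj"`.
#' @param path output file path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "hg_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  dt <- if (n_frames(traj) > 1) diff(traj$times)[1] else 0
  writeLines(sprintf("REMARK 250 FRAME SPACING %.6f PS", dt), con)
  rec <- ifelse(top$entity == "protein", "ATOM  ", "HETATM")
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "%s%5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      rec, seq_len(n_atoms(traj)),
      formatC(top$name, width = 4), formatC(top$resname, width = 4),
      substr(top$chain, 1, 1), top$resno,
      traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f],
      formatC(top$element, width = 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory
#'
#' Dispatches on file extension: multi-model PDB (`.pdb`, via bio3d),
#' DCD (`.dcd`, via bio3d, requires `topology_path` pointing to a PDB
#' with matching atoms) or the plain text fallback (anything else,
#' self-contained). Frame times are taken from the file where recorded,
#' otherwise from `frame_spacing`.
#'
#' @param coord_path coordinate file.
#' @param topology_path PDB topology for DCD input.
#' @param frame_spacing frame spacing in ps when the file does not
#'   record one.
#' @return an `"hg_traj"`.
#' @export
read_trajectory <- function(coord_path, topology_path = NULL,
                            frame_spacing = NULL) {
  if (!file.exists(coord_path)) stop("file not found: ", coord_path,
                                     call. = FALSE)
  ext <- tolower(tools::file_ext(coord_path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(coord_path, multi = TRUE)
    at <- pdb$atom
    water <- at$resid %in% c("HOH", "WAT", "TIP", "SOL")
    entity <- ifelse(at$type == "ATOM" & !water, "protein",
                     ifelse(water, "water", "ligand"))
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem) | elem == ""))
      elem <- substr(trimws(at$elety), 1, 1)
    top <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      resname = at$resid, name = at$elety,
                      element = trimws(elem), entity = entity,
                      stringsAsFactors = FALSE)
    nf <- nrow(pdb$xyz)
    coords <- array(NA_real_, c(nrow(top), 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    dt <- frame_spacing
    hdr <- grep("FRAME SPACING", readLines(coord_path, n = 5), value = TRUE)
    if (length(hdr)) dt <- as.numeric(strsplit(trimws(hdr), "\\s+")[[1]][5])
    if (is.null(dt)) dt <- 1
    return(trajectory(top, coords, times = if (nf > 1) dt else 0))
  }
  if (ext == "dcd") {
    if (is.null(topology_path))
      stop("DCD input needs topology_path (a PDB file)", call. = FALSE)
    ref <- read_trajectory(topology_path)
    xyz <- bio3d::read.dcd(coord_path, verbose = FALSE)
    if (ncol(xyz) != 3L * n_atoms(ref))
      stop("DCD has ", ncol(xyz) / 3, " atoms but topology has ",
           n_atoms(ref), call. = FALSE)
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(n_atoms(ref), 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    dt <- if (is.null(frame_spacing)) 1 else frame_spacing
    return(trajectory(ref$topology, coords, times = if (nf > 1) dt else 0))
  }
  read_trajectory_txt(coord_path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

## ---- TSV writers ----------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export analysis results as TSV
#'
#' Writers for the tabular outputs of each analysis stage (long-format
#' twist map; per-residue integrated deviation; RMSF profile; per-frame
#' engagement series plus one-line fate summary; PCA spectrum and
#' projections; cluster assignments).
#'
#' @param x analysis result object.
#' @param path output file path (for [write_engagement_tsv()] and
#'   [write_pca_tsv()], a base path without extension that gains
#'   suffixed files).
#' @return the written path(s), invisibly.
#' @export
write_twist_map_tsv <- function(x, path) {
  stopifnot(inherits(x, "twist_map"))
  long <- data.frame(
    resno = rep(x$residue_ids, times = ncol(x$theta)),
    time_ps = rep(x$frame_times, each = length(x$residue_ids)),
    theta = as.numeric(x$theta), delta_theta = as.numeric(x$delta_theta))
  invisible(write_tsv(long, path))
}

#' @rdname write_twist_map_tsv
#' @export
write_integrated_deviation_tsv <- function(x, path) {
  stopifnot(inherits(x, "integrated_deviation"))
  invisible(write_tsv(data.frame(resno = x$residue_ids,
                                 integral_deg_us = x$value), path))
}

#' @rdname write_twist_map_tsv
#' @export
write_rmsf_tsv <- function(x, path) {
  stopifnot(inherits(x, "rmsf_profile"))
  invisible(write_tsv(data.frame(resno = x$residue_ids, rmsf = x$rmsf), path))
}

#' @rdname write_twist_map_tsv
#' @export
write_engagement_tsv <- function(x, path) {
  stopifnot(inherits(x, "engagement_series"))
  p1 <- write_tsv(data.frame(time_ps = x$frame_times,
                             hbond_count = x$hbond_count,
                             min_distance = x$min_distance),
                  paste0(path, "_series.tsv"))
  p2 <- write_tsv(data.frame(occupancy_percent = x$occupancy_percent,
                             fate = x$fate), paste0(path, "_fate.tsv"))
  invisible(c(p1, p2))
}

#' @rdname write_twist_map_tsv
#' @export
write_pca_tsv <- function(x, path) {
  stopifnot(inherits(x, "ensemble_pca"))
  p1 <- write_tsv(data.frame(component = seq_along(x$eigenvalues),
                             eigenvalue = x$eigenvalues,
                             variance_fraction = x$variance_fraction),
                  paste0(path, "_spectrum.tsv"))
  k <- min(5L, ncol(x$projections))
  proj <- data.frame(frame = seq_len(nrow(x$projections)),
                     replica = x$replica, x$projections[, seq_len(k)])
  p2 <- write_tsv(proj, paste0(path, "_projections.tsv"))
  invisible(c(p1, p2))
}

#' @rdname write_twist_map_tsv
#' @export
write_cluster_tsv <- function(x, path) {
  stopifnot(inherits(x, "gromos_clust"))
  invisible(write_tsv(data.frame(frame = seq_along(x$assignments),
                                 cluster = x$assignments), path))
}

#' Write and read ground-truth schedules as TSV
#'
#' Generator ground truth (step-twist matrices, state labels,
#' engagement schedules) round-trips losslessly through these.
#'
#' @param x matrix or vector ground truth.
#' @param path file path.
#' @export
write_ground_truth_tsv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(as.character(x), path)
  }
  invisible(path)
}

#' @rdname write_ground_truth_tsv
#' @param mode `"matrix"`, `"numeric"` or `"character"`.
#' @export
read_ground_truth_tsv <- function(path, mode = c("matrix", "numeric",
                                                 "character")) {
  mode <- match.arg(mode)
  if (mode == "matrix")
    return(as.matrix(utils::read.table(path, sep = "\t")))
  x <- readLines(path)
  if (mode == "numeric") as.numeric(x) else x
}

## ---- pipeline -------------------------------------------------------------

pipeline_defaults <- function() {
  list(seed = 1L,
       generator = list(kind = "engagement", n_residues = 30L,
                        n_frames = 200L, noise_sigma = 0.05,
                        motif_residues = c(14L, 15L, 16L)),
       twist = list(reference = 100),
       pca = list(),
       cluster = list(cutoff = 1.0, max_frames = 50L))
}

merge_config <- function(defaults, user, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, "$", k))
    else user[[k]]
  }
  defaults
}

#' Run the demonstration analysis pipeline
#'
#' Generates a seeded synthetic ligand-engagement trajectory, runs the
#' full analysis sequence -- twist map, time-integrated deviation, RMSF,
#' engagement series with binding-fate call, pooled PCA and gromos
#' clustering -- and writes every stage's TSV outputs plus a JSON
#' manifest (resolved configuration, seed, package version, config hash
#' and output list) into `out_dir`. Reruns with the same configuration
#' produce identical outputs.
#'
#' @param config named list overriding the defaults (unknown keys are
#'   rejected before any stage runs): `seed`, `generator` (`kind`
#'   currently `"engagement"`; `n_residues`, `n_frames`, `noise_sigma`,
#'   `motif_residues`), `twist$reference`, `cluster$cutoff`,
#'   `cluster$max_frames`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- merge_config(pipeline_defaults(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(status = "failed", failed_stage = stage,
                       error = conditionMessage(e), outputs = outputs)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  g <- cfg$generator
  traj <- step("generate", {
    nf <- g$n_frames
    sched <- rep("engaged", nf)
    hs <- helix_spec(g$n_residues, noise_sigma = g$noise_sigma,
                     n_frames = nf, seed = cfg$seed)
    es <- engagement_spec(g$motif_residues, sched, noise_sigma = g$noise_sigma,
                          seed = cfg$seed)
    generate_engagement_trajectory(es, hs)
  })
  step("write_trajectory", {
    write_trajectory_txt(traj, file.path(out_dir, "trajectory.txt"))
    write_ground_truth_tsv(attr(traj, "ground_truth"),
                           file.path(out_dir, "ground_truth.tsv"))
    outputs <- c(outputs, "trajectory.txt", "ground_truth.tsv")
  })
  tm <- step("twist", twist_map(traj, reference = cfg$twist$reference))
  step("twist_out", {
    write_twist_map_tsv(tm, file.path(out_dir, "twist_map.tsv"))
    write_integrated_deviation_tsv(integrate_deviation(tm),
                                   file.path(out_dir, "integrated_deviation.tsv"))
    outputs <- c(outputs, "twist_map.tsv", "integrated_deviation.tsv")
  })
  step("rmsf", {
    write_rmsf_tsv(rmsf_profile(traj), file.path(out_dir, "rmsf.tsv"))
    outputs <- c(outputs, "rmsf.tsv")
  })
  step("engagement", {
    es <- engagement_series(traj, select_atoms(traj, entity = "ligand"),
                            select_atoms(traj, resno = g$motif_residues,
                                         entity = "protein"))
    es <- classify_binding_fate(es, attr(traj, "site_center"),
                                ligand_com_series(traj))
    write_engagement_tsv(es, file.path(out_dir, "engagement"))
    outputs <- c(outputs, "engagement_series.tsv", "engagement_fate.tsv")
  })
  step("pca", {
    dec <- pooled_pca(traj)
    write_pca_tsv(dec, file.path(out_dir, "pca"))
    outputs <- c(outputs, "pca_spectrum.tsv", "pca_projections.tsv")
  })
  step("cluster", {
    nf <- min(n_frames(traj), cfg$cluster$max_frames)
    sub <- trajectory(traj$topology,
                      traj$coords[, , seq_len(nf), drop = FALSE],
                      traj$times[seq_len(nf)])
    cl <- cluster_gromos(sub, cutoff = cfg$cluster$cutoff)
    write_cluster_tsv(cl, file.path(out_dir, "clusters.tsv"))
    rep_traj <- trajectory(traj$topology,
                           traj$coords[, , cl$representative_frame,
                                       drop = FALSE],
                           0)
    write_trajectory_pdb(rep_traj, file.path(out_dir, "representative.pdb"))
    outputs <- c(outputs, "clusters.tsv", "representative.pdb")
  })

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- list(status = "ok",
                   package = "helixgate",
                   version = as.character(utils::packageVersion("helixgate")),
                   seed = cfg$seed,
                   config = "config.json",
                   config_hash = unname(tools::md5sum(cfg_path)),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
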