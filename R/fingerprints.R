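#' Interaction typing rules
#'
#' Geometric thresholds for the five interaction types recorded in
#' per-residue protein-ligand fingerprints. Defaults follow the common
#' fingerprinting-tool family: hydrogen bonds as in [hbond_criteria()],
#' salt bridges at 4.5 A between oppositely charged heavy atoms,
#' pi-cation at 4.5 A cation-to-ring-centroid with an axial offset of at
#' most 30 degrees, hydrophobic carbon-carbon contacts at 4.5 A, and
#' water bridges on the hydrogen-bond distance cutoff.
#'
#' @param hbond an [hbond_criteria()].
#' @param salt_bridge_distance Angstrom.
#' @param pi_cation_distance Angstrom (centroid distance).
#' @param pi_cation_offset degrees; maximum angle between the ring
#'   normal and the centroid-to-cation vector.
#' @param hydrophobic_distance Angstrom.
#' @param types character vector of enabled interaction types.
#' @export
interaction_rules <- function(hbond = hbond_criteria(),
                              salt_bridge_distance = 4.5,
                              pi_cation_distance = 4.5,
                              pi_cation_offset = 30,
                              hydrophobic_distance = 4.5,
                              types = c("hydrogen_bond", "salt_bridge",
                                        "pi_cation", "hydrophobic",
                                        "water_bridge")) {
  stopifnot(salt_bridge_distance > 0, pi_cation_distance > 0,
            hydrophobic_distance > 0,
            pi_cation_offset >= 0, pi_cation_offset <= 180)
  structure(list(hbond = hbond, salt_bridge_distance = salt_bridge_distance,
                 pi_cation_distance = pi_cation_distance,
                 pi_cation_offset = pi_cation_offset,
                 hydrophobic_distance = hydrophobic_distance,
                 types = types),
            class = "interaction_rules")
}

## Built-in residue annotation templates: formal charges, aromatic ring
## atoms and apolar carbons for the standard amino acids plus the
## ornithine and leucine ligands. Avoids a chemistry-toolkit dependency
## at desk scale.
residue_templates <- function() {
  list(
    cationic = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    ORN = c("NE", "NZ"), LIG = "N"),
    anionic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    ring = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                        "CZ2", "CZ3", "CH2"),
                HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
    apolar = list(ALA = "CB", VAL = c("CB", "CG1", "CG2"),
                  LEU = c("CB", "CG", "CD1", "CD2"),
                  ILE = c("CB", "CG1", "CG2", "CD1"),
                  MET = c("CB", "CG", "CE"), PRO = c("CB", "CG", "CD"),
                  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  TRP = c("CB", "CG"), TYR = c("CB", "CG"),
                  LIG = c("CB", "CG", "CD1", "CD2"))
  )
}

template_atoms <- function(tmpl, top, idx, resname, names_list) {
  sel <- names_list[[resname]]
  if (is.null(sel)) return(integer())
  idx[top$name[idx] %in% sel]
}

#' Interaction fingerprint of one frame
#'
#' Types every (residue, interaction) contact between a ligand and a set
#' of protein residues in a single frame. Hydrogen bonds use
#' [detect_hbonds_frame()] in both directions (ligand donors to residue
#' acceptors and vice versa; distance-only where no hydrogen is
#' present); salt bridges pair oppositely charged heavy atoms within the
#' cutoff; pi-cation pairs a cationic nitrogen with an aromatic-ring
#' centroid within distance and axial offset; hydrophobic pairs apolar
#' carbons; water bridges require a water oxygen within hydrogen-bond
#' distance of both partners. Charge, ring and apolar annotations come
#' from the built-in residue template table.
#'
#' @param traj an `"hg_traj"`.
#' @param frame frame index.
#' @param ligand_idx ligand atom indices.
#' @param resno protein residue numbers screened.
#' @param rules an [interaction_rules()].
#' @return data frame with columns `resno`, `type` (zero rows when no
#'   contact).
#' @export
frame_fingerprint <- function(traj, frame, ligand_idx, resno,
                              rules = interaction_rules()) {
  stopifnot(inherits(traj, "hg_traj"), inherits(rules, "interaction_rules"))
  top <- traj$topology
  xyz <- traj$coords[, , frame, drop = TRUE]
  tmpl <- residue_templates()
  lig_heavy <- heavy_only(top, ligand_idx)
  if (!length(lig_heavy)) stop("ligand selection has no heavy atoms",
                               call. = FALSE)
  lig_res <- unique(top$resname[lig_heavy])[1]
  hits <- list()
  add <- function(r, type) hits[[length(hits) + 1L]] <<- data.frame(
    resno = r, type = type, stringsAsFactors = FALSE)

  lig_don <- lig_heavy[top$element[lig_heavy] %in% c("N", "O")]
  lig_acc <- lig_don
  lig_h <- if (length(lig_don)) vapply(lig_don, function(d) {
    h <- ligand_idx[top$element[ligand_idx] == "H"]
    if (length(h)) h[1L] else NA_integer_
  }, integer(1)) else integer()
  lig_cat <- template_atoms(tmpl, top, lig_heavy, lig_res, tmpl$cationic)
  lig_ani <- template_atoms(tmpl, top, lig_heavy, lig_res, tmpl$anionic)
  if (!length(lig_ani))  # carboxylate-like terminal oxygens of the ligand
    lig_ani <- lig_heavy[top$name[lig_heavy] %in% c("O", "OXT")]
  lig_apo <- template_atoms(tmpl, top, lig_heavy, lig_res, tmpl$apolar)

  waters <- select_atoms(traj, entity = "water")
  waters <- waters[top$element[waters] == "O"]

  for (r in sort(unique(as.integer(resno)))) {
    ridx <- which(top$resno == r & top$entity == "protein")
    if (!length(ridx)) next
    rheavy <- heavy_only(top, ridx)
    rname <- top$resname[ridx[1L]]

    if ("hydrogen_bond" %in% rules$types) {
      racc <- rheavy[top$element[rheavy] %in% c("N", "O")]
      got <- FALSE
      if (length(lig_don) && length(racc)) {
        got <- nrow(detect_hbonds_frame(xyz, lig_don, racc, lig_h,
                                        rules$hbond)) > 0
      }
      if (!got && length(lig_acc)) {
        rdon <- rheavy[top$element[rheavy] %in% c("N", "O")]
        if (length(rdon))
          got <- nrow(detect_hbonds_frame(xyz, rdon, lig_acc, NULL,
                                          rules$hbond)) > 0
      }
      if (got) add(r, "hydrogen_bond")
    }
    if ("salt_bridge" %in% rules$types) {
      rcat <- template_atoms(tmpl, top, rheavy, rname, tmpl$cationic)
      rani <- template_atoms(tmpl, top, rheavy, rname, tmpl$anionic)
      sb <- FALSE
      if (length(lig_cat) && length(rani))
        sb <- min(pair_dist(xyz[lig_cat, , drop = FALSE],
                            xyz[rani, , drop = FALSE])) <= rules$salt_bridge_distance
      if (!sb && length(lig_ani) && length(rcat))
        sb <- min(pair_dist(xyz[lig_ani, , drop = FALSE],
                            xyz[rcat, , drop = FALSE])) <= rules$salt_bridge_distance
      if (sb) add(r, "salt_bridge")
    }
    if ("pi_cation" %in% rules$types) {
      ring <- template_atoms(tmpl, top, rheavy, rname, tmpl$ring)
      if (length(ring) >= 3 && length(lig_cat)) {
        if (pi_cation_contact(xyz, ring, lig_cat, rules)) add(r, "pi_cation")
      }
    }
    if ("hydrophobic" %in% rules$types) {
      rapo <- template_atoms(tmpl, top, rheavy, rname, tmpl$apolar)
      if (length(rapo) && length(lig_apo)) {
        if (min(pair_dist(xyz[lig_apo, , drop = FALSE],
                          xyz[rapo, , drop = FALSE])) <=
            rules$hydrophobic_distance) add(r, "hydrophobic")
      }
    }
    if ("water_bridge" %in% rules$types && length(waters)) {
      cut <- rules$hbond$max_donor_acceptor_distance
      wb <- FALSE
      for (w in waters) {
        dl <- min(sqrt(colSums((t(xyz[lig_heavy, , drop = FALSE]) - xyz[w, ])^2)))
        dr <- min(sqrt(colSums((t(xyz[rheavy, , drop = FALSE]) - xyz[w, ])^2)))
        if (dl <= cut && dr <= cut) { wb <- TRUE; break }
      }
      if (wb) add(r, "water_bridge")
    }
  }
  if (!length(hits))
    return(data.frame(resno = integer(), type = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, hits))
}

## cationic nitrogen within centroid distance and axial offset of a ring
pi_cation_contact <- function(xyz, ring_idx, cat_idx, rules) {
  ring <- xyz[ring_idx, , drop = FALSE]
  centroid <- colMeans(ring)
  centred <- sweep(ring, 2, centroid)
  normal <- svd(centred)$v[, 3L]            # least-variance direction
  for (ci in cat_idx) {
    v <- xyz[ci, ] - centroid
    d <- sqrt(sum(v^2))
    if (d > rules$pi_cation_distance) next
    ang <- acos(min(1, abs(sum(v * normal)) / d)) * 180 / pi
    if (ang <= rules$pi_cation_offset) return(TRUE)
  }
  FALSE
}

#' Fingerprint a whole replicate
#'
#' Runs [frame_fingerprint()] over every frame and tabulates, for each
#' (residue, type), the fraction of frames in which the interaction is
#' present.
#'
#' @inheritParams frame_fingerprint
#' @return data frame `resno`, `type`, `frequency` with the residue
#'   universe recorded in attribute `"universe"`.
#' @export
fingerprint_replicate <- function(traj, ligand_idx, resno,
                                  rules = interaction_rules()) {
  nf <- n_frames(traj)
  per_frame <- lapply(seq_len(nf), function(f)
    frame_fingerprint(traj, f, ligand_idx, resno, rules))
  all_rows <- do.call(rbind, per_frame)
  if (is.null(all_rows) || !nrow(all_rows)) {
    out <- data.frame(resno = integer(), type = character(),
                      frequency = numeric(), stringsAsFactors = FALSE)
  } else {
    tab <- stats::aggregate(cnt ~ resno + type,
                            data = cbind(all_rows, cnt = 1), FUN = sum)
    out <- data.frame(resno = tab$resno, type = tab$type,
                      frequency = tab$cnt / nf, stringsAsFactors = FALSE)
    out <- out[order(out$resno, out$type), ]
    rownames(out) <- NULL
  }
  attr(out, "universe") <- sort(unique(as.integer(resno)))
  out
}

#' Aggregate fingerprints across replicates
#'
#' Joins per-replicate (residue, type) frequencies over the union of
#' observed rows (absent rows count as frequency 0), and reports the
#' mean and sample standard deviation across replicates -- the
#' replicate-averaged per-residue interaction profile.
#'
#' @param replicates list of [fingerprint_replicate()] results sharing
#'   an identical residue universe.
#' @return A data frame of class `"fingerprint_table"` with columns
#'   `resno`, `type`, one `freq_repN` column per replicate, `mean`,
#'   `sd`, `n`.
#' @export
aggregate_fingerprints <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  unis <- lapply(replicates, attr, "universe")
  if (length(unique(vapply(unis, paste, "", collapse = ","))) != 1L)
    stop("replicates have mismatched residue universes", call. = FALSE)
  keys <- unique(do.call(rbind, lapply(replicates, function(r)
    r[, c("resno", "type")])))
  keys <- keys[order(keys$resno, keys$type), , drop = FALSE]
  rownames(keys) <- NULL
  freq <- sapply(replicates, function(r) {
    m <- merge(keys, r, by = c("resno", "type"), all.x = TRUE, sort = FALSE)
    m <- m[order(m$resno, m$type), ]
    ifelse(is.na(m$frequency), 0, m$frequency)
  })
  freq <- matrix(freq, nrow = nrow(keys))
  colnames(freq) <- paste0("freq_rep", seq_along(replicates))
  out <- cbind(keys, as.data.frame(freq),
               mean = rowMeans(freq),
               sd = if (ncol(freq) > 1) apply(freq, 1, stats::sd) else 0,
               n = ncol(freq))
  class(out) <- c("fingerprint_table", "data.frame")
  out
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat("Fingerprint table:", nrow(x), "residue-interaction rows,",
      x$n[1], "replicate(s)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
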