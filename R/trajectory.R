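#' Trajectory container
#'
#' A trajectory couples an atom topology with per-frame coordinates and
#' uniformly spaced frame times. Coordinates are stored as an
#' `n_atoms x 3 x n_frames` array in Angstrom; times in picoseconds.
#'
#' @param topology data frame with one row per atom and columns `chain`,
#'   `resno` (integer residue number), `resname`, `name` (atom name),
#'   `element`, `entity` (one of `"protein"`, `"ligand"`, `"water"`).
#' @param coords numeric array `n_atoms x 3 x n_frames` (a plain
#'   `n_atoms x 3` matrix is promoted to a single frame).
#' @param times numeric vector of frame times in ps, or a single frame
#'   spacing from which times `0, dt, 2*dt, ...` are built.
#' @return An object of class `"hg_traj"`.
#' @export
trajectory <- function(topology, coords, times) {
  topology <- validate_topology(topology)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology)) {
    stop("coordinate array has ", dim(coords)[1], " atoms but topology has ",
         nrow(topology), call. = FALSE)
  }
  nf <- dim(coords)[3]
  if (length(times) == 1L && nf > 1L) times <- (seq_len(nf) - 1) * times
  if (length(times) != nf) {
    stop("length(times) [", length(times), "] != number of frames [", nf, "]",
         call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "hg_traj")
}

validate_topology <- function(top) {
  top <- as.data.frame(top, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resname", "name", "element", "entity")
  miss <- setdiff(req, names(top))
  if (length(miss)) stop("topology lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(top$entity %in% c("protein", "ligand", "water"))) {
    stop("entity must be protein, ligand or water", call. = FALSE)
  }
  top$resno <- as.integer(top$resno)
  top
}

#' @export
print.hg_traj <- function(x, ...) {
  cat("Trajectory:", n_atoms(x), "atoms,", n_frames(x), "frames")
  if (n_frames(x) > 1L) {
    dt <- diff(x$times)
    cat(sprintf(", %g ps spacing (%g ns total)", dt[1],
                diff(range(x$times)) / 1e3))
  }
  cat("\n  entities:", paste(sprintf("%s=%d", names(table(x$topology$entity)),
                                     table(x$topology$entity)), collapse = " "), "\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj an `hg_traj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an `n_atoms x 3` coordinate matrix
#' @param traj an `hg_traj`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Select atoms from a topology
#'
#' Typed selection over the topology table, the role a selection grammar
#' plays in trajectory toolkits: each non-NULL argument restricts the
#' match, and all restrictions are combined with AND. Returns atom
#' indices (1-based, in topology order).
#'
#' @param x an `hg_traj` or a topology data frame.
#' @param chain,resname,name,element,entity character vectors of accepted
#'   values (OR within an argument).
#' @param resno integer vector of residue numbers (e.g. a range `30:60`).
#' @param invert logical; if TRUE, return the complement.
#' @return integer vector of atom indices; empty selections are allowed
#'   here and validated by the consuming operation.
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, resname = NULL,
                         name = NULL, element = NULL, entity = NULL,
                         invert = FALSE) {
  top <- if (inherits(x, "hg_traj")) x$topology else validate_topology(x)
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain))   keep <- keep & top$chain %in% chain
  if (!is.null(resno))   keep <- keep & top$resno %in% resno
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(name))    keep <- keep & top$name %in% name
  if (!is.null(element)) keep <- keep & top$element %in% element
  if (!is.null(entity))  keep <- keep & top$entity %in% entity
  if (invert) keep <- !keep
  which(keep)
}

## indices of heavy (non-hydrogen) atoms within a selection
heavy_only <- function(top, idx) idx[top$element[idx] != "H"]

## minimal topology builder used by generators and tests
make_topology <- function(n_res, chain = "A", resname = "ALA", atom = "CA",
                          element = "C", entity = "protein",
                          resno = seq_len(n_res)) {
  data.frame(chain = chain, resno = as.integer(resno), resname = resname,
             name = atom, element = element, entity = entity,
             stringsAsFactors = FALSE)
}
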