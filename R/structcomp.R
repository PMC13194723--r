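#' Read a static structure (PDB or mmCIF)
#'
#' Parses via bio3d (`read.pdb` / `read.cif` by extension). Only altloc
#' A (or blank) is retained, with a warning when alternates are dropped.
#' Ligand and water entities are flagged from the record type and
#' residue name.
#'
#' @param path file path ending in `.pdb`, `.ent`, `.cif` or `.mmcif`.
#' @return A list of class `"hg_structure"` whose `atoms` element is a
#'   data frame with `chain`, `resno`, `insert`, `resname`, `name`,
#'   `element`, `entity`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  alt <- !(is.na(at$alt) | at$alt %in% c("", "A"))
  if (any(alt)) {
    warning(sum(alt), " alternate-location atoms dropped (kept altloc A)")
    at <- at[!alt, ]
  }
  water <- at$resid %in% c("HOH", "WAT", "TIP", "SOL")
  entity <- ifelse(at$type == "ATOM" & !water, "protein",
                   ifelse(water, "water", "ligand"))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = at$resid, name = at$elety,
                      element = trimws(elem), entity = entity,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "hg_structure")
}

#' Build a structure object from an atom table
#'
#' Constructor used for synthetic structures in examples and tests.
#'
#' @param atoms data frame as documented in [read_structure()].
#' @export
structure_model <- function(atoms) {
  req <- c("chain", "resno", "resname", "name", "element", "entity",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, insert, atom) keys",
                               call. = FALSE)
  structure(list(atoms = atoms, source = "constructed"),
            class = "hg_structure")
}

#' @export
print.hg_structure <- function(x, ...) {
  a <- x$atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno)[a$entity == "protein"])),
      "protein residues,", sum(a$entity == "ligand"), "ligand atoms\n")
  invisible(x)
}

struct_xyz <- function(s, idx) as.matrix(s$atoms[idx, c("x", "y", "z")])

#' Select atoms of a structure
#'
#' @param s an `"hg_structure"`.
#' @inheritParams select_atoms
#' @param heavy drop hydrogens (default TRUE).
#' @return integer row indices into `s$atoms`.
#' @export
select_structure <- function(s, chain = NULL, resno = NULL, resname = NULL,
                             name = NULL, entity = NULL, heavy = TRUE) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(entity))  keep <- keep & a$entity %in% entity
  if (heavy)             keep <- keep & a$element != "H"
  which(keep)
}

#' C-alpha RMSD between two structures
#'
#' Pairs C-alpha atoms by shared (chain, residue number) keys, Kabsch
#' superposes the matched set and reports the post-fit RMSD and the
#' number of matched pairs.
#'
#' @param a,b `"hg_structure"` objects.
#' @param chain optional chain restriction applied to both.
#' @return list with `rmsd` (Angstrom) and `n_matched`.
#' @export
ca_rmsd_pair <- function(a, b, chain = NULL) {
  ia <- select_structure(a, chain = chain, name = "CA", entity = "protein")
  ib <- select_structure(b, chain = chain, name = "CA", entity = "protein")
  ka <- paste(a$atoms$chain[ia], a$atoms$resno[ia])
  kb <- paste(b$atoms$chain[ib], b$atoms$resno[ib])
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no shared C-alpha residues", call. = FALSE)
  xa <- struct_xyz(a, ia[match(shared, ka)])
  xb <- struct_xyz(b, ib[match(shared, kb)])
  fit <- kabsch_superpose(xa, xb)
  list(rmsd = fit$rmsd, n_matched = length(shared))
}

#' Residues within a distance shell of a centre entity
#'
#' All protein residues having any heavy atom within `cutoff` of any
#' heavy atom of the centre selection -- e.g. the binding-site shell
#' around a bound ligand.
#'
#' @param s an `"hg_structure"`.
#' @param center_idx atom indices of the centre entity (e.g. from
#'   [select_structure()] on the ligand); must be non-empty.
#' @param cutoff shell radius, Angstrom.
#' @return data frame `chain`, `resno` of shell residues (zero rows for
#'   cutoff 0).
#' @export
shell_residues <- function(s, center_idx, cutoff) {
  if (!length(center_idx)) stop("no centre atoms found", call. = FALSE)
  a <- s$atoms
  prot <- select_structure(s, entity = "protein")
  if (cutoff <= 0 || !length(prot))
    return(data.frame(chain = character(), resno = integer()))
  d <- pair_dist(struct_xyz(s, prot), struct_xyz(s, center_idx))
  near <- prot[apply(d, 1, min) <= cutoff]
  out <- unique(data.frame(chain = a$chain[near], resno = a$resno[near],
                           stringsAsFactors = FALSE))
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Minimum heavy-atom contact distance between two selections
#'
#' @param s an `"hg_structure"`.
#' @param idx_a,idx_b atom index vectors (hydrogens are excluded).
#' @return minimum pairwise distance, Angstrom.
#' @export
contact_distance <- function(s, idx_a, idx_b) {
  idx_a <- idx_a[s$atoms$element[idx_a] != "H"]
  idx_b <- idx_b[s$atoms$element[idx_b] != "H"]
  if (!length(idx_a)) stop("selection A resolves to zero heavy atoms",
                           call. = FALSE)
  if (!length(idx_b)) stop("selection B resolves to zero heavy atoms",
                           call. = FALSE)
  min(pair_dist(struct_xyz(s, idx_a), struct_xyz(s, idx_b)))
}

#' Per-atom displacement between two conformational states
#'
#' Superposes structure `b` onto structure `a` over a stated (chain,
#' residue) selection -- e.g. the rigid scaffold -- and reports the
#' Euclidean displacement of each requested atom between the two
#' states.
#'
#' @param a,b `"hg_structure"` objects (e.g. apo and ligand-bound).
#' @param superpose_resno residue numbers of the superposition set.
#' @param report data frame with columns `resno`, `name` naming the
#'   atoms to report; every atom must exist in both structures.
#' @param chain optional chain restriction.
#' @return the `report` table with a `displacement` column (Angstrom).
#' @export
state_displacement <- function(a, b, superpose_resno, report, chain = NULL) {
  ia <- select_structure(a, chain = chain, resno = superpose_resno,
                         name = "CA", entity = "protein")
  ib <- select_structure(b, chain = chain, resno = superpose_resno,
                         name = "CA", entity = "protein")
  ka <- paste(a$atoms$chain[ia], a$atoms$resno[ia])
  kb <- paste(b$atoms$chain[ib], b$atoms$resno[ib])
  shared <- intersect(ka, kb)
  if (length(shared) < 3) stop("superposition set has < 3 shared C-alphas",
                               call. = FALSE)
  fit <- kabsch_superpose(struct_xyz(b, ib[match(shared, kb)]),
                          struct_xyz(a, ia[match(shared, ka)]))
  disp <- numeric(nrow(report))
  for (k in seq_len(nrow(report))) {
    sa <- select_structure(a, chain = chain, resno = report$resno[k],
                           name = report$name[k])
    sb <- select_structure(b, chain = chain, resno = report$resno[k],
                           name = report$name[k])
    if (length(sa) != 1L || length(sb) != 1L)
      stop("report atom ", report$resno[k], "/", report$name[k],
           " missing or ambiguous", call. = FALSE)
    pb <- apply_fit(struct_xyz(b, sb), fit)
    disp[k] <- sqrt(sum((struct_xyz(a, sa) - pb)^2))
  }
  cbind(report, displacement = disp)
}

#' Pairwise sequence identity and similarity
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties via
#' Biostrings, scored with a substitution matrix (BLOSUM62 by default).
#' Identity is the fraction of alignment columns with identical
#' residues; similarity the fraction with a positive substitution score
#' (identities included). Both are reported over the full alignment
#' length including gap columns; the alternative shorter-sequence
#' denominators are attached as attributes `"identity_short"` and
#' `"similarity_short"` since conventions differ between programs.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings, standard
#'   one-letter codes).
#' @param substitution_matrix matrix name (e.g. `"BLOSUM62"`) or an
#'   actual scoring matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return A list of class `"alignment_result"` with `aligned_a`,
#'   `aligned_b`, `percent_identity`, `percent_similarity`, `columns`
#'   and `scoring`.
#' @export
pairwise_identity_similarity <- function(seq_a, seq_b,
                                         substitution_matrix = "BLOSUM62",
                                         gap_open = 10, gap_extend = 0.5) {
  for (s in c(seq_a, seq_b)) {
    if (!nchar(s)) stop("empty sequence", call. = FALSE)
    bad <- setdiff(strsplit(toupper(s), "")[[1]],
                   strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO", "")[[1]])
    if (length(bad)) stop("invalid residue letter(s): ",
                          paste(bad, collapse = ""), call. = FALSE)
  }
  mat <- if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    get(substitution_matrix, envir = e)
  } else substitution_matrix
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncol_al <- length(al_a)
  aligned <- al_a != "-" & al_b != "-"
  ident <- aligned & al_a == al_b
  simil <- ident
  pairs <- which(aligned & !ident)
  if (length(pairs)) {
    sc <- mat[cbind(al_a[pairs], al_b[pairs])]
    simil[pairs] <- sc > 0
  }
  short_len <- min(nchar(seq_a), nchar(seq_b))
  res <- structure(list(
    aligned_a = paste(al_a, collapse = ""),
    aligned_b = paste(al_b, collapse = ""),
    percent_identity = 100 * sum(ident) / ncol_al,
    percent_similarity = 100 * sum(simil) / ncol_al,
    columns = ncol_al,
    scoring = sprintf("%s, gap open %g / extend %g (global)",
                      if (is.character(substitution_matrix))
                        substitution_matrix else "custom matrix",
                      gap_open, gap_extend)),
    class = "alignment_result")
  attr(res, "identity_short") <- 100 * sum(ident) / short_len
  attr(res, "similarity_short") <- 100 * sum(simil) / short_len
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment (%s): %.1f%% identity, %.1f%% similarity over %d columns\n",
              x$scoring, x$percent_identity, x$percent_similarity, x$columns))
  invisible(x)
}
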