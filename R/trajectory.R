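# Trajectory container: static topology (one atom table) plus a
# [n_atoms x 3 x n_frames] coordinate array in nanometres. One object per
# replicate simulation of one enzyme-peptide complex.

new_trajectory <- function(atoms, coords, enzyme_chain, substrate_chain,
                           kac_resno, peptide = NULL, replicate_id = 1L,
                           kac_carbonyl_atom = "OH") {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials")
  zn_idx <- which(toupper(atoms$element) == "ZN")
  if (length(zn_idx) != 1)
    stop("topology error: expected exactly one Zn atom (element ZN), found ",
         length(zn_idx))
  kac_o_idx <- which(atoms$chain == substrate_chain &
                     atoms$resno == kac_resno &
                     atoms$name == kac_carbonyl_atom)
  if (length(kac_o_idx) != 1)
    stop("topology error: acetyl carbonyl atom '", kac_carbonyl_atom,
         "' not found in substrate residue ", kac_resno)
  if (!any(atoms$chain == enzyme_chain))
    stop("topology error: enzyme chain '", enzyme_chain, "' absent")
  structure(list(atoms = atoms, coords = coords,
                 enzyme_chain = enzyme_chain,
                 substrate_chain = substrate_chain,
                 kac_resno = kac_resno, peptide = peptide,
                 replicate_id = as.integer(replicate_id),
                 zn_idx = zn_idx, kac_o_idx = kac_o_idx),
            class = "kdac_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `kdac_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @export
print.kdac_trajectory <- function(x, ...) {
  cat("<kdac_trajectory> ", nrow(x$atoms), " atoms, ", n_frames(x),
      " frames; enzyme chain ", x$enzyme_chain, ", substrate chain ",
      x$substrate_chain, ", acetyllysine at residue ", x$kac_resno,
      ", replicate ", x$replicate_id, "\n", sep = "")
  invisible(x)
}

# Zn and acetyl-carbonyl positions, [n_frames x 3] matrices (nm)
zn_positions <- function(traj) t(traj$coords[traj$zn_idx, , , drop = TRUE])
kac_carbonyl_positions <- function(traj)
  t(traj$coords[traj$kac_o_idx, , , drop = TRUE])

# atom-row indices of one residue
residue_atom_idx <- function(traj, chain, resno) {
  which(traj$atoms$chain == chain & traj$atoms$resno == resno)
}

# substrate residue number for a signed offset from the acetyllysine
substrate_resno <- function(traj, offset) traj$kac_resno + offset

#' Extract a single frame
#'
#' @param traj A `kdac_trajectory`.
#' @param index 1-based frame index.
#' @return A `kdac_frame`: the atom table with `x`, `y`, `z` columns (nm)
#'   plus `zn_position` and `kac_carbonyl_position` attributes.
#' @export
get_frame <- function(traj, index) {
  stopifnot(index >= 1, index <= n_frames(traj))
  fr <- traj$atoms
  fr$x <- traj$coords[, 1, index]
  fr$y <- traj$coords[, 2, index]
  fr$z <- traj$coords[, 3, index]
  structure(fr, zn_position = traj$coords[traj$zn_idx, , index],
            kac_carbonyl_position = traj$coords[traj$kac_o_idx, , index],
            index = index, enzyme_chain = traj$enzyme_chain,
            substrate_chain = traj$substrate_chain,
            kac_resno = traj$kac_resno,
            class = c("kdac_frame", "data.frame"))
}

infer_element <- function(name) {
  n <- sub("^[0-9]+", "", name)
  ifelse(substr(n, 1, 1) == "H", "H",
         ifelse(toupper(substr(n, 1, 2)) == "ZN", "ZN", substr(n, 1, 1)))
}

#' Load a multi-model PDB trajectory
#'
#' Reads a multi-model PDB (one MODEL per saved frame) and returns a
#' trajectory in nanometres. The enzyme and substrate chains must both be
#' present; the substrate must carry the acetyllysine with its acetyl
#' carbonyl oxygen (atom `kac_carbonyl_atom`), and a single Zn atom must
#' exist. Coordinates are converted from the PDB's angstroms.
#'
#' @param path Path to a multi-model PDB file.
#' @param enzyme_chain,substrate_chain PDB chain identifiers.
#' @param kac_resno Residue number of the acetyllysine in the substrate chain.
#' @param peptide Optional `kdac_peptide` (or sequence string) for the
#'   substrate.
#' @param replicate_id Integer replicate label.
#' @param kac_carbonyl_atom Atom name of the acetyl carbonyl oxygen
#'   (default `"OH"`, the PDB ALY convention).
#' @return A `kdac_trajectory`.
#' @export
load_trajectory <- function(path, enzyme_chain, substrate_chain, kac_resno,
                            peptide = NULL, replicate_id = 1L,
                            kac_carbonyl_atom = "OH") {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("malformed trajectory '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  element <- if (!is.null(at$elesy) && !all(is.na(at$elesy)) &&
                 !all(trimws(at$elesy) == ""))
    trimws(at$elesy) else infer_element(trimws(at$elety))
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resname = trimws(at$resid), chain = trimws(at$chain),
                      resno = at$resno, element = toupper(element),
                      stringsAsFactors = FALSE)
  atoms$is_hydrogen <- atoms$element == "H"
  nf <- nrow(pdb$xyz)
  na <- nrow(atoms)
  if (ncol(pdb$xyz) != 3 * na)
    stop("malformed trajectory: inconsistent atom count across models")
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A->nm
  for (ch in c(enzyme_chain, substrate_chain))
    if (!any(atoms$chain == ch))
      stop("topology error: chain '", ch, "' not found in ", path)
  if (is.character(peptide)) peptide <- parse_peptide(peptide)
  new_trajectory(atoms, coords, enzyme_chain, substrate_chain, kac_resno,
                 peptide = peptide, replicate_id = replicate_id,
                 kac_carbonyl_atom = kac_carbonyl_atom)
}

#' Write a trajectory as a multi-model PDB
#'
#' Emits one MODEL/ENDMDL block per frame in fixed-column PDB format
#' (coordinates in angstroms, 3 decimals). Output is byte-deterministic for
#' a given trajectory, which the synthetic generator relies on.
#'
#' @param traj A `kdac_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$atoms
  rectype <- ifelse(at$resname %in% c("ZN", "HOH"), "HETATM", "ATOM")
  name_fmt <- ifelse(nchar(at$name) >= 4, at$name,
                     sprintf(" %-3s", at$name))
  con <- file(path, open = "wb")  # binary: fixed LF line endings
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f] * 10  # nm -> A
    lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rectype, at$serial, name_fmt, at$resname, at$chain,
                     at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     at$element)
    writeLines(c(sprintf("MODEL %8d", f), lines, "ENDMDL"), con, sep = "\n")
  }
  writeLines("END", con, sep = "\n")
  invisible(path)
}
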