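# Per-frame geometric interaction detectors. All distances in nanometres.
# Definitions: a van der Waals contact is any-atom/any-atom proximity
# <= 0.30 nm; an ionic interaction is a cationic-group hydrogen <= 0.25 nm
# from an anionic-group oxygen; a hydrogen bond requires donor-acceptor
# heavy atoms <= 0.35 nm with hydrogen-donor-acceptor angle <= 30 degrees;
# a frame is catalytically relevant while the Zn(2+)-to-acetyl-carbonyl
# distance does not exceed 0.32 nm.

#' Interaction criteria
#'
#' Bundles the geometric cutoffs used by all detectors. Defaults are the
#' standard MD conventions for this analysis: 0.30 nm any-atom contact,
#' 0.25 nm ionic H--O, 0.35 nm / 30 degree hydrogen bond, and 0.32 nm
#' Zn--carbonyl for catalytic relevance.
#'
#' @param contact_cutoff,ionic_cutoff,hbond_heavy_cutoff,catalytic_cutoff
#'   Distance cutoffs in nm.
#' @param hbond_angle_max Maximum hydrogen-donor-acceptor angle, degrees.
#' @return A `kdac_criteria` list.
#' @export
interaction_criteria <- function(contact_cutoff = 0.30, ionic_cutoff = 0.25,
                                 hbond_heavy_cutoff = 0.35,
                                 hbond_angle_max = 30,
                                 catalytic_cutoff = 0.32) {
  vals <- c(contact_cutoff, ionic_cutoff, hbond_heavy_cutoff,
            hbond_angle_max, catalytic_cutoff)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all criteria must be positive and finite")
  structure(list(contact_cutoff = contact_cutoff,
                 ionic_cutoff = ionic_cutoff,
                 hbond_heavy_cutoff = hbond_heavy_cutoff,
                 hbond_angle_max = hbond_angle_max,
                 catalytic_cutoff = catalytic_cutoff),
            class = "kdac_criteria")
}

#' Minimum interatomic distance between two atom sets
#'
#' @param a,b Numeric coordinate matrices (rows = atoms, columns = x,y,z, nm).
#' @return Minimum Euclidean cross-pair distance, nm.
#' @export
min_interatomic_distance <- function(a, b) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("min_interatomic_distance: empty atom set")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  x
}

# ---- residue selection helpers -------------------------------------------

#' Residue reference
#'
#' A lightweight selector naming one residue by chain and residue number,
#' accepted by all frame-level detectors.
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @export
res_ref <- function(chain, resno) list(chain = chain, resno = as.integer(resno))

#' @rdname res_ref
#' @param frame A `kdac_frame` (or `kdac_trajectory`).
#' @param offset Signed substrate position relative to the acetyllysine.
#' @export
substrate_ref <- function(frame, offset) {
  res_ref(attr(frame, "substrate_chain") %||% frame$substrate_chain,
          (attr(frame, "kac_resno") %||% frame$kac_resno) + offset)
}

#' @rdname res_ref
#' @export
enzyme_ref <- function(frame, resno) {
  res_ref(attr(frame, "enzyme_chain") %||% frame$enzyme_chain, resno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frame_residue <- function(frame, ref) {
  sel <- frame$chain == ref$chain & frame$resno == ref$resno
  if (!any(sel))
    stop("selection error: no atoms for residue ", ref$resno,
         " in chain ", ref$chain)
  frame[sel, , drop = FALSE]
}

# ---- detectors ------------------------------------------------------------

#' Detect a van der Waals contact in one frame
#'
#' True when any atom of residue `a` is within `contact_cutoff` of any atom
#' of residue `b`.
#'
#' @param frame A `kdac_frame` from [get_frame()].
#' @param a,b Residue references ([res_ref()], [enzyme_ref()],
#'   [substrate_ref()]).
#' @param criteria An [interaction_criteria()] object.
#' @return Logical scalar.
#' @export
detect_contact <- function(frame, a, b, criteria = interaction_criteria()) {
  ra <- frame_residue(frame, a)
  rb <- frame_residue(frame, b)
  min_interatomic_distance(ra, rb) <= criteria$contact_cutoff
}

#' Detect an ionic interaction in one frame
#'
#' One residue must carry a cationic group bearing hydrogens (Arg
#' guanidinium, Lys ammonium, protonated His) and the other an anionic
#' carboxylate; polarity is inferred from the residue names. True when any
#' cationic-group hydrogen is within `ionic_cutoff` of an anionic-group
#' oxygen.
#'
#' @inheritParams detect_contact
#' @param his_protonated Treat histidines as protonated?
#' @return Logical scalar.
#' @export
detect_ionic <- function(frame, a, b, criteria = interaction_criteria(),
                         his_protonated = FALSE) {
  ra <- frame_residue(frame, a)
  rb <- frame_residue(frame, b)
  cha <- residue_chemistry(ra$resname[1], his_protonated)
  chb <- residue_chemistry(rb$resname[1], his_protonated)
  a_cat <- length(cha$cationic_h) > 0
  b_cat <- length(chb$cationic_h) > 0
  a_ani <- length(cha$anionic_o) > 0
  b_ani <- length(chb$anionic_o) > 0
  if (a_cat && b_ani) {
    hs <- ra[ra$name %in% cha$cationic_h, ]
    os <- rb[rb$name %in% chb$anionic_o, ]
  } else if (b_cat && a_ani) {
    hs <- rb[rb$name %in% chb$cationic_h, ]
    os <- ra[ra$name %in% cha$anionic_o, ]
  } else {
    stop("pairing error: need one cationic and one anionic residue, got ",
         ra$resname[1], " / ", rb$resname[1])
  }
  if (nrow(hs) == 0 || nrow(os) == 0)
    stop("pairing error: charge-group atoms missing from frame")
  min_interatomic_distance(hs, os) <= criteria$ionic_cutoff
}

#' Detect a hydrogen bond in one frame
#'
#' True when some donor heavy atom D with a bonded hydrogen H, and some
#' acceptor heavy atom A in the requested scope, satisfy
#' |D - A| <= `hbond_heavy_cutoff` and angle(H-D-A) <= `hbond_angle_max`.
#' A donor residue without donor hydrogens yields `FALSE` (with a message),
#' not an error.
#'
#' @inheritParams detect_contact
#' @param donor,acceptor Residue references.
#' @param acceptor_scope `"sidechain"` or `"backbone"` (carbonyl O).
#' @param his_protonated Treat histidines as protonated?
#' @return Logical scalar.
#' @export
detect_hbond <- function(frame, donor, acceptor,
                         criteria = interaction_criteria(),
                         acceptor_scope = c("sidechain", "backbone"),
                         his_protonated = FALSE) {
  acceptor_scope <- match.arg(acceptor_scope)
  rd <- frame_residue(frame, donor)
  ra <- frame_residue(frame, acceptor)
  pairs <- donor_pairs(rd, his_protonated)
  if (nrow(pairs) == 0) {
    message("no donor hydrogens on residue ", donor$resno, "; hbond FALSE")
    return(FALSE)
  }
  acc <- acceptor_atoms(ra, acceptor_scope, his_protonated)
  if (nrow(acc) == 0) return(FALSE)
  for (i in seq_len(nrow(pairs))) {
    D <- as.numeric(rd[rd$name == pairs[i, "donor"], c("x", "y", "z")][1, ])
    H <- as.numeric(rd[rd$name == pairs[i, "hydrogen"], c("x", "y", "z")][1, ])
    for (j in seq_len(nrow(acc))) {
      A <- as.numeric(acc[j, c("x", "y", "z")])
      if (hbond_geometry_ok(D, H, A, criteria)) return(TRUE)
    }
  }
  FALSE
}

# donor (D,H) name pairs present in a residue's atom table, incl. backbone N-H
donor_pairs <- function(res_atoms, his_protonated = FALSE,
                        scope = c("both", "sidechain", "backbone")) {
  scope <- match.arg(scope)
  chem <- residue_chemistry(res_atoms$resname[1], his_protonated)
  p <- chem$sc_donors
  if (scope == "backbone") p <- BACKBONE_DONOR
  if (scope == "both") p <- rbind(p, BACKBONE_DONOR)
  keep <- p[, "donor"] %in% res_atoms$name & p[, "hydrogen"] %in% res_atoms$name
  p[keep, , drop = FALSE]
}

acceptor_atoms <- function(res_atoms, scope, his_protonated = FALSE) {
  chem <- residue_chemistry(res_atoms$resname[1], his_protonated)
  names <- if (scope == "sidechain") chem$sc_acceptors else BACKBONE_ACCEPTORS
  res_atoms[res_atoms$name %in% names, , drop = FALSE]
}

hbond_geometry_ok <- function(D, H, A, criteria) {
  da <- A - D
  dda <- sqrt(sum(da^2))
  if (dda > criteria$hbond_heavy_cutoff) return(FALSE)
  dh <- H - D
  cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * dda)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi <= criteria$hbond_angle_max
}

#' Is a frame in a catalytically relevant conformation?
#'
#' True while the Zn(2+)-to-acetyl-carbonyl-oxygen distance does not exceed
#' `catalytic_cutoff` (0.32 nm); the boundary itself counts as catalytic.
#'
#' @param frame A `kdac_frame`.
#' @param criteria An [interaction_criteria()] object.
#' @return Logical scalar.
#' @export
is_catalytic_frame <- function(frame, criteria = interaction_criteria()) {
  zn <- attr(frame, "zn_position")
  ko <- attr(frame, "kac_carbonyl_position")
  # squared comparison keeps the boundary case (exactly 0.32 nm) exact
  sum((zn - ko)^2) <= criteria$catalytic_cutoff^2
}

# ---- vectorized (all-frames) counterparts used by scan_interactions ------

# 3 x F coordinate matrix of one atom across frames (robust to F == 1)
.atom_xyz <- function(coords, i) matrix(coords[i, , ], nrow = 3)

# logical vector over frames: min cross-pair distance <= cutoff
.occ_mindist <- function(coords, idx_a, idx_b, cutoff) {
  nf <- dim(coords)[3]
  best <- rep(Inf, nf)
  for (i in idx_a) {
    ci <- .atom_xyz(coords, i)
    for (j in idx_b) {
      d2 <- colSums((ci - .atom_xyz(coords, j))^2)
      best <- pmin(best, d2)
    }
  }
  best <= cutoff^2
}

# logical vector over frames for one (D,H,A) index triple
.occ_hbond_triple <- function(coords, d_i, h_i, a_i, cutoff, angle_max) {
  da <- .atom_xyz(coords, a_i) - .atom_xyz(coords, d_i)
  dda2 <- colSums(da^2)
  dh <- .atom_xyz(coords, h_i) - .atom_xyz(coords, d_i)
  dot <- colSums(dh * da)
  cosang <- dot / sqrt(colSums(dh^2) * dda2)
  cosang <- pmax(-1, pmin(1, cosang))
  (dda2 <= cutoff^2) & (acos(cosang) * 180 / pi <= angle_max)
}

#' Per-frame catalytic-relevance mask for a whole trajectory
#' @param traj A `kdac_trajectory`.
#' @param criteria An [interaction_criteria()] object.
#' @return Logical vector, one element per frame.
#' @export
catalytic_mask <- function(traj, criteria = interaction_criteria()) {
  d2 <- colSums((.atom_xyz(traj$coords, traj$zn_idx) -
                 .atom_xyz(traj$coords, traj$kac_o_idx))^2)
  d2 <= criteria$catalytic_cutoff^2
}
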