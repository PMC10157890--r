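# Residue chemistry used by the geometric detectors and the capability
# bookkeeping of the low-frequency filter. Atom names follow PDB v3
# conventions for the standard amino acids; ALY is acetyllysine.

#' Residue chemistry table
#'
#' Returns, for a three-letter residue name, the atom-name sets that define
#' its interaction chemistry: hydrogens of a cationic group, oxygens of an
#' anionic group, side-chain donor--hydrogen pairs and side-chain acceptor
#' heavy atoms. Histidine is treated as neutral by default; pass
#' `his_protonated = TRUE` for the imidazolium form. Peptide substrates are
#' assumed N-acetylated and C-amidated, so termini carry no charge.
#'
#' @param resname Three-letter residue name (e.g. `"ARG"`, `"ALY"`).
#' @param his_protonated Treat histidine as protonated (cationic)?
#' @return A list with character vectors `cationic_h`, `anionic_o`,
#'   `sc_acceptors` and a two-column matrix `sc_donors` (donor, hydrogen).
#' @export
residue_chemistry <- function(resname, his_protonated = FALSE) {
  dn <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("donor", "hydrogen")
    m
  }
  empty <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("donor", "hydrogen")))
  out <- list(cationic_h = character(0), anionic_o = character(0),
              sc_donors = empty, sc_acceptors = character(0))
  switch(resname,
    ARG = {
      out$cationic_h <- c("HE", "HH11", "HH12", "HH21", "HH22")
      out$sc_donors <- dn("NE", "HE", "NH1", "HH11", "NH1", "HH12",
                          "NH2", "HH21", "NH2", "HH22")
    },
    LYS = {
      out$cationic_h <- c("HZ1", "HZ2", "HZ3")
      out$sc_donors <- dn("NZ", "HZ1", "NZ", "HZ2", "NZ", "HZ3")
    },
    HIS = {
      if (his_protonated) out$cationic_h <- c("HD1", "HE2")
      out$sc_donors <- dn("ND1", "HD1")
      out$sc_acceptors <- "NE2"
    },
    ASP = out$anionic_o <- c("OD1", "OD2"),
    GLU = out$anionic_o <- c("OE1", "OE2"),
    SER = {
      out$sc_donors <- dn("OG", "HG")
      out$sc_acceptors <- "OG"
    },
    THR = {
      out$sc_donors <- dn("OG1", "HG1")
      out$sc_acceptors <- "OG1"
    },
    TYR = {
      out$sc_donors <- dn("OH", "HH")
      out$sc_acceptors <- "OH"
    },
    ASN = {
      out$sc_donors <- dn("ND2", "HD21", "ND2", "HD22")
      out$sc_acceptors <- "OD1"
    },
    GLN = {
      out$sc_donors <- dn("NE2", "HE21", "NE2", "HE22")
      out$sc_acceptors <- "OE1"
    },
    TRP = out$sc_donors <- dn("NE1", "HE1"),
    CYS = {
      out$sc_donors <- dn("SG", "HG")
      out$sc_acceptors <- "SG"
    },
    MET = out$sc_acceptors <- "SD",
    ALY = {
      # acetyllysine: amide N-H donor, acetyl carbonyl O acceptor
      out$sc_donors <- dn("NZ", "HZ")
      out$sc_acceptors <- "OH"
    },
    NULL
  )
  if (resname %in% c("ASP", "GLU"))
    out$sc_acceptors <- out$anionic_o
  out
}

# one-letter -> three-letter, incl. acetyllysine pseudo-letter used internally
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", k = "ALY")

# backbone donors/acceptors shared by all residues (amide H named "H")
BACKBONE_ACCEPTORS <- c("O", "OXT")
BACKBONE_DONOR <- matrix(c("N", "H"), ncol = 2,
                         dimnames = list(NULL, c("donor", "hydrogen")))

#' Can a substrate residue type form a given interaction with an enzyme residue?
#'
#' Capability feeds the denominator of the low-frequency filter: the mean
#' frequency of an interaction is taken over the peptides whose residue at
#' that substrate position is chemically capable of it. Contacts are always
#' possible; ionic interactions require opposite formal charges; side-chain
#' hydrogen bonds require a complementary donor/acceptor pair; hydrogen bonds
#' to the substrate backbone only require a polar enzyme side chain.
#'
#' @param sub_letter One-letter code of the substrate residue at the position
#'   (lower-case `"k"` for acetyllysine).
#' @param enzyme_resname Three-letter enzyme residue name.
#' @param itype One of `"contact"`, `"hbond_sidechain"`, `"hbond_to_backbone"`,
#'   `"ionic"`.
#' @param his_protonated Treat histidines as protonated?
#' @return Logical scalar.
#' @export
interaction_capable <- function(sub_letter, enzyme_resname, itype,
                                his_protonated = FALSE) {
  if (itype == "contact") return(TRUE)
  sub3 <- AA3[[sub_letter]]
  sub <- residue_chemistry(sub3, his_protonated)
  enz <- residue_chemistry(enzyme_resname, his_protonated)
  switch(itype,
    ionic = (length(sub$cationic_h) > 0 && length(enz$anionic_o) > 0) ||
            (length(enz$cationic_h) > 0 && length(sub$anionic_o) > 0),
    hbond_sidechain =
      (nrow(sub$sc_donors) > 0 && length(enz$sc_acceptors) > 0) ||
      (nrow(enz$sc_donors) > 0 && length(sub$sc_acceptors) > 0),
    hbond_to_backbone =
      nrow(enz$sc_donors) > 0 || length(enz$sc_acceptors) > 0,
    stop("unknown interaction type: ", itype)
  )
}
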