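#' Parse an acetylpeptide sequence
#'
#' Sequences use one-letter codes with the acetyllysine written `K(ac)`,
#' e.g. `"FRK(ac)WR"`. Exactly one acetyllysine is required; it anchors the
#' substrate register, so downstream code addresses residues by signed offset
#' (-2, -1, +1, +2, ...) from it. Panel peptides are synthesized with
#' N-terminal acetylation and C-terminal amidation, which neutralizes both
#' termini; the flags record exceptions (e.g. a native C-terminus).
#'
#' @param sequence Character scalar, e.g. `"FRK(ac)WR"`.
#' @param n_terminal_acetyl,c_terminal_amide Terminal capping flags.
#' @return An object of class `kdac_peptide`: list with `residues`
#'   (one-letter vector, `"k"` at the acetyllysine), `kac_index`, `sequence`,
#'   and the capping flags.
#' @export
#' @examples
#' p <- parse_peptide("FRK(ac)WR")
#' residue_at(p, +1)  # "W"
parse_peptide <- function(sequence, n_terminal_acetyl = TRUE,
                          c_terminal_amide = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- gsub("\\s", "", sequence)
  n_kac <- lengths(regmatches(s, gregexpr("K\\(ac\\)", s)))
  if (n_kac != 1)
    stop("sequence must contain exactly one acetyllysine 'K(ac)': ", sequence)
  s2 <- sub("K\\(ac\\)", "k", s)
  residues <- strsplit(s2, "")[[1]]
  bad <- setdiff(residues, names(AA3))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  structure(list(residues = residues,
                 kac_index = which(residues == "k"),
                 sequence = s,
                 n_terminal_acetyl = n_terminal_acetyl,
                 c_terminal_amide = c_terminal_amide),
            class = "kdac_peptide")
}

#' Residue at a signed offset from the acetyllysine
#'
#' @param peptide A `kdac_peptide` (or a sequence string, parsed on the fly).
#' @param offset Integer offset; 0 is the acetyllysine itself.
#' @return One-letter code, or `NA_character_` if the position does not exist.
#' @export
residue_at <- function(peptide, offset) {
  if (is.character(peptide)) peptide <- parse_peptide(peptide)
  i <- peptide$kac_index + offset
  if (i < 1 || i > length(peptide$residues)) return(NA_character_)
  peptide$residues[i]
}

#' @export
print.kdac_peptide <- function(x, ...) {
  cat("<kdac_peptide> ", x$sequence, "  (acetyllysine at index ",
      x$kac_index, ")\n", sep = "")
  invisible(x)
}
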