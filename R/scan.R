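# Whole-trajectory interaction scanning and replicate aggregation into
# percent-time frequency tables, with the two exclusion rules:
#  (1) an interaction observed only outside catalytically relevant frames in
#      every replicate is excluded ("noncatalytic-only");
#  (2) after truncation, interactions averaging < 1% across the peptides
#      chemically capable of them are excluded ("low-frequency").

ITYPES <- c("contact", "hbond_sidechain", "hbond_to_backbone", "ionic")

record_key <- function(r) {
  paste(r$enzyme_residue$resname, r$enzyme_residue$resno,
        r$substrate_position, r$itype, sep = "|")
}

#' Scan a trajectory for enzyme-substrate interactions
#'
#' For every (enzyme residue, substrate position) pair and interaction type,
#' computes the per-frame occurrence vector: van der Waals contact
#' (any-atom proximity), side-chain/side-chain hydrogen bonds (either
#' donation direction), enzyme-side-chain-to-substrate-backbone hydrogen
#' bonds (either direction), and ionic interactions where charge groups are
#' complementary. Only pairs with at least one occurrence yield a record.
#' Each record also carries the trajectory's per-frame catalytic-relevance
#' mask (Zn-carbonyl distance criterion).
#'
#' @param traj A `kdac_trajectory`.
#' @param criteria An [interaction_criteria()] object.
#' @param positions Integer substrate offsets to scan; default all positions
#'   present except 0 (the acetyllysine itself).
#' @param his_protonated Treat histidines as protonated?
#' @return List of interaction records; each is a list with
#'   `enzyme_residue` (chain/resno/resname), `substrate_position`, `itype`,
#'   `occurrence` and `catalytic_mask` (logical per-frame vectors).
#' @export
scan_interactions <- function(traj, criteria = interaction_criteria(),
                              positions = NULL, his_protonated = FALSE) {
  at <- traj$atoms
  co <- traj$coords
  enz <- unique(at[at$chain == traj$enzyme_chain & at$element != "ZN",
                   c("resno", "resname")])
  if (is.null(positions)) {
    sub_res <- sort(unique(at$resno[at$chain == traj$substrate_chain]))
    positions <- setdiff(sub_res - traj$kac_resno, 0L)
  }
  cmask <- catalytic_mask(traj, criteria)
  records <- list()
  for (ei in seq_len(nrow(enz))) {
    e_resno <- enz$resno[ei]
    e_resname <- enz$resname[ei]
    eidx <- which(at$chain == traj$enzyme_chain & at$resno == e_resno)
    echem <- residue_chemistry(e_resname, his_protonated)
    for (pos in positions) {
      s_resno <- traj$kac_resno + pos
      sidx <- which(at$chain == traj$substrate_chain & at$resno == s_resno)
      if (length(sidx) == 0) next
      s_resname <- at$resname[sidx[1]]
      schem <- residue_chemistry(s_resname, his_protonated)
      eres <- list(chain = traj$enzyme_chain, resno = e_resno,
                   resname = e_resname)
      emit <- function(itype, occ) {
        if (any(occ))
          records[[length(records) + 1]] <<- list(
            enzyme_residue = eres, substrate_position = pos, itype = itype,
            occurrence = occ, catalytic_mask = cmask)
      }
      # contact
      emit("contact", .occ_mindist(co, eidx, sidx, criteria$contact_cutoff))
      # ionic (either polarity)
      ion <- .ionic_occ(co, at, eidx, echem, sidx, schem,
                        criteria$ionic_cutoff)
      if (!is.null(ion)) emit("ionic", ion)
      # hydrogen bonds, side chain <-> side chain (both directions)
      hsc <- .hbond_occ(co, at, eidx, sidx, criteria, his_protonated,
                        donor_scope = "sidechain", acceptor_scope = "sidechain") |
             .hbond_occ(co, at, sidx, eidx, criteria, his_protonated,
                        donor_scope = "sidechain", acceptor_scope = "sidechain")
      emit("hbond_sidechain", hsc)
      # enzyme side chain <-> substrate backbone (both directions)
      hbb <- .hbond_occ(co, at, eidx, sidx, criteria, his_protonated,
                        donor_scope = "sidechain", acceptor_scope = "backbone") |
             .hbond_occ(co, at, sidx, eidx, criteria, his_protonated,
                        donor_scope = "backbone", acceptor_scope = "sidechain")
      emit("hbond_to_backbone", hbb)
    }
  }
  records
}

.ionic_occ <- function(co, at, idx_a, chem_a, idx_b, chem_b, cutoff) {
  occ <- NULL
  pair <- function(h_chem, h_idx, o_chem, o_idx) {
    hs <- h_idx[at$name[h_idx] %in% h_chem$cationic_h]
    os <- o_idx[at$name[o_idx] %in% o_chem$anionic_o]
    if (length(hs) && length(os))
      .occ_mindist(co, hs, os, cutoff) else NULL
  }
  for (o in list(pair(chem_a, idx_a, chem_b, idx_b),
                 pair(chem_b, idx_b, chem_a, idx_a)))
    if (!is.null(o)) occ <- if (is.null(occ)) o else occ | o
  occ
}

.hbond_occ <- function(co, at, don_idx, acc_idx, criteria, his_protonated,
                       donor_scope, acceptor_scope) {
  nf <- dim(co)[3]
  occ <- rep(FALSE, nf)
  don_atoms <- at[don_idx, ]
  pairs <- donor_pairs(don_atoms, his_protonated, scope = donor_scope)
  if (nrow(pairs) == 0) return(occ)
  acc_atoms <- at[acc_idx, ]
  chem <- residue_chemistry(acc_atoms$resname[1], his_protonated)
  acc_names <- if (acceptor_scope == "sidechain") chem$sc_acceptors
               else BACKBONE_ACCEPTORS
  a_is <- acc_idx[at$name[acc_idx] %in% acc_names]
  if (length(a_is) == 0) return(occ)
  for (i in seq_len(nrow(pairs))) {
    d_i <- don_idx[match(pairs[i, "donor"], at$name[don_idx])]
    h_i <- don_idx[match(pairs[i, "hydrogen"], at$name[don_idx])]
    for (a_i in a_is)
      occ <- occ | .occ_hbond_triple(co, d_i, h_i, a_i,
                                     criteria$hbond_heavy_cutoff,
                                     criteria$hbond_angle_max)
  }
  occ
}

#' Aggregate interaction records across replicates into a frequency table
#'
#' Per interaction key, the percent time is computed within each replicate
#' (100 x occurrences / frames; replicates lacking the record contribute 0),
#' averaged over all replicates, then truncated toward zero to an integer
#' percent. Keys flooring to 0 are dropped, which realizes the 1% lower
#' limit of reported frequencies. Keys whose occurrences fall entirely in
#' non-catalytic frames in every replicate are moved to the exclusion set
#' with reason `"noncatalytic-only"` before truncation.
#'
#' @param records_by_replicate List (one element per replicate) of record
#'   lists from [scan_interactions()].
#' @param peptide Optional `kdac_peptide` the table belongs to.
#' @return A `kdac_freqtable`: list with `entries` (data frame: resname,
#'   resno, position, itype, percent_raw, percent), `excluded` (same keys
#'   plus `reason`), `replicate_count`.
#' @export
aggregate_frequencies <- function(records_by_replicate, peptide = NULL) {
  stopifnot(length(records_by_replicate) >= 1)
  R <- length(records_by_replicate)
  info <- list()
  for (r in seq_len(R)) {
    recs <- records_by_replicate[[r]]
    for (rec in recs) {
      nf <- length(rec$occurrence)
      if (nf == 0) stop("zero-frame replicate")
      k <- record_key(rec)
      if (is.null(info[[k]]))
        info[[k]] <- list(rec = rec, pct = numeric(R), cat = logical(R))
      info[[k]]$pct[r] <- 100 * sum(rec$occurrence) / nf
      info[[k]]$cat[r] <- any(rec$occurrence & rec$catalytic_mask)
    }
  }
  row_of <- function(k, v, extra) {
    rec <- v$rec
    data.frame(resname = rec$enzyme_residue$resname,
               resno = rec$enzyme_residue$resno,
               position = rec$substrate_position, itype = rec$itype,
               extra, stringsAsFactors = FALSE)
  }
  entries <- list(); excluded <- list()
  for (k in names(info)) {
    v <- info[[k]]
    raw <- mean(v$pct)
    if (!any(v$cat)) {
      excluded[[k]] <- row_of(k, v, data.frame(percent_raw = raw,
                                               reason = "noncatalytic-only"))
    } else {
      pct <- trunc(raw)
      if (pct >= 1)
        entries[[k]] <- row_of(k, v, data.frame(percent_raw = raw,
                                                percent = as.integer(pct)))
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, unname(l)) else proto
  entries <- bind(entries, data.frame(resname = character(), resno = integer(),
                                      position = integer(), itype = character(),
                                      percent_raw = numeric(),
                                      percent = integer()))
  excluded <- bind(excluded, data.frame(resname = character(),
                                        resno = integer(),
                                        position = integer(),
                                        itype = character(),
                                        percent_raw = numeric(),
                                        reason = character()))
  o <- order(entries$resno, entries$position, entries$itype)
  structure(list(entries = entries[o, , drop = FALSE],
                 excluded = excluded, replicate_count = R,
                 peptide = peptide),
            class = "kdac_freqtable")
}

#' @export
print.kdac_freqtable <- function(x, ...) {
  cat("<kdac_freqtable> ", nrow(x$entries), " retained interactions, ",
      nrow(x$excluded), " excluded, ", x$replicate_count, " replicates\n",
      sep = "")
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  invisible(x)
}

freqtable_lookup <- function(tab, resno, position, itype) {
  e <- tab$entries
  hit <- e$resno == resno & e$position == position & e$itype == itype
  if (any(hit)) e$percent_raw[which(hit)[1]] else 0
}

#' Exclude low-frequency interactions across a peptide panel
#'
#' An interaction key (enzyme residue, substrate position, type) is retained
#' only if its mean pre-truncation frequency, taken over the peptides whose
#' residue at that position is chemically capable of the interaction, is at
#' least 1%. Incapable peptides do not enter the mean's denominator; a single
#' capable peptide with a frequency above the threshold is sufficient to
#' keep the key. Removed keys move to each table's exclusion set with reason
#' `"low-frequency"`.
#'
#' @param tables_by_peptide Named list of `kdac_freqtable` (names = peptide
#'   sequences); each table should carry its `peptide`.
#' @param his_protonated Treat histidines as protonated?
#' @return The filtered list of tables.
#' @export
apply_low_frequency_filter <- function(tables_by_peptide,
                                       his_protonated = FALSE) {
  all_keys <- unique(do.call(rbind, lapply(unname(tables_by_peptide),
    function(t) t$entries[c("resname", "resno", "position", "itype")])))
  if (is.null(all_keys) || nrow(all_keys) == 0) return(tables_by_peptide)
  for (i in seq_len(nrow(all_keys))) {
    k <- all_keys[i, ]
    vals <- c()
    for (nm in names(tables_by_peptide)) {
      tab <- tables_by_peptide[[nm]]
      pep <- tab$peptide %||% parse_peptide(nm)
      letter <- residue_at(pep, k$position)
      if (is.na(letter)) next                     # position absent
      if (!interaction_capable(letter, k$resname, k$itype, his_protonated))
        next
      vals <- c(vals, freqtable_lookup(tab, k$resno, k$position, k$itype))
    }
    if (length(vals) == 0 || mean(vals) >= 1) next
    for (nm in names(tables_by_peptide)) {
      tab <- tables_by_peptide[[nm]]
      e <- tab$entries
      hit <- e$resno == k$resno & e$position == k$position &
             e$itype == k$itype
      if (any(hit)) {
        drop <- e[hit, , drop = FALSE]
        tab$excluded <- rbind(tab$excluded,
          data.frame(resname = drop$resname, resno = drop$resno,
                     position = drop$position, itype = drop$itype,
                     percent_raw = drop$percent_raw,
                     reason = "low-frequency"))
        tab$entries <- e[!hit, , drop = FALSE]
        tables_by_peptide[[nm]] <- tab
      }
    }
  }
  tables_by_peptide
}

#' Binding-site occupancy fractions from contact records
#'
#' Classifies each frame by whether the +1 substrate residue is
#' simultaneously in contact with all residues of `site_def_p1` and the +2
#' residue with all of `site_def_p2`, then returns the fractions of frames
#' with dual occupancy, occupancy by exactly one position, and neither.
#' The three fractions sum to 1.
#'
#' @param records Record list from [scan_interactions()] (contact records
#'   are used; a site residue with no contact record counts as never in
#'   contact).
#' @param site_def_p1,site_def_p2 Integer vectors of enzyme residue numbers
#'   defining the pocket for the +1 and +2 positions.
#' @return Named numeric vector `c(dual, single, none)`.
#' @export
compute_occupancy <- function(records, site_def_p1, site_def_p2) {
  if (length(site_def_p1) == 0 || length(site_def_p2) == 0)
    stop("empty site definition")
  nf <- length(records[[1]]$occurrence)
  occ_of <- function(resno, pos) {
    for (r in records)
      if (r$itype == "contact" && r$enzyme_residue$resno == resno &&
          r$substrate_position == pos) return(r$occurrence)
    rep(FALSE, nf)
  }
  all_contact <- function(site, pos)
    Reduce(`&`, lapply(site, occ_of, pos = pos), rep(TRUE, nf))
  p1 <- all_contact(site_def_p1, 1L)
  p2 <- all_contact(site_def_p2, 2L)
  c(dual = mean(p1 & p2), single = mean(xor(p1, p2)),
    none = mean(!p1 & !p2))
}
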