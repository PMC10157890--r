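# Seeded generators for every input the pipeline consumes: toy
# enzyme-peptide trajectories with planted two-state (Markov) interaction
# episodes and catalytic-pose excursions, activity panels with planted
# multiplicative cluster effects, and Michaelis-Menten timecourses.
# The scaffold geometry is deliberately schematic: enzyme anchors sit on a
# 1.5 nm grid around a substrate threaded past a fixed Zn site. Realism is
# not the goal; what matters is that the planted episodes are detectable by
# the geometric criteria with known ground truth. Occurrence follows a
# two-state Markov chain (not i.i.d. draws) so that frame-to-frame
# autocorrelation, as in real trajectories, is present.

#' Describe a planted interaction
#'
#' @param enzyme_resno Enzyme residue number to create.
#' @param substrate_position Signed offset from the acetyllysine.
#' @param itype Interaction type to plant (`"contact"`, `"ionic"`,
#'   `"hbond_sidechain"`, `"hbond_to_backbone"`).
#' @param p_on,p_off Per-frame Markov transition probabilities
#'   (off->on, on->off); stationary occupancy is
#'   `p_on / (p_on + p_off)`.
#' @param enzyme_resname Enzyme residue type; defaults to a chemistry able
#'   to form `itype` (ALA for contact, ARG/ASP for ionic depending on the
#'   substrate charge, SER for hydrogen bonds).
#' @return A `kdac_planted` list, with `stationary` occupancy.
#' @export
planted_interaction <- function(enzyme_resno, substrate_position, itype,
                                p_on, p_off, enzyme_resname = NULL) {
  stopifnot(p_on > 0, p_on < 1, p_off > 0, p_off < 1,
            itype %in% ITYPES)
  structure(list(enzyme_resno = as.integer(enzyme_resno),
                 substrate_position = as.integer(substrate_position),
                 itype = itype, p_on = p_on, p_off = p_off,
                 enzyme_resname = enzyme_resname,
                 stationary = p_on / (p_on + p_off)),
            class = "kdac_planted")
}

# two-state Markov chain; initial state from the stationary distribution
simulate_two_state <- function(n, p_on, p_off) {
  f <- p_on / (p_on + p_off)
  s <- logical(n)
  u <- stats::runif(n)
  s[1] <- u[1] < f
  for (i in 2:n)
    s[i] <- if (s[i - 1]) u[i] >= p_off else u[i] < p_on
  s
}

# substrate-position anchor (nm): threaded along z past the Zn site
.sub_anchor <- function(pos) c(0, 0, 1.5 * pos)

# per-planted-interaction approach direction, in the y-z plane so that the
# backbone-O offset (along x) never shortcuts the controlled distance;
# kept within +/-30 degrees of +y so probes never stray toward the
# neighbouring substrate positions (1.5 nm apart along z)
.approach_dir <- function(i) {
  thetas <- seq(-30, 30, length.out = 9) * pi / 180
  theta <- thetas[((i - 1) %% 9) + 1]
  c(0, cos(theta), sin(theta))
}

# substrate residue atoms for one-letter code; anchor = CA position.
# Only the atoms the detectors look at are materialized.
.substrate_atoms <- function(letter, anchor) {
  # backbone O offset 0.25 nm along x so hydrogen bonds planted on the side
  # chain cannot satisfy the backbone geometry and vice versa
  nm <- c("CA", "O"); xyz <- rbind(anchor, anchor + c(0.25, 0, 0))
  add <- function(names, offsets) {
    nm <<- c(nm, names)
    xyz <<- rbind(xyz, sweep(offsets, 2, anchor, `+`))
  }
  switch(letter,
    D = add(c("OD1", "OD2"), rbind(c(0, 0, 0) * 0, c(-0.12, 0, 0))),
    E = add(c("OE1", "OE2"), rbind(c(0, 0, 0) * 0, c(-0.12, 0, 0))),
    R = add(c("NH1", "HH11"), rbind(c(-0.10, 0, 0), c(0, 0, 0) * 0)),
    K = add(c("NZ", "HZ1"), rbind(c(-0.10, 0, 0), c(0, 0, 0) * 0)),
    N = add("OD1", rbind(c(0, 0, 0) * 0)),
    Q = add("OE1", rbind(c(0, 0, 0) * 0)),
    Y = add("OH", rbind(c(0, 0, 0) * 0)),
    S = add("OG", rbind(c(0, 0, 0) * 0)),
    T = add("OG1", rbind(c(0, 0, 0) * 0)),
    NULL)
  list(names = nm, xyz = xyz)
}

#' Generate a synthetic enzyme-peptide trajectory
#'
#' Builds a toy complex and simulates `n_frames` frames. Each planted
#' interaction follows its own two-state Markov chain; in "on" frames the
#' relevant probe geometry satisfies the corresponding detector (contact:
#' enzyme probe at U(0.20, 0.29) nm from the substrate anchor; ionic: H-O
#' at U(0.18, 0.24); hydrogen bond: collinear D-H-A with |D-A| at
#' U(0.28, 0.34)), and in "off" frames it does not (U(0.40, 0.80),
#' U(0.30, 0.60), and a 45-degree bent geometry at 0.30 nm respectively).
#' The Zn-to-acetyl-carbonyl distance follows its own chain: U(0.28, 0.31)
#' in catalytically relevant frames, U(0.33, 0.50) otherwise. Identical
#' seeds give identical trajectories (and identical written files).
#'
#' @param planted List of [planted_interaction()] objects; enzyme residue
#'   numbers must be distinct.
#' @param n_frames Frames to simulate (default 2500, i.e. 5 ns at one frame
#'   per 2 ps).
#' @param catalytic_p_on,catalytic_p_off Transition probabilities of the
#'   catalytic-pose chain (defaults give 90% stationary catalytic fraction).
#' @param seed Integer seed; all randomness derives from it.
#' @param peptide Substrate sequence (default `"FRK(ac)WR"`).
#' @param replicate_id Replicate label stored on the trajectory.
#' @return A `kdac_trajectory` (enzyme chain `"A"`, substrate chain `"B"`).
#' @export
generate_trajectory <- function(planted, n_frames = 2500,
                                catalytic_p_on = 0.18,
                                catalytic_p_off = 0.02,
                                seed = 1, peptide = "FRK(ac)WR",
                                replicate_id = 1L) {
  if (is.character(peptide)) peptide <- parse_peptide(peptide)
  pep_len <- length(peptide$residues)
  kac_resno <- peptide$kac_index
  resnos <- vapply(planted, `[[`, 0L, "enzyme_resno")
  if (anyDuplicated(resnos))
    stop("spec error: each planted interaction needs its own enzyme residue")
  for (p in planted) {
    idx <- kac_resno + p$substrate_position
    if (idx < 1 || idx > pep_len)
      stop("spec error: substrate position ", p$substrate_position,
           " outside peptide")
  }
  set.seed(as.integer(seed))

  name <- character(0); resname <- character(0); chain <- character(0)
  resno <- integer(0); static_xyz <- list()
  add_atom <- function(nm, rn, ch, no, xyz = NULL) {
    name <<- c(name, nm); resname <<- c(resname, rn)
    chain <<- c(chain, ch); resno <<- c(resno, as.integer(no))
    static_xyz[[length(static_xyz) + 1]] <<- list(xyz)  # list(NULL) = dynamic
    length(name)
  }

  # substrate chain B
  sub_letters <- peptide$residues
  for (i in seq_len(pep_len)) {
    pos <- i - kac_resno
    anchor <- .sub_anchor(pos)
    if (sub_letters[i] == "k") {
      add_atom("CA", "ALY", "B", i, anchor)
      add_atom("CH", "ALY", "B", i, anchor + c(0.15, 0, 0))
      kac_o_i <- add_atom("OH", "ALY", "B", i)          # dynamic (Zn chain)
    } else {
      at <- .substrate_atoms(sub_letters[i], anchor)
      for (j in seq_along(at$names))
        add_atom(at$names[j], AA3[[sub_letters[i]]], "B", i, at$xyz[j, ])
    }
  }
  # Zn ion on the enzyme chain
  zn_pos <- c(0.30, 0, 0)
  add_atom("ZN", "ZN", "A", 999L, zn_pos)

  # enzyme residues: CA anchor fixed, probe atoms dynamic
  probes <- list()
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    sub_idx <- kac_resno + p$substrate_position
    sub_letter <- sub_letters[sub_idx]
    u <- .approach_dir(i)
    anchor <- .sub_anchor(p$substrate_position)
    rn <- p$enzyme_resname %||% switch(p$itype,
      contact = "ALA",
      ionic = if (sub_letter %in% c("D", "E")) "ARG" else "ASP",
      hbond_sidechain = "SER", hbond_to_backbone = "SER")
    ok <- switch(p$itype,
      contact = TRUE,
      ionic = sub_letter %in% c("D", "E", "R", "K"),
      hbond_sidechain = sub_letter %in% c("D", "E", "N", "Q", "S", "T", "Y"),
      hbond_to_backbone = TRUE)
    if (!ok || (p$itype != "contact" &&
                !interaction_capable(sub_letter, rn, p$itype)))
      stop("spec error: substrate residue ", sub_letter,
           " cannot form a detectable ", p$itype, " in the toy scaffold")
    add_atom("CA", rn, "A", p$enzyme_resno, anchor + 1.5 * u)
    pr <- list(planted = p, u = u, resname = rn, anchor = anchor,
               sub_idx = sub_idx)
    if (p$itype == "contact") {
      pr$atom_idx <- add_atom("CB", rn, "A", p$enzyme_resno)
      pr$target <- anchor
    } else if (p$itype == "ionic") {
      if (rn == "ARG") {
        pr$atom_idx <- c(H = add_atom("HH11", rn, "A", p$enzyme_resno),
                         N = add_atom("NH1", rn, "A", p$enzyme_resno))
        # target: substrate anionic oxygen at its anchor
        pr$target <- anchor
      } else {
        pr$atom_idx <- c(O = add_atom("OD1", rn, "A", p$enzyme_resno))
        pr$target <- anchor   # substrate cationic H sits at the anchor
      }
    } else {
      pr$atom_idx <- c(D = add_atom("OG", rn, "A", p$enzyme_resno),
                       H = add_atom("HG", rn, "A", p$enzyme_resno))
      pr$target <- if (p$itype == "hbond_to_backbone")
        anchor + c(0.25, 0, 0) else anchor   # backbone O vs side-chain acc.
    }
    probes[[i]] <- pr
  }

  n_atoms <- length(name)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (a in seq_len(n_atoms))
    if (!is.null(static_xyz[[a]][[1]]))
      coords[a, , ] <- static_xyz[[a]][[1]]

  # catalytic-pose chain drives the acetyl carbonyl oxygen
  cat_state <- simulate_two_state(n_frames, catalytic_p_on, catalytic_p_off)
  dzn <- ifelse(cat_state, 0.28 + 0.03 * stats::runif(n_frames),
                           0.33 + 0.17 * stats::runif(n_frames))
  coords[kac_o_i, 1, ] <- zn_pos[1] - dzn
  coords[kac_o_i, 2, ] <- 0
  coords[kac_o_i, 3, ] <- 0

  # planted interaction chains drive the probe atoms
  perp <- c(1, 0, 0)   # perpendicular to every approach direction
  for (pr in probes) {
    p <- pr$planted
    state <- simulate_two_state(n_frames, p$p_on, p$p_off)
    uu <- stats::runif(n_frames)
    place <- function(idx, xyz) for (d in 1:3) coords[idx, d, ] <<- xyz[d, ]
    if (p$itype == "contact") {
      dist <- ifelse(state, 0.20 + 0.09 * uu, 0.40 + 0.40 * uu)
      place(pr$atom_idx, outer(pr$u, dist) + pr$target)
    } else if (p$itype == "ionic") {
      dist <- ifelse(state, 0.18 + 0.06 * uu, 0.30 + 0.30 * uu)
      probe_xyz <- outer(pr$u, dist) + pr$target
      if (pr$resname == "ARG") {
        place(pr$atom_idx["H"], probe_xyz)
        place(pr$atom_idx["N"], outer(pr$u, dist + 0.10) + pr$target)
      } else {
        place(pr$atom_idx["O"], probe_xyz)
      }
    } else {
      r_on <- 0.28 + 0.06 * uu
      # on: D at distance r along u from the acceptor, H collinear toward A
      D_on <- outer(pr$u, r_on) + pr$target
      H_on <- outer(pr$u, r_on - 0.10) + pr$target
      # off: |D-A| = 0.30 but H bent 45 degrees away from the D->A axis
      v45 <- -pr$u * cos(pi / 4) + perp * sin(pi / 4)
      D_off <- outer(pr$u, rep(0.30, n_frames)) + pr$target
      H_off <- D_off + 0.10 * v45
      sel <- rep(state, each = 3)
      D <- D_on; D[!sel] <- D_off[!sel]
      H <- H_on; H[!sel] <- H_off[!sel]
      place(pr$atom_idx["D"], D)
      place(pr$atom_idx["H"], H)
    }
  }

  atoms <- data.frame(serial = seq_len(n_atoms), name = name,
                      resname = resname, chain = chain, resno = resno,
                      element = infer_element(name),
                      stringsAsFactors = FALSE)
  atoms$is_hydrogen <- atoms$element == "H"
  new_trajectory(atoms, coords, enzyme_chain = "A", substrate_chain = "B",
                 kac_resno = kac_resno, peptide = peptide,
                 replicate_id = replicate_id)
}

#' Generate a synthetic activity panel with planted cluster effects
#'
#' Per replicate, log activity = log(baseline) + sum of log effects of the
#' clusters containing the peptide + N(0, noise_sd_log^2). Deterministic
#' under `seed`.
#'
#' @param peptides Character vector of sequences.
#' @param baseline Baseline specific activity, 1/s (default 0.02, mid-range
#'   for these panels).
#' @param cluster_effects List of `list(position=, residues=, effect=)`;
#'   a peptide receives the multiplicative `effect` when its residue at
#'   `position` is in `residues`.
#' @param noise_sd_log SD of log-activity noise (default 0.2, ~20% CV as
#'   typical of replicate endpoint assays).
#' @param replicates Replicates per peptide (default 4).
#' @param seed Integer seed.
#' @param enzyme Enzyme label.
#' @param detection_limit Detection limit passed to the records.
#' @return List of `kdac_activity` records with replicate values.
#' @export
generate_activity_panel <- function(peptides, baseline = 0.02,
                                    cluster_effects = list(),
                                    noise_sd_log = 0.2, replicates = 4L,
                                    seed = 1, enzyme = "KDAC",
                                    detection_limit = 0) {
  stopifnot(replicates >= 1)
  for (ce in cluster_effects) stopifnot(ce$effect > 0)
  set.seed(as.integer(seed))
  lapply(peptides, function(s) {
    pep <- parse_peptide(s)
    lmu <- log(baseline)
    for (ce in cluster_effects) {
      r <- residue_at(pep, ce$position)
      if (!is.na(r) && r %in% ce$residues) lmu <- lmu + log(ce$effect)
    }
    vals <- exp(lmu + stats::rnorm(replicates, 0, noise_sd_log))
    activity_record(pep, enzyme = enzyme, replicates = vals,
                    detection_limit = detection_limit)
  })
}

#' Generate Michaelis-Menten timecourses
#'
#' Product formed is v0 * t * (1 + eps), eps ~ N(0, noise_sd^2) i.i.d. per
#' point, with v0 from the Michaelis-Menten equation. Default
#' concentrations span 0.1x-10x K_M.
#'
#' @param K_M Michaelis constant, uM.
#' @param k_cat Turnover number, 1/s.
#' @param enzyme_conc Enzyme concentration, nM.
#' @param concentrations Substrate concentrations, uM; the default is a
#'   ten-point dilution series spanning 0.1x-10x K_M, as in plate-based
#'   steady-state assays.
#' @param timepoints Sampling times, seconds (default 3-40 min).
#' @param noise_sd Fractional noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame with `conc`, `time`, `product` (uM).
#' @export
generate_timecourses <- function(K_M, k_cat, enzyme_conc,
                                 concentrations = K_M *
                                   c(0.1, 0.2, 0.33, 0.5, 0.75,
                                     1, 1.5, 2.5, 5, 10),
                                 timepoints = c(180, 600, 1200, 2400),
                                 noise_sd = 0, seed = 1) {
  set.seed(as.integer(seed))
  E <- enzyme_conc * 1e-3
  grid <- expand.grid(time = timepoints, conc = concentrations)
  v0 <- k_cat * E * grid$conc / (K_M + grid$conc)
  eps <- if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  data.frame(conc = grid$conc, time = grid$time,
             product = v0 * grid$time * (1 + eps))
}
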