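# Independent brute-force oracles and fixture builders. The oracles use
# their own hard-coded atom dictionaries and explicit double loops so they
# share no code path with the package's detectors.

# ---- brute-force geometric oracles ---------------------------------------

oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

frame_xyz <- function(frame, sel) {
  as.matrix(frame[sel, c("x", "y", "z"), drop = FALSE])
}

oracle_contact <- function(frame, chain_a, resno_a, chain_b, resno_b,
                           cutoff = 0.30) {
  a <- frame_xyz(frame, frame$chain == chain_a & frame$resno == resno_a)
  b <- frame_xyz(frame, frame$chain == chain_b & frame$resno == resno_b)
  oracle_min_dist(a, b) <= cutoff
}

# guanidinium hydrogens / carboxylate oxygens, hard-coded
ORACLE_CATIONIC_H <- c(ARG = "HE HH11 HH12 HH21 HH22", LYS = "HZ1 HZ2 HZ3")
ORACLE_ANIONIC_O <- c(ASP = "OD1 OD2", GLU = "OE1 OE2")

oracle_ionic <- function(frame, cat_chain, cat_resno, ani_chain, ani_resno,
                         cutoff = 0.25) {
  csel <- frame$chain == cat_chain & frame$resno == cat_resno
  asel <- frame$chain == ani_chain & frame$resno == ani_resno
  hn <- strsplit(ORACLE_CATIONIC_H[[frame$resname[csel][1]]], " ")[[1]]
  on <- strsplit(ORACLE_ANIONIC_O[[frame$resname[asel][1]]], " ")[[1]]
  hs <- frame_xyz(frame, csel & frame$name %in% hn)
  os <- frame_xyz(frame, asel & frame$name %in% on)
  for (i in seq_len(nrow(hs))) for (j in seq_len(nrow(os)))
    if (sqrt(sum((hs[i, ] - os[j, ])^2)) <= cutoff) return(TRUE)
  FALSE
}

# explicit vector-arithmetic angle check for one D/H donor and a set of
# acceptor atom names
oracle_hbond <- function(frame, don_chain, don_resno, d_name, h_name,
                         acc_chain, acc_resno, acc_names,
                         dist_cutoff = 0.35, angle_max = 30) {
  dsel <- frame$chain == don_chain & frame$resno == don_resno
  D <- as.numeric(frame_xyz(frame, dsel & frame$name == d_name)[1, ])
  H <- as.numeric(frame_xyz(frame, dsel & frame$name == h_name)[1, ])
  asel <- frame$chain == acc_chain & frame$resno == acc_resno &
    frame$name %in% acc_names
  A <- frame_xyz(frame, asel)
  for (j in seq_len(nrow(A))) {
    a <- as.numeric(A[j, ])
    dda <- sqrt(sum((a - D)^2))
    if (dda > dist_cutoff) next
    v1 <- H - D; v2 <- a - D
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
    if (ang * 180 / pi <= angle_max) return(TRUE)
  }
  FALSE
}

# ---- statistical oracles --------------------------------------------------

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n, n1)
  u_all <- apply(combos, 2, function(idx)
    sum(seq_len(n)[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by explicit enumeration over the margin-constrained
# table family, probabilities from binomial coefficients
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, k - x) / choose(n, k)
  xs <- max(0, k - r2):min(k, r1)
  ps <- vapply(xs, prob, 0)
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# ---- fixture builders -----------------------------------------------------

# minimal hand-built trajectory: enzyme chain A with an ARG (cationic,
# donor) and a SER (donor/acceptor), substrate chain B with a GLU (anionic,
# acceptor) at +1 and the acetyllysine at 0; atom coordinates supplied or
# randomized per frame. Returns a kdac_trajectory.
toy_atoms <- function() {
  data.frame(
    serial = 1:13,
    name = c("CA", "NH1", "HH11", "HH12",      # ARG 101 (A)
             "CA", "OG", "HG",                 # SER 102 (A)
             "ZN",                             # Zn    (A)
             "CA", "O", "OE1", "OE2",          # GLU +1 (B, resno 2)
             "OH"),                            # ALY 0  (B, resno 1)
    resname = c(rep("ARG", 4), rep("SER", 3), "ZN",
                rep("GLU", 4), "ALY"),
    chain = c(rep("A", 8), rep("B", 5)),
    resno = c(rep(101L, 4), rep(102L, 3), 999L, rep(2L, 4), 1L),
    element = c("C", "N", "H", "H", "C", "O", "H", "ZN",
                "C", "O", "O", "O", "O"),
    is_hydrogen = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

toy_trajectory <- function(coords) {
  kdacselect:::new_trajectory(toy_atoms(), coords, enzyme_chain = "A",
                              substrate_chain = "B", kac_resno = 1L,
                              peptide = parse_peptide("K(ac)E"))
}

# random frames in a 1 nm box (interactions occur often enough to exercise
# both branches of every detector)
random_toy_trajectory <- function(n_frames, seed) {
  set.seed(seed)
  coords <- array(runif(13 * 3 * n_frames, 0, 1), c(13, 3, n_frames))
  toy_trajectory(coords)
}

# a bare interaction record for aggregation tests
make_record <- function(resno, resname, pos, itype, occ,
                        cmask = rep(TRUE, length(occ))) {
  list(enzyme_residue = list(chain = "A", resno = as.integer(resno),
                             resname = resname),
       substrate_position = as.integer(pos), itype = itype,
       occurrence = occ, catalytic_mask = cmask)
}

# occurrence vector with exactly k TRUE entries out of n (prefix placement)
occ_frac <- function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))

# hand-built frequency table (white-box constructor for statistics tests)
make_freqtable <- function(entries, peptide, replicate_count = 5L) {
  structure(list(entries = entries,
                 excluded = data.frame(),
                 replicate_count = replicate_count,
                 peptide = parse_peptide(peptide)),
            class = "kdac_freqtable")
}

fixture_path <- function(name)
  system.file("extdata", name, package = "kdacselect")

# the 16-peptide derivative panel (x at +1, y at +2 over {W,A,R,E})
derivative_panel_sequences <- function() {
  combos <- expand.grid(p1 = c("W", "A", "R", "E"),
                        p2 = c("W", "A", "R", "E"))
  sprintf("FRK(ac)%s%s", combos$p1, combos$p2)
}
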