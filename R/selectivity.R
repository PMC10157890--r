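# Cluster-based association of interaction frequencies with deacetylation
# activity. Stage 1: pooled two-sample t-tests of interaction frequency,
# cluster members vs non-members, Bonferroni-corrected over the whole family
# (p <= 0.01). Stage 2: Mann-Whitney U on activity for stage-1 significant
# clusters (p <= 0.05); a ranked test limits the influence of the other
# substrate position. Frame co-occurrence uses a log-space two-sided
# Fisher's exact test so extreme associations (p ~ 1e-131) stay finite.

#' Enumerate substrate clusters
#'
#' Builds all clusters of panel peptides sharing one or two particular
#' residues at one substrate position. A cluster with no members or no
#' non-members is flagged untestable.
#'
#' @param peptides Character vector of peptide sequences (acetyllysine
#'   written `K(ac)`), or list of `kdac_peptide`.
#' @param alphabet Candidate residues (one-letter codes).
#' @param positions Substrate offsets to cluster on.
#' @return List of `kdac_cluster` objects: `position`, `residues`,
#'   `members`, `nonmembers` (peptide sequences), `testable`, `id`.
#' @export
enumerate_clusters <- function(peptides, alphabet = c("A", "E", "R", "W", "Y"),
                               positions = c(1L, 2L)) {
  stopifnot(length(alphabet) >= 1)
  peps <- lapply(peptides, function(p)
    if (is.character(p)) parse_peptide(p) else p)
  seqs <- vapply(peps, `[[`, "", "sequence")
  subsets <- c(lapply(alphabet, identity),
               if (length(alphabet) >= 2) combn(alphabet, 2, simplify = FALSE))
  clusters <- list()
  for (pos in positions) {
    at_pos <- vapply(peps, residue_at, "", offset = pos)
    for (rs in subsets) {
      members <- seqs[!is.na(at_pos) & at_pos %in% rs]
      nonmembers <- setdiff(seqs, members)
      clusters[[length(clusters) + 1]] <- structure(
        list(position = as.integer(pos), residues = rs,
             members = members, nonmembers = nonmembers,
             testable = length(members) > 0 && length(nonmembers) > 0,
             id = paste0(ifelse(pos > 0, paste0("+", pos), pos), ":",
                         paste(rs, collapse = ""))),
        class = "kdac_cluster")
    }
  }
  clusters
}

# pooled-variance two-sample t; degenerate variance handled explicitly
pooled_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 < .Machine$double.eps^2) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1, df = n1 + n2 - 2))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = .Machine$double.xmin,
                df = n1 + n2 - 2))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Cluster interaction t-test
#'
#' Pooled-variance two-sided t-test of one interaction's frequencies,
#' cluster members versus non-members. Peptides absent from `freqs` count
#' as frequency 0 (the interaction was not observed for them).
#'
#' @param cluster A `kdac_cluster`.
#' @param freqs Named numeric vector: peptide sequence -> frequency (%)
#'   for one (enzyme residue, interaction type).
#' @return List with `t_statistic`, `p_raw`, `df`, `cluster`.
#' @export
cluster_interaction_ttest <- function(cluster, freqs) {
  get0s <- function(nms) {
    v <- freqs[nms]
    v[is.na(v)] <- 0
    unname(v)
  }
  if (length(cluster$members) < 2 || length(cluster$nonmembers) < 2)
    stop("cluster needs >= 2 members and >= 2 nonmembers for a t-test")
  r <- pooled_ttest(get0s(cluster$members), get0s(cluster$nonmembers))
  list(cluster = cluster, t_statistic = r$t, p_raw = r$p, df = r$df)
}

#' Mann-Whitney U test of cluster activity
#'
#' Two-sided Mann-Whitney U comparing activities of cluster members against
#' non-members: exact (via the null U distribution) when the smaller group
#' has at most 8 observations and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction. Direction is
#' read from the median difference.
#'
#' @param cluster A `kdac_cluster`.
#' @param activities Named numeric vector: peptide sequence -> normalized
#'   activity. Peptides without activity are dropped.
#' @return List with `U_statistic`, `p_value`, `direction`
#'   (`"enhanced"`/`"inhibited"`/`"none"`), `exact`, `cluster`.
#' @export
cluster_activity_mwu <- function(cluster, activities) {
  x <- activities[intersect(cluster$members, names(activities))]
  y <- activities[intersect(cluster$nonmembers, names(activities))]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("cluster needs >= 1 member and >= 1 nonmember with activity")
  r <- mwu_test(as.numeric(x), as.numeric(y))
  dmed <- stats::median(x) - stats::median(y)
  direction <- if (dmed > 0) "enhanced" else if (dmed < 0) "inhibited"
               else "none"
  c(r, list(direction = direction, cluster = cluster))
}

#' Two-sided Mann-Whitney U test
#'
#' @param x,y Numeric samples.
#' @return List with `U_statistic` (for `x`), `p_value`, `exact`.
#' @export
mwu_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8 && !ties) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U_statistic = U, p_value = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U_statistic = U, p_value = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)   # continuity correction
  list(U_statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table, in log space
#'
#' Sums hypergeometric probabilities of all tables (at the observed margins)
#' no more probable than the observed one — the standard two-sided
#' convention. Computed with log-probabilities so p-values far below double
#' underflow in intermediate terms (e.g. 1e-131) remain exact; `log10_p` is
#' finite even when `p_value` underflows to 0.
#'
#' @param a,b,c,d Cell counts: rows are condition present/absent, columns
#'   outcome present/absent.
#' @return List with `p_value`, `log10_p`, `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margin in 2x2 table; p = 1")
    return(list(p_value = 1, log10_p = 0,
                table = matrix(c(a, b, c, d), 2, byrow = TRUE)))
  }
  xs <- max(0, k - r2):min(k, r1)
  lp <- stats::dhyper(xs, r1, r2, k, log = TRUE)
  lp_obs <- stats::dhyper(a, r1, r2, k, log = TRUE)
  keep <- lp <= lp_obs + 1e-7             # relative tolerance, as fisher.test
  m <- max(lp[keep])
  logp <- m + log(sum(exp(lp[keep] - m)))
  logp <- min(0, logp)
  list(p_value = exp(logp), log10_p = logp / log(10),
       table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("yes", "no"), c("yes", "no"))))
}

#' Fisher co-occurrence test of two per-frame interaction masks
#'
#' Builds the 2x2 frame-count table of joint occurrence and applies the
#' two-sided log-space Fisher test. Direction is `"positive"` when the
#' observed co-occurrence count exceeds its expectation under independence.
#'
#' @param mask_a,mask_b Equal-length logical frame vectors.
#' @return List with `p_value`, `log10_p`, `table`, `odds_direction`.
#' @export
cooccurrence_fisher <- function(mask_a, mask_b) {
  stopifnot(length(mask_a) == length(mask_b), length(mask_a) >= 1)
  a <- sum(mask_a & mask_b); b <- sum(mask_a & !mask_b)
  c_ <- sum(!mask_a & mask_b); d <- sum(!mask_a & !mask_b)
  res <- fisher_exact_2x2(a, b, c_, d)
  n <- length(mask_a)
  expected <- (a + b) * (a + c_) / n
  res$odds_direction <- if (a >= expected) "positive" else "negative"
  res
}

#' Pearson correlation between summed interaction time and activity
#'
#' @param x Named numeric vector: peptide -> summed interaction time (%).
#' @param y Named numeric vector: peptide -> activity.
#' @param exclude Peptide sequences to drop before correlating.
#' @return List with `r`, `r_squared`, `p_value`, `slope`, `intercept`, `n`.
#' @export
activity_interaction_correlation <- function(x, y, exclude = character(0)) {
  common <- setdiff(intersect(names(x), names(y)), exclude)
  if (length(common) < 3)
    stop("need >= 3 common peptides after exclusion")
  xv <- as.numeric(x[common]); yv <- as.numeric(y[common])
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- stats::lm.fit(cbind(1, xv), yv)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, slope = fit$coefficients[2],
       intercept = fit$coefficients[1], n = length(common))
}

#' Run the full two-stage cluster selectivity analysis
#'
#' Stage 1 tests every (testable cluster, enzyme residue, interaction type)
#' triple at the cluster's substrate position with a pooled t-test of
#' member vs non-member frequencies; Bonferroni correction uses the total
#' number of tests actually run as the family size. Stage 2 applies the
#' Mann-Whitney activity test to clusters significant in stage 1. A cluster
#' x interaction is labelled selectivity-associated when both stages pass.
#'
#' @param tables_by_peptide Named list of `kdac_freqtable` (after
#'   [apply_low_frequency_filter()]).
#' @param activities Named numeric vector: peptide -> normalized activity.
#' @param alphabet,positions Cluster enumeration parameters.
#' @param cluster_alpha Stage-1 threshold on the Bonferroni-adjusted p.
#' @param activity_alpha Stage-2 Mann-Whitney threshold.
#' @return List with `interaction_tests` (data frame), `activity_tests`
#'   (data frame), `family_size`, `clusters`.
#' @export
run_selectivity_analysis <- function(tables_by_peptide, activities,
                                     alphabet = c("A", "E", "R", "W", "Y"),
                                     positions = c(1L, 2L),
                                     cluster_alpha = 0.01,
                                     activity_alpha = 0.05) {
  peps <- names(tables_by_peptide)
  clusters <- enumerate_clusters(peps, alphabet, positions)
  keys <- unique(do.call(rbind, lapply(unname(tables_by_peptide), function(t)
    t$entries[c("resname", "resno", "position", "itype")])))
  rows <- list()
  for (cl in clusters) {
    if (!cl$testable || length(cl$members) < 2 || length(cl$nonmembers) < 2)
      next
    kk <- keys[keys$position == cl$position, , drop = FALSE]
    for (i in seq_len(nrow(kk))) {
      freqs <- vapply(peps, function(nm)
        freqtable_lookup(tables_by_peptide[[nm]], kk$resno[i],
                         kk$position[i], kk$itype[i]), 0)
      names(freqs) <- peps
      tt <- cluster_interaction_ttest(cl, freqs)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl$id, position = cl$position,
        residues = paste(cl$residues, collapse = ""),
        resname = kk$resname[i], resno = kk$resno[i], itype = kk$itype[i],
        t_statistic = tt$t_statistic, p_raw = tt$p_raw,
        stringsAsFactors = FALSE)
    }
  }
  itests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), position = integer(),
               residues = character(), resname = character(),
               resno = integer(), itype = character(),
               t_statistic = numeric(), p_raw = numeric())
  m <- nrow(itests)
  itests$p_adjusted <- pmin(1, m * itests$p_raw)
  itests$significant <- itests$p_adjusted <= cluster_alpha
  sig_clusters <- unique(itests$cluster[itests$significant])
  arows <- list()
  for (cl in clusters) {
    if (!(cl$id %in% sig_clusters)) next
    mw <- tryCatch(cluster_activity_mwu(cl, activities),
                   error = function(e) NULL)
    if (is.null(mw)) next
    arows[[length(arows) + 1]] <- data.frame(
      cluster = cl$id, U_statistic = mw$U_statistic, p_value = mw$p_value,
      direction = mw$direction, exact = mw$exact,
      significant = mw$p_value <= activity_alpha, stringsAsFactors = FALSE)
  }
  atests <- if (length(arows)) do.call(rbind, arows) else
    data.frame(cluster = character(), U_statistic = numeric(),
               p_value = numeric(), direction = character(),
               exact = logical(), significant = logical())
  itests$selectivity_associated <- itests$significant &
    itests$cluster %in% atests$cluster[atests$significant]
  list(interaction_tests = itests, activity_tests = atests,
       family_size = m, clusters = clusters)
}
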