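# Endpoint activity-panel analysis and steady-state kinetics: normalization
# against a reference peptide, pairwise pooled t-test significance matrices
# (Bonferroni), ratio error propagation, initial rates, Michaelis-Menten
# fitting with catalytic efficiency, and Fisher's-exact validation of
# residue-presence activity correlations. Below-detection activities are
# censored ("-" in the source tables): they count as not deacetylated in
# the Fisher validation and are excluded from normalization/correlation.

#' Create an activity record
#'
#' @param peptide Sequence string (acetyllysine `K(ac)`) or `kdac_peptide`.
#' @param enzyme Enzyme label (e.g. `"KDAC6"`).
#' @param replicates Numeric replicate specific activities (1/s), or `NULL`
#'   when only a mean and sd are known (as in published tables).
#' @param mean,sd Summary statistics; computed from `replicates` if omitted.
#'   `mean = NA` encodes activity below the detection limit.
#' @param n Replicate count when `replicates` is not given.
#' @param detection_limit Smallest reliably measurable activity (1/s).
#' @return A `kdac_activity` list; `detectable` is `TRUE` iff the mean
#'   exceeds the detection limit.
#' @export
activity_record <- function(peptide, enzyme = "KDAC", replicates = NULL,
                            mean = NULL, sd = NULL, n = NULL,
                            detection_limit = 0) {
  if (is.character(peptide)) peptide <- parse_peptide(peptide)
  if (!is.null(replicates)) {
    mean <- base::mean(replicates)
    sd <- stats::sd(replicates)
    n <- length(replicates)
  }
  if (is.null(mean)) stop("need replicates or a mean")
  structure(list(peptide = peptide, enzyme = enzyme, replicates = replicates,
                 mean = mean, sd = sd, n = n,
                 detection_limit = detection_limit,
                 detectable = !is.na(mean) && mean >= detection_limit),
            class = "kdac_activity")
}

record_sequences <- function(records)
  vapply(records, function(r) r$peptide$sequence, "")

#' Read an activity panel from CSV
#'
#' Expects columns `sequence`, `mean`, `sd` (empty `mean` = below the
#' detection limit); extra columns are kept as attributes on each record.
#'
#' @param path CSV path.
#' @param enzyme Enzyme label.
#' @param detection_limit Detection limit (1/s).
#' @param n Assumed replicate count.
#' @return List of `kdac_activity` records.
#' @export
read_activity_table <- function(path, enzyme = "KDAC", detection_limit = 0,
                                n = 4L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "mean", "sd") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    activity_record(df$sequence[i], enzyme = enzyme,
                    mean = if (is.na(df$mean[i])) NA_real_ else df$mean[i],
                    sd = df$sd[i], n = n,
                    detection_limit = detection_limit))
}

#' Normalize activities to a reference peptide
#'
#' The reference peptide's activity defines 1; every detectable record is
#' divided by the reference mean, with the standard deviation propagated as
#' for a ratio of independent measurements. Below-detection records are
#' excluded (censored, not zero).
#'
#' @param records List of `kdac_activity`.
#' @param reference Reference peptide sequence (default `"FRK(ac)WR"`).
#' @return Data frame with `sequence`, `value`, `sd`.
#' @export
normalize_activities <- function(records, reference = "FRK(ac)WR") {
  seqs <- record_sequences(records)
  ri <- match(reference, seqs)
  if (is.na(ri)) stop("reference peptide not in panel: ", reference)
  ref <- records[[ri]]
  if (!ref$detectable)
    stop("normalization error: reference activity below detection limit")
  keep <- vapply(records, `[[`, TRUE, "detectable")
  recs <- records[keep]
  value <- vapply(recs, function(r) r$mean / ref$mean, 0)
  sdv <- vapply(recs, function(r)
    (r$mean / ref$mean) *
      sqrt((r$sd / r$mean)^2 + (ref$sd / ref$mean)^2), 0)
  data.frame(sequence = seqs[keep], value = value, sd = sdv,
             stringsAsFactors = FALSE)
}

#' Pairwise activity significance matrix
#'
#' Pooled-variance two-tailed t-tests for every unordered pair of records,
#' Bonferroni-corrected over the number of pairs. Matrix codes: `"row"`
#' (row peptide significantly higher), `"col"`, or `"ns"`.
#'
#' @param records List of `kdac_activity` carrying replicate values.
#' @param alpha Threshold on the Bonferroni-adjusted p (default 0.01).
#' @return List with character matrix `codes`, numeric matrices `p_raw`
#'   and `p_adjusted` (all peptide x peptide), and `n_pairs`.
#' @export
pairwise_activity_ttests <- function(records, alpha = 0.01) {
  seqs <- record_sequences(records)
  k <- length(records)
  m <- k * (k - 1) / 2
  p_raw <- matrix(NA_real_, k, k, dimnames = list(seqs, seqs))
  codes <- matrix("", k, k, dimnames = list(seqs, seqs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    xi <- records[[i]]$replicates
    xj <- records[[j]]$replicates
    if (is.null(xi) || is.null(xj) || length(xi) < 2 || length(xj) < 2)
      stop("pairwise tests need >= 2 replicates per record")
    tt <- pooled_ttest(xi, xj)
    p_raw[i, j] <- p_raw[j, i] <- tt$p
    sig <- min(1, m * tt$p) <= alpha
    if (!sig) {
      codes[i, j] <- codes[j, i] <- "ns"
    } else if (mean(xi) > mean(xj)) {
      codes[i, j] <- "row"; codes[j, i] <- "col"
    } else {
      codes[i, j] <- "col"; codes[j, i] <- "row"
    }
  }
  list(codes = codes, p_raw = p_raw, p_adjusted = pmin(1, m * p_raw),
       n_pairs = m)
}

#' Activity ratio with propagated error
#'
#' @param a,b `kdac_activity` records; both must be detectable.
#' @return Named vector `c(ratio, sd)`; the sd follows the standard
#'   relative-error propagation for a quotient.
#' @export
activity_ratio_with_error <- function(a, b) {
  if (!a$detectable || !b$detectable)
    stop("undefined ratio: activity below detection limit")
  ratio <- a$mean / b$mean
  c(ratio = ratio,
    sd = ratio * sqrt((a$sd / a$mean)^2 + (b$sd / b$mean)^2))
}

#' Initial rates from kinetic timecourses
#'
#' For each substrate concentration, the initial rate is the least-squares
#' slope of product vs time (intercept fitted). A quadratic term improving
#' the fit by more than 10 AIC units triggers a product-depletion warning.
#'
#' @param timecourse Data frame with columns `conc`, `time`, `product`.
#' @return Data frame with `conc`, `v0`, `se`.
#' @export
initial_rates <- function(timecourse) {
  stopifnot(all(c("conc", "time", "product") %in% names(timecourse)))
  out <- lapply(split(timecourse, timecourse$conc), function(d) {
    if (nrow(d) < 3)
      stop("insufficient data: < 3 timepoints at concentration ", d$conc[1])
    fit <- stats::lm(product ~ time, data = d)
    if (nrow(d) >= 4 && stats::var(d$time) > 0) {
      fit2 <- stats::lm(product ~ time + I(time^2), data = d)
      cf2 <- summary(fit2)$coefficients
      curv_sig <- nrow(cf2) >= 3 && !is.na(cf2[3, 4]) &&
        cf2[3, 1] < 0 && cf2[3, 4] < 0.01
      if (isTRUE(stats::AIC(fit) - stats::AIC(fit2) > 10) && curv_sig)
        warning("timecourse at [S] = ", d$conc[1],
                " flattens over time (possible substrate depletion)")
    }
    s <- summary(fit)$coefficients
    data.frame(conc = d$conc[1], v0 = s["time", "Estimate"],
               se = s["time", "Std. Error"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$conc), ]
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of v0 = kcat * E * S / (KM + S) over initial
#' rates, initialized at KM = median S and kcat = max(v0)/E. Rate errors in
#' endpoint-style assays scale with the rate itself, so the default
#' weighting is relative (1/v0^2); pass `weighting = "none"` for ordinary
#' least squares. Catalytic efficiency kcat/KM is converted to 1/(M s)
#' (KM in uM). The fit is flagged unreliable when KM is poorly identified
#' (outside the sampled concentration range by more than 5x, or relative
#' SE > 0.5).
#'
#' @param rates Data frame with `conc` (uM) and `v0` (uM/s), e.g. from
#'   [initial_rates()].
#' @param enzyme_conc Enzyme concentration, nM.
#' @param weighting `"relative"` (default) or `"none"`.
#' @return A `kdac_kinetic_fit`: `K_M`, `K_M_se` (uM), `k_cat`, `k_cat_se`
#'   (1/s), `efficiency`, `efficiency_se` (1/(M s)), `enzyme_conc`,
#'   `n_concentrations`, `reliable`.
#' @export
fit_michaelis_menten <- function(rates, enzyme_conc,
                                 weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc", "v0") %in% names(rates)))
  S <- rates$conc
  v0 <- rates$v0
  if (length(unique(S)) < 5)
    stop("insufficient data: need >= 5 distinct substrate concentrations")
  E <- enzyme_conc * 1e-3   # nM -> uM
  start <- list(KM = stats::median(S), kcat = max(v0) / E)
  w <- if (weighting == "relative" && all(v0 > 0)) 1 / v0^2
       else rep(1, length(v0))
  do_fit <- function(st) minpack.lm::nlsLM(
    v0 ~ kcat * E * S / (KM + S), start = st,
    lower = c(KM = 1e-9, kcat = 1e-12), weights = w,
    data = data.frame(S = S, v0 = v0))
  fit <- tryCatch(do_fit(start), error = function(e) e)
  if (inherits(fit, "error"))
    fit <- tryCatch(do_fit(list(KM = min(S) / 10, kcat = max(v0) / E)),
                    error = function(e) e)
  if (!inherits(fit, "error")) {
    cf <- summary(fit)$coefficients
    KM <- cf["KM", "Estimate"]; KM_se <- cf["KM", "Std. Error"]
    kcat <- cf["kcat", "Estimate"]; kcat_se <- cf["kcat", "Std. Error"]
  } else {
    # K_M gradient numerically degenerate (e.g. all S >> K_M): fall back to
    # direct least squares on log parameters; near-singular curvature then
    # shows up as enormous SEs and the fit is flagged unreliable below.
    ss <- function(par) {
      pred <- exp(par[2]) * E * S / (exp(par[1]) + S)
      sum(w * (v0 - pred)^2)
    }
    opt <- stats::optim(log(c(start$KM, start$kcat)), ss, hessian = TRUE)
    KM <- exp(opt$par[1]); kcat <- exp(opt$par[2])
    dof <- length(v0) - 2
    sigma2 <- opt$value / max(1, dof)
    covm <- tryCatch(solve(opt$hessian / 2) * sigma2,
                     error = function(e) matrix(Inf, 2, 2))
    se_log <- suppressWarnings(sqrt(pmax(0, diag(covm))))
    KM_se <- KM * se_log[1]; kcat_se <- kcat * se_log[2]
  }
  eff <- kcat / (KM * 1e-6)
  eff_se <- eff * sqrt((kcat_se / kcat)^2 + (KM_se / KM)^2)
  reliable <- isTRUE(KM <= 5 * max(S) && KM >= min(S) / 5 &&
                       is.finite(KM_se) && KM_se / KM <= 0.5)
  structure(list(K_M = KM, K_M_se = KM_se, k_cat = kcat, k_cat_se = kcat_se,
                 efficiency = eff, efficiency_se = eff_se,
                 enzyme_conc = enzyme_conc,
                 n_concentrations = length(unique(S)),
                 reliable = reliable, fit = fit),
            class = "kdac_kinetic_fit")
}

#' @export
print.kdac_kinetic_fit <- function(x, ...) {
  cat(sprintf("<kdac_kinetic_fit> K_M = %.3g +/- %.2g uM, k_cat = %.3g +/- %.2g 1/s, kcat/KM = %.3g 1/(M s)%s\n",
              x$K_M, x$K_M_se, x$k_cat, x$k_cat_se, x$efficiency,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' Correlate endpoint activity with catalytic efficiency
#'
#' @param endpoints Named numeric vector: peptide -> endpoint activity.
#' @param fits Named list: peptide -> `kdac_kinetic_fit`.
#' @return As [activity_interaction_correlation()].
#' @export
endpoint_efficiency_correlation <- function(endpoints, fits) {
  eff <- vapply(fits, `[[`, 0, "efficiency")
  activity_interaction_correlation(eff, endpoints)
}

#' Fisher's exact validation of a residue-presence activity correlation
#'
#' Cross-classifies panel peptides by a user predicate on the sequence
#' (e.g. aromatic residue at +1) and by detectable activity, and applies
#' the two-sided Fisher exact test. Below-detection peptides count as not
#' deacetylated.
#'
#' @param records List of `kdac_activity`.
#' @param predicate Function `kdac_peptide -> logical`.
#' @return List with `table` (rows: predicate yes/no; columns: detectable
#'   yes/no), `p_value`, `log10_p`.
#' @export
residue_presence_fisher <- function(records, predicate) {
  pr <- vapply(records, function(r) isTRUE(predicate(r$peptide)), TRUE)
  det <- vapply(records, `[[`, TRUE, "detectable")
  if (all(pr) || !any(pr))
    stop("predicate must split the panel")
  res <- fisher_exact_2x2(sum(pr & det), sum(pr & !det),
                          sum(!pr & det), sum(!pr & !det))
  dimnames(res$table) <- list(predicate = c("yes", "no"),
                              detectable = c("yes", "no"))
  res
}

#' Descending activity ranks of a panel
#'
#' Ranks records by mean specific activity, most active first;
#' below-detection records rank last. Ties get min rank-compatible order
#' via `rank(ties.method = "min")`.
#'
#' @param records List of `kdac_activity`.
#' @return Data frame with `sequence`, `mean`, `rank`.
#' @export
activity_ranks <- function(records) {
  seqs <- record_sequences(records)
  means <- vapply(records, function(r)
    if (is.na(r$mean)) -Inf else r$mean, 0)
  data.frame(sequence = seqs, mean = ifelse(is.finite(means), means, NA),
             rank = rank(-means, ties.method = "min"),
             stringsAsFactors = FALSE)
}
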