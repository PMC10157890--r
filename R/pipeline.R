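# End-to-end orchestration: trajectory scanning -> frequency tables ->
# exclusion filters -> cluster selectivity statistics -> report bundle.
# All thresholds live in one config object whose defaults are the analysis
# conventions used throughout: 0.01 for cluster tests (Bonferroni), 0.05
# for the activity Mann-Whitney stage, 1e-10 for frame co-occurrence
# Fisher tests, 0.01 for correlations.

#' Analysis configuration
#'
#' @param criteria An [interaction_criteria()] object.
#' @param alphabet Cluster residue alphabet.
#' @param positions Substrate positions for clustering.
#' @param cluster_alpha,activity_alpha,cooccurrence_alpha,correlation_alpha
#'   Significance thresholds.
#' @param reference_peptide Peptide defining normalized activity 1.
#' @param seed Seed recorded in the run log and used by any simulation the
#'   pipeline performs.
#' @return A `kdac_config` list.
#' @export
analysis_config <- function(criteria = interaction_criteria(),
                            alphabet = c("A", "E", "R", "W", "Y"),
                            positions = c(1L, 2L),
                            cluster_alpha = 0.01, activity_alpha = 0.05,
                            cooccurrence_alpha = 1e-10,
                            correlation_alpha = 0.01,
                            reference_peptide = "FRK(ac)WR", seed = 1L) {
  thr <- c(cluster_alpha, activity_alpha, cooccurrence_alpha,
           correlation_alpha)
  stopifnot(all(thr > 0), all(thr <= 1))
  structure(list(criteria = criteria, alphabet = alphabet,
                 positions = as.integer(positions),
                 cluster_alpha = cluster_alpha,
                 activity_alpha = activity_alpha,
                 cooccurrence_alpha = cooccurrence_alpha,
                 correlation_alpha = correlation_alpha,
                 reference_peptide = reference_peptide,
                 seed = as.integer(seed)),
            class = "kdac_config")
}

#' Run the full selectivity-mapping pipeline
#'
#' Scans every replicate trajectory of every peptide, aggregates replicate
#' frequencies with catalytic-pose exclusion and truncation, applies the
#' panel-wide low-frequency filter, normalizes the activity panel, runs the
#' two-stage cluster selectivity analysis, and (when `out_dir` is given)
#' writes the report bundle: per-position frequency heat-map TSVs,
#' an exclusion log (JSON), the cluster report (JSON), the normalized
#' activity CSV and a run log recording thresholds and seed. File outputs
#' are deterministic: identical inputs give byte-identical reports.
#'
#' @param config An [analysis_config()].
#' @param trajectories Named list (peptide sequence -> list of
#'   `kdac_trajectory` replicates), or a named list of character vectors of
#'   multi-model PDB paths (loaded with [load_trajectory()]; chain/topology
#'   arguments then come from `load_args`).
#' @param activities List of `kdac_activity` records (or a CSV path for
#'   [read_activity_table()]).
#' @param out_dir Output directory, or `NULL` for no files.
#' @param load_args List of arguments for [load_trajectory()] when
#'   `trajectories` are paths.
#' @return Invisibly, a list with `freq_tables`, `normalized`,
#'   `selectivity`, `config`.
#' @export
run_pipeline <- function(config, trajectories, activities, out_dir = NULL,
                         load_args = list()) {
  if (length(trajectories) == 0) stop("no trajectories supplied")
  if (is.character(activities))
    activities <- read_activity_table(activities)
  tables <- list()
  for (pep in names(trajectories)) {
    reps <- trajectories[[pep]]
    if (is.character(reps))
      reps <- lapply(seq_along(reps), function(i)
        do.call(load_trajectory,
                c(list(path = reps[i], peptide = pep, replicate_id = i),
                  load_args)))
    if (length(reps) == 0) stop("no trajectories for peptide ", pep)
    recs <- lapply(reps, scan_interactions, criteria = config$criteria)
    tables[[pep]] <- aggregate_frequencies(recs,
                                           peptide = parse_peptide(pep))
  }
  tables <- apply_low_frequency_filter(tables)
  norm <- normalize_activities(activities,
                               reference = config$reference_peptide)
  act_vec <- stats::setNames(norm$value, norm$sequence)
  sel <- run_selectivity_analysis(tables, act_vec,
                                  alphabet = config$alphabet,
                                  positions = config$positions,
                                  cluster_alpha = config$cluster_alpha,
                                  activity_alpha = config$activity_alpha)
  bundle <- list(freq_tables = tables, normalized = norm,
                 selectivity = sel, config = config)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  invisible(bundle)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  for (pos in cfg$positions) {
    for (pep in names(bundle$freq_tables)) {
      f <- file.path(out_dir, sprintf("freq_%s_pos%+d.tsv",
                                      gsub("[^A-Za-z0-9]", "", pep), pos))
      export_heatmap(bundle$freq_tables[[pep]], position = pos, file = f)
    }
  }
  excl <- lapply(bundle$freq_tables, function(t) t$excluded)
  .write_json(excl, file.path(out_dir, "exclusions.json"))
  .write_json(list(schema_version = 1L,
                   family_size = bundle$selectivity$family_size,
                   interaction_tests = bundle$selectivity$interaction_tests,
                   activity_tests = bundle$selectivity$activity_tests),
              file.path(out_dir, "cluster_report.json"))
  utils::write.csv(bundle$normalized,
                   file.path(out_dir, "normalized_activity.csv"),
                   row.names = FALSE)
  .write_json(list(schema_version = 1L,
                   package_version = as.character(
                     utils::packageVersion("kdacselect")),
                   seed = cfg$seed,
                   thresholds = list(cluster = cfg$cluster_alpha,
                                     activity = cfg$activity_alpha,
                                     cooccurrence = cfg$cooccurrence_alpha,
                                     correlation = cfg$correlation_alpha),
                   criteria = unclass(cfg$criteria)),
              file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
}

#' Export a frequency table as a heat-map matrix TSV
#'
#' Rows are enzyme residues (ordered by residue number, labelled e.g.
#' `H499`), columns the four interaction types; cells hold the truncated
#' percent time and are empty where the interaction was not retained.
#' Excluded keys never appear.
#'
#' @param tab A `kdac_freqtable`.
#' @param position Substrate position to export.
#' @param file Optional TSV path.
#' @return The matrix as a data frame (residue label column + one column
#'   per interaction type), invisibly when writing.
#' @export
export_heatmap <- function(tab, position, file = NULL) {
  e <- tab$entries[tab$entries$position == position, , drop = FALSE]
  res <- unique(e[order(e$resno), c("resname", "resno")])
  lab <- paste0(substr(res$resname, 1, 1), res$resno)
  m <- matrix(NA_integer_, nrow = nrow(res), ncol = length(ITYPES),
              dimnames = list(lab, ITYPES))
  for (i in seq_len(nrow(e))) {
    ri <- match(e$resno[i], res$resno)
    m[ri, e$itype[i]] <- e$percent[i]
  }
  df <- data.frame(residue = lab, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(df))
  }
  df
}

#' Read a heat-map TSV back into entry form
#'
#' Inverse of [export_heatmap()] for retained entries.
#'
#' @param file TSV path.
#' @param position Substrate position the file was exported for.
#' @return Data frame with `resno`, `itype`, `percent`.
#' @export
read_heatmap <- function(file, position) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (it in intersect(ITYPES, names(df))) {
    keep <- !is.na(df[[it]])
    if (any(keep))
      out[[it]] <- data.frame(
        resno = as.integer(sub("^[A-Za-z]", "", df$residue[keep])),
        position = position, itype = it,
        percent = as.integer(df[[it]][keep]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$resno, res$itype), ]
}
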