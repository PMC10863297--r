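# End-to-end orchestration: simulate (optional) -> scan -> unique ->
# drift -> infoloss, with a machine-readable run manifest. The package's
# functions are the interface; run_pipeline() composes them with one
# parameter set and writes every stage's table to disk.

#' Pipeline parameter set
#'
#' Gathers every stage parameter with its operation default, so a whole
#' run is reproducible from one object plus a seed.
#'
#' @param target_tissue Tissue whose unique signature is analyzed.
#' @param delta,q,min_values Unique-site calling parameters, see
#'   [call_unique_sites()].
#' @param if_threshold Fibrosis cut for [group_drift()].
#' @param k SD multiplier for the information-loss score.
#' @param min_pairs Minimum complete pairs in [pearson_scan()].
#' @param top_frac Fraction for [top_fraction()] in the overlap
#'   enrichment.
#' @param synth A [synth_config()] used when the pipeline simulates its
#'   own inputs.
#' @param n_cohort Cohort size when simulating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_tissue = "kidney", delta = 0.2,
                            q = 0.05, min_values = NULL, if_threshold = 20,
                            k = 2, min_pairs = 10, top_frac = 0.10,
                            synth = synth_config(), n_cohort = 100) {
  stopifnot(delta >= 0, q > 0, q < 0.5, if_threshold >= 0,
            if_threshold <= 100, k > 0, min_pairs >= 3,
            top_frac > 0, top_frac <= 1)
  structure(list(target_tissue = target_tissue, delta = delta, q = q,
                 min_values = min_values, if_threshold = if_threshold,
                 k = k, min_pairs = min_pairs, top_frac = top_frac,
                 synth = synth, n_cohort = n_cohort),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either simulated or user-supplied inputs:
#' per-CpG correlation scan against IF, unique-site calling on the atlas,
#' drift toward the common baseline with the sign test, overlap
#' enrichment of unique sites with the top IF-correlated decile, the
#' uniqueness-vs-IF relation, and the per-sample information-loss score.
#' When `output_dir` is given, every stage's table is written as TSV
#' together with a `manifest.tsv` of parameters, so identical
#' config + seed reproduce identical files.
#'
#' @param config A [pipeline_config()].
#' @param atlas,cohort_matrix,cohort_sheet Optional real inputs; when any
#'   is `NULL` the synthetic generators supply them (from
#'   `config$synth`).
#' @param output_dir Optional directory for stage outputs.
#' @return A list with `scan`, `calls`, `drift`, `sign_test`,
#'   `enrichment`, `uniqueness_vs_if`, `reference`, `info_loss`, and
#'   (when simulated) `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), atlas = NULL,
                         cohort_matrix = NULL, cohort_sheet = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(atlas) || is.null(cohort_matrix) || is.null(cohort_sheet)) {
    message("run_pipeline: simulating atlas and cohort (seed ",
            config$synth$seed, ")")
    gen <- generate_atlas(config$synth)
    atlas <- gen$atlas
    truth <- gen$truth
    cohort <- generate_kidney_cohort(gen$truth, config$n_cohort,
                                     config$synth)
    cohort_matrix <- cohort$matrix
    cohort_sheet <- cohort$sheet
  }

  al <- align_samples(cohort_matrix, cohort_sheet)
  scan <- pearson_scan(al$matrix,
                       stats::setNames(al$sheet$IF, al$sheet$sample_id),
                       min_pairs = config$min_pairs)
  calls <- call_unique_sites(atlas, config$target_tissue,
                             delta = config$delta, q = config$q,
                             min_values = config$min_values)
  if (nrow(calls) >= 3L) {
    drift <- group_drift(al$matrix, al$sheet, calls,
                         if_threshold = config$if_threshold)
    informative <- !is.na(drift$toward_common)
    st <- sign_test(sum(drift$toward_common[informative]),
                    sum(informative))
    enr <- overlap_enrichment(intersect(calls$probe_id, scan$probe_id),
                              top_fraction(scan, config$top_frac),
                              scan$probe_id)
    uvi <- uniqueness_vs_if(calls, scan)
    reference <- build_reference(al$matrix, al$sheet, calls)
    info <- score_cohort(al$matrix, al$sheet, reference, k = config$k)
  } else {
    message("run_pipeline: only ", nrow(calls), " unique-site call(s); ",
            "drift and information-loss stages skipped")
    drift <- st <- enr <- uvi <- reference <- info <- NULL
  }

  result <- list(scan = scan, calls = calls, drift = drift,
                 sign_test = st, enrichment = enr,
                 uniqueness_vs_if = uvi, reference = reference,
                 info_loss = info, truth = truth)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(output_dir, name)
    write_results_table(scan, out("scan.tsv"))
    write_results_table(calls, out("unique_calls.tsv"))
    if (!is.null(drift)) {
      write_results_table(drift, out("drift.tsv"))
      write_results_table(reference, out("reference.tsv"))
      write_results_table(info$scores, out("info_loss.tsv"))
    }
    manifest <- data.frame(
      key = c("target_tissue", "delta", "q", "if_threshold", "k",
              "min_pairs", "top_frac", "seed", "n_cohort",
              "n_unique_calls", "sign_test_log10_p",
              "enrichment_observed", "enrichment_expected",
              "uniqueness_vs_if_r"),
      value = c(config$target_tissue, config$delta, config$q,
                config$if_threshold, config$k, config$min_pairs,
                config$top_frac, config$synth$seed, config$n_cohort,
                nrow(calls),
                if (is.null(st)) NA else st$log10_p,
                if (is.null(enr)) NA else enr$observed,
                if (is.null(enr)) NA else enr$expected,
                if (is.null(uvi)) NA else uvi$r),
      stringsAsFactors = FALSE)
    write_results_table(manifest, out("manifest.tsv"), sort_by = NA)
  }
  result
}

#' Validate pipeline inputs without mutating them
#'
#' Collects every detectable violation — beta values out of range,
#' duplicate identifiers, phenotype range errors, matrix/sheet alignment
#' mismatches — into a report, without stopping at the first problem.
#'
#' @param matrix Probes x samples beta matrix.
#' @param sheet Sample-sheet data frame.
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `where` and `message`; zero rows when the inputs are clean.
#' @export
validate_inputs <- function(matrix, sheet) {
  rows <- list()
  add <- function(severity, where, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      severity = severity, where = where, message = msg,
      stringsAsFactors = FALSE)
  }
  bad <- which(!is.na(matrix) & (matrix < -BOUND_TOL |
                                   matrix > 1 + BOUND_TOL), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    for (i in seq_len(min(nrow(bad), 20L))) {
      add("error", "matrix",
          paste0("beta value ", format(matrix[bad[i, 1], bad[i, 2]]),
                 " out of [0,1] at probe ", rownames(matrix)[bad[i, 1]],
                 ", sample ", colnames(matrix)[bad[i, 2]]))
    }
  }
  dup <- unique(rownames(matrix)[duplicated(rownames(matrix))])
  for (d in dup) add("error", "matrix", paste0("duplicate probe_id ", d))
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  for (d in dup) add("error", "sheet", paste0("duplicate sample_id ", d))
  if ("IF" %in% colnames(sheet)) {
    for (s in sheet$sample_id[!is.na(sheet$IF) &
                                (sheet$IF < 0 | sheet$IF > 100)]) {
      add("error", "sheet", paste0("IF out of [0,100] for sample ", s))
    }
  }
  if ("eGFR" %in% colnames(sheet)) {
    for (s in sheet$sample_id[!is.na(sheet$eGFR) & sheet$eGFR < 0]) {
      add("error", "sheet", paste0("negative eGFR for sample ", s))
    }
  }
  only_m <- setdiff(colnames(matrix), sheet$sample_id)
  only_s <- setdiff(sheet$sample_id, colnames(matrix))
  if (length(only_m) > 0L || length(only_s) > 0L) {
    add("warning", "alignment",
        paste0(length(only_m), " matrix-only and ", length(only_s),
               " sheet-only sample(s)"))
  }
  if (length(rows) == 0L) {
    return(data.frame(severity = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
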