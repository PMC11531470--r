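# Report-bundle plumbing. Every number written here is produced by a module
# operation; this layer only formats (4 significant digits) and writes.
# Bundles are fully deterministic: no wall-clock timestamps anywhere, so an
# identical configuration reproduces a byte-identical bundle.

.fmt_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  basename(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  basename(path)
}

#' Run the reference-ranking pipeline and write a report bundle
#'
#' Ties together QC filtering, the four stability methods and the
#' comprehensive rank aggregation, writing a plain-text report bundle:
#' per-method score tables, the aggregate ranking, QC exclusions, a run log
#' (configuration, package version, group sizes, tie-breaks and dropped
#' samples) and a MANIFEST listing every file with its status. A method
#' whose preconditions fail is recorded as failed in the MANIFEST while the
#' remaining results are still written.
#'
#' @param ct a [ct_matrix()] or path to a wide Ct table.
#' @param meta sample metadata data.frame or path.
#' @param out_dir output directory (created if needed).
#' @param methods at least two of `c("deltact", "genorm", "bestkeeper",
#'   "normfinder")`.
#' @param group_key metadata column used for grouped NormFinder and QC
#'   reporting.
#' @param grouped run NormFinder grouped by `group_key`?
#' @param apply_qc apply [qc_filter()] before the analysis?
#' @param min_viability,min_cd19,require_rna_ok QC thresholds, see
#'   [qc_filter()].
#' @param dispersion BestKeeper dispersion flavour.
#' @param genes optional gene subset to rank (e.g. to leave a target miRNA
#'   out of the candidate panel).
#' @return invisibly, a list with the in-memory results (`results`), the QC
#'   partition (`qc`), failed methods (`failures`) and `out_dir`.
#' @export
run_rank <- function(ct, meta, out_dir,
                     methods = c("deltact", "genorm", "bestkeeper",
                                 "normfinder"),
                     group_key = "compartment", grouped = FALSE,
                     apply_qc = TRUE, min_viability = 25, min_cd19 = 60,
                     require_rna_ok = TRUE, dispersion = "sd",
                     genes = NULL) {
  if (is.character(ct)) ct <- read_ct_table(ct, "wide")
  if (is.character(meta)) meta <- read_sample_meta(meta)
  validate_sample_meta(meta)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 2)
    stop("configuration error: need at least 2 methods to aggregate",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- c("refstab rank run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("refstab"))),
                 sprintf("methods: %s", paste(methods, collapse = ", ")),
                 sprintf("group key: %s; grouped normfinder: %s",
                         group_key, grouped),
                 sprintf("qc: apply=%s viability>%g cd19>%g rna_ok=%s",
                         apply_qc, min_viability, min_cd19, require_rna_ok))
  manifest <- character(0)
  failures <- character(0)

  qc <- NULL
  if (apply_qc) {
    qc <- qc_filter(meta, min_viability, min_cd19, require_rna_ok)
    manifest <- c(manifest,
                  paste0(.write_tsv(qc$excluded,
                                    file.path(out_dir, "qc_exclusions.tsv")),
                         "\tok"))
    log_lines <- c(log_lines,
                   sprintf("qc: kept %d, excluded %d (%s)",
                           length(qc$kept), nrow(qc$excluded),
                           if (nrow(qc$excluded))
                             paste(sprintf("%s:%s", qc$excluded$sample_id,
                                           qc$excluded$reason),
                                   collapse = ", ")
                           else "none"))
    ct <- subset_ct(ct, samples = intersect(colnames(ct$ct), qc$kept))
  }
  if (!is.null(genes)) ct <- subset_ct(ct, genes = genes)
  grp <- meta[[group_key]][match(colnames(ct$ct), meta$sample_id)]
  sizes <- table(grp)
  log_lines <- c(log_lines,
                 sprintf("analysis samples: %d (%s)", ncol(ct$ct),
                         paste(sprintf("%s=%d", names(sizes), sizes),
                               collapse = ", ")))

  results <- list()
  ranks <- list()
  try_method <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      failures <<- c(failures, name)
      log_lines <<- c(log_lines,
                      sprintf("method %s FAILED: %s", name,
                              conditionMessage(out)))
      NULL
    } else out
  }

  if ("deltact" %in% methods) {
    res <- try_method("deltact", function() {
      pairs <- pairwise_deltas(ct)
      scores <- deltact_scores(pairs)
      list(pairs = pairs, scores = scores)
    })
    if (!is.null(res)) {
      results$deltact <- res
      ranks$deltact <- stats::setNames(res$scores$rank, res$scores$gene)
      manifest <- c(manifest,
        paste0(.write_tsv(.fmt_df(res$pairs),
                          file.path(out_dir, "deltact_pairs.tsv")), "\tok"),
        paste0(.write_tsv(.fmt_df(res$scores),
                          file.path(out_dir, "deltact_scores.tsv")), "\tok"))
    } else {
      manifest <- c(manifest, "deltact_scores.tsv\tFAILED")
    }
  }
  if ("genorm" %in% methods) {
    res <- try_method("genorm", function() genorm_rank(ct))
    if (!is.null(res)) {
      results$genorm <- res
      ranks$genorm <- res$ranks
      step <- match(names(res$m_values), res$exclusion_order)
      tab <- data.frame(gene = names(res$m_values),
                        m_first_iteration = res$m_values,
                        m_at_exclusion = res$m_at_exclusion,
                        exclusion_step = ifelse(is.na(step), "final pair",
                                                as.character(step)),
                        rank = res$ranks[names(res$m_values)],
                        stringsAsFactors = FALSE, row.names = NULL)
      tab <- tab[order(tab$rank, tab$gene), ]
      vtab <- data.frame(step = names(res$v_series), v = res$v_series,
                         stringsAsFactors = FALSE, row.names = NULL)
      manifest <- c(manifest,
        paste0(.write_tsv(.fmt_df(tab),
                          file.path(out_dir, "genorm.tsv")), "\tok"),
        paste0(.write_tsv(.fmt_df(vtab),
                          file.path(out_dir, "genorm_v.tsv")), "\tok"))
      if (length(res$tie_breaks))
        log_lines <- c(log_lines, paste("genorm", res$tie_breaks))
    } else {
      manifest <- c(manifest, "genorm.tsv\tFAILED")
    }
  }
  if ("bestkeeper" %in% methods) {
    res <- try_method("bestkeeper", function()
      bestkeeper_stats(ct, dispersion = dispersion))
    if (!is.null(res)) {
      results$bestkeeper <- res
      ranks$bestkeeper <- stats::setNames(res$genes$rank, res$genes$gene)
      manifest <- c(manifest,
        paste0(.write_tsv(.fmt_df(res$genes),
                          file.path(out_dir, "bestkeeper.tsv")), "\tok"))
    } else {
      manifest <- c(manifest, "bestkeeper.tsv\tFAILED")
    }
  }
  if ("normfinder" %in% methods) {
    res <- try_method("normfinder", function()
      suppressMessages(normfinder_stability(ct, meta = meta,
                                            grouped = grouped,
                                            group_key = group_key)))
    if (!is.null(res)) {
      results$normfinder <- res
      ranks$normfinder <- stats::setNames(res$stability$rank,
                                          res$stability$gene)
      manifest <- c(manifest,
        paste0(.write_tsv(.fmt_df(res$stability),
                          file.path(out_dir, "normfinder.tsv")), "\tok"))
      if (length(res$dropped_samples))
        log_lines <- c(log_lines,
                       paste("normfinder dropped incomplete samples:",
                             paste(res$dropped_samples, collapse = ", ")))
      meta_json <- list(grouping_key = if (grouped) group_key else "none",
                        group_sizes = as.list(res$groups),
                        gamma2 = res$gamma2)
      manifest <- c(manifest,
        paste0(.write_json(meta_json,
                           file.path(out_dir, "normfinder_run.json")),
               "\tok"))
    } else {
      manifest <- c(manifest, "normfinder.tsv\tFAILED")
    }
  }

  if (length(ranks) >= 2) {
    agg <- comprehensive_rank(ranks)
    results$aggregate <- agg
    manifest <- c(manifest,
      paste0(.write_tsv(.fmt_df(as.data.frame(agg)),
                        file.path(out_dir, "aggregate.tsv")), "\tok"))
  } else {
    log_lines <- c(log_lines,
                   "aggregate SKIPPED: fewer than 2 methods succeeded")
    manifest <- c(manifest, "aggregate.tsv\tFAILED")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  writeLines(c(manifest, "run_log.txt\tok"),
             file.path(out_dir, "MANIFEST"))
  invisible(list(results = results, qc = qc, failures = failures,
                 out_dir = out_dir))
}

#' Run the reference-choice expression sensitivity analysis
#'
#' Computes 2^-ddCt relative quantification of a target gene once per
#' requested reference set (the "sweep" exposing how reference choice
#' changes the conclusion), writing one RQ table and one JSON summary per
#' panel plus a combined summary and MANIFEST.
#'
#' @param ct a [ct_matrix()] or path to a wide Ct table.
#' @param meta metadata data.frame or path.
#' @param out_dir output directory.
#' @param target target gene id.
#' @param reference_sets list of character vectors, one per panel; panel
#'   names default to the concatenated gene ids.
#' @param calibrator_group,group_key,compare,calibration passed to
#'   [delta_delta_ct()].
#' @return invisibly, list of [delta_delta_ct()] results (one per panel).
#' @export
run_express <- function(ct, meta, out_dir, target, reference_sets,
                        calibrator_group, group_key = "group",
                        compare = NULL,
                        calibration = "group_mean") {
  if (is.character(ct)) ct <- read_ct_table(ct, "wide")
  if (is.character(meta)) meta <- read_sample_meta(meta)
  if (!is.list(reference_sets)) reference_sets <- list(reference_sets)
  if (is.null(names(reference_sets)))
    names(reference_sets) <- vapply(reference_sets, paste, "", collapse = "+")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  panels <- list()
  summary_all <- list()
  for (nm in names(reference_sets)) {
    res <- suppressMessages(
      delta_delta_ct(ct, target = target, references = reference_sets[[nm]],
                     meta = meta, calibrator_group = calibrator_group,
                     group_key = group_key, compare = compare,
                     calibration = calibration))
    panels[[nm]] <- res
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    manifest <- c(manifest,
      paste0(.write_tsv(.fmt_df(res$samples),
                        file.path(out_dir, sprintf("rq_%s.tsv", safe))),
             "\tok"))
    summary_all[[nm]] <- list(references = res$references,
                              group_stats = .fmt_df(res$group_stats),
                              mann_whitney_p = res$p_value,
                              test_groups = res$test_groups,
                              calibrator_group = res$calibrator_group,
                              calibration = res$calibration,
                              excluded_samples = res$excluded_samples)
  }
  manifest <- c(manifest,
    paste0(.write_json(list(target = target, panels = summary_all),
                       file.path(out_dir, "express_summary.json")), "\tok"))
  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(panels)
}
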