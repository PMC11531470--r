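#' Default candidate-reference panel for the synthetic cohort
#'
#' Six candidate references spanning the stability spectrum seen in
#' leukemia xenograft qPCR panels: two genuinely stable miRNA-like genes, a
#' nucleolar snoRNA-like gene whose expression is confounded with the
#' disease compartment (higher expression, i.e. lower Ct, in bone-marrow
#' and CNS-derived samples), a high-variance ribosomal-RNA-like gene, and
#' two intermediates. Offsets and sigmas are in cycles.
#'
#' @return data.frame with columns `gene`, `basal_ct`, `sigma`, and one
#'   `offset_<group>` column per cohort group.
#' @export
default_panel <- function() {
  data.frame(
    gene = c("miR-532-like", "miR-103a-like", "RNU6-like", "RNU1A1-like",
             "SNORD44-like", "5sRNA-like"),
    basal_ct = c(25, 22, 20, 24, 19, 16),
    sigma = c(0.5, 0.6, 1.2, 1.4, 1.5, 2.5),
    offset_cell_line = c(0, 0, 0, 0, 0, 0),
    offset_spleen = c(0, 0, 0, 0, -0.5, 0),
    offset_bm = c(0, 0, 0, 0, -2, 0),
    offset_cns = c(0, 0, 0, 0, -1, 0),
    offset_pbmc = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic qPCR cohort generator
#'
#' Defines the generative model
#' `Ct_igs = basal_i + d_ig + u_s + e_igs`, with per-sample loading shifts
#' `u_s ~ N(0, loading_sd^2)` and per-gene noise `e ~ N(0, sigma_ig^2)`,
#' plus an optional target miRNA overexpressed in the leukemia groups.
#' Defaults mirror a two-arm leukemia benchmarking cohort: 9 cell lines,
#' 22 spleen-, 22 bone-marrow- and 12 CNS-derived xenograft samples, and 6
#' healthy-control PBMC donors; the target is 4-fold (2 cycles) up in every
#' leukemia group.
#'
#' @param group_sizes named integer vector over
#'   `c("cell_line", "spleen", "bm", "cns", "pbmc")`; every size >= 2.
#' @param panel gene panel as in [default_panel()].
#' @param loading_sd per-sample RNA-loading shift SD in cycles (>= 0).
#' @param target `NULL`, or list with `gene`, `basal_ct`, `sigma`, and
#'   `log2_fold` (named per-group log2 fold-changes vs baseline; a positive
#'   value lowers Ct).
#' @param missing_rate fraction of wells masked at random, in `[0, 0.5]`.
#' @param qc_fail_frac fraction of PDX samples drawn as quality-control
#'   failures (low viability or low CD19).
#' @param rna_fail_frac fraction of samples flagged with poor RNA quality.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(group_sizes = c(cell_line = 9, spleen = 22, bm = 22,
                                       cns = 12, pbmc = 6),
                       panel = default_panel(),
                       loading_sd = 0.8,
                       target = list(gene = "miR-181a-like", basal_ct = 27,
                                     sigma = 0.6,
                                     log2_fold = c(cell_line = 2, spleen = 2,
                                                   bm = 2, cns = 2,
                                                   pbmc = 0)),
                       missing_rate = 0,
                       qc_fail_frac = 0.1,
                       rna_fail_frac = 0.05) {
  stopifnot(is.numeric(group_sizes), !is.null(names(group_sizes)))
  if (any(group_sizes < 2))
    stop("every group size must be at least 2", call. = FALSE)
  if (!all(names(group_sizes) %in% .compartment_levels))
    stop("group names must be among: ",
         paste(.compartment_levels, collapse = ", "), call. = FALSE)
  need <- c("gene", "basal_ct", "sigma", paste0("offset_", names(group_sizes)))
  miss <- setdiff(need, colnames(panel))
  if (length(miss))
    stop("panel missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(panel$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (loading_sd < 0) stop("loading_sd must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]", call. = FALSE)
  stopifnot(qc_fail_frac >= 0, qc_fail_frac <= 1,
            rna_fail_frac >= 0, rna_fail_frac <= 1)
  if (!is.null(target)) {
    stopifnot(all(c("gene", "basal_ct", "sigma", "log2_fold") %in%
                    names(target)),
              all(names(group_sizes) %in% names(target$log2_fold)))
    if (target$gene %in% panel$gene)
      stop("target gene id collides with the panel", call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, panel = panel,
                 loading_sd = loading_sd, target = target,
                 missing_rate = missing_rate, qc_fail_frac = qc_fail_frac,
                 rna_fail_frac = rna_fail_frac),
            class = "sim_config")
}

.group_cohort <- c(cell_line = "cell_line", spleen = "pdx", bm = "pdx",
                   cns = "pdx", pbmc = "healthy_control")
.group_prefix <- c(cell_line = "CL", spleen = "SP", bm = "BM", cns = "CNS",
                   pbmc = "HC")

#' Simulate a synthetic qPCR cohort
#'
#' Draws a Ct matrix, matching sample metadata (with viability / CD19 /
#' RNA-quality draws so [qc_filter()] is exercisable), and the ground truth
#' used by recovery tests. A single global RNG stream is used; the same
#' seed yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `ct` (a [ct_matrix()]; panel genes plus the target
#'   gene when configured), `meta` (validated metadata; `group` =
#'   compartment), and `truth`: list with `panel` (true per-gene `sigma`
#'   and per-group offsets), `target`, `loading_shifts` (realized `u_s`),
#'   `stability_order` (most stable first, by `sigma` + SD of the true
#'   group offsets), `seed`.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  sample_ids <- unlist(lapply(names(gs), function(g)
    sprintf("%s%02d", .group_prefix[[g]], seq_len(gs[[g]]))))
  n <- length(sample_ids)
  u <- config$loading_sd * stats::rnorm(n)  # scaled so the RNG stream
  # length is invariant to zero-variance settings

  pan <- config$panel
  gene_rows <- lapply(seq_len(nrow(pan)), function(i) {
    off <- unlist(pan[i, paste0("offset_", groups)])
    pan$basal_ct[i] + off + u + pan$sigma[i] * stats::rnorm(n)
  })
  genes <- pan$gene
  if (!is.null(config$target)) {
    tg <- config$target
    gene_rows <- c(gene_rows,
                   list(tg$basal_ct - tg$log2_fold[groups] + u +
                          tg$sigma * stats::rnorm(n)))
    genes <- c(genes, tg$gene)
  }
  m <- do.call(rbind, gene_rows)
  dimnames(m) <- list(genes, sample_ids)
  m <- pmin(pmax(m, 0), 50)   # instrument range

  # QC metadata: designated failures draw from low Beta distributions
  cohort <- unname(.group_cohort[groups])
  is_pdx <- cohort == "pdx"
  fail_qc <- is_pdx & stats::runif(n) < config$qc_fail_frac
  fail_mode <- ifelse(stats::runif(n) < 0.5, "viability", "cd19")
  viability <- 100 * stats::rbeta(n, 12, 1.5)
  viability[fail_qc & fail_mode == "viability"] <-
    100 * stats::rbeta(sum(fail_qc & fail_mode == "viability"), 2, 12)
  cd19 <- ifelse(is_pdx, 100 * stats::rbeta(n, 14, 1.5), NA_real_)
  sel <- fail_qc & fail_mode == "cd19"
  cd19[sel] <- 100 * stats::rbeta(sum(sel), 2, 2)
  rna_ok <- stats::runif(n) >= config$rna_fail_frac

  meta <- data.frame(sample_id = sample_ids, cohort = cohort,
                     compartment = groups, group = groups,
                     viability_pct = viability, cd19_pct = cd19,
                     rna_quality_ok = rna_ok,
                     donor_id = sprintf("D%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
  validate_sample_meta(meta)

  ct <- ct_matrix(m)
  if (config$missing_rate > 0)
    ct <- inject_missing(ct, config$missing_rate)

  off_mat <- as.matrix(pan[, paste0("offset_", names(gs)), drop = FALSE])
  rownames(off_mat) <- pan$gene
  instability <- pan$sigma + apply(off_mat, 1, stats::sd)
  truth <- list(
    panel = data.frame(gene = pan$gene, sigma = pan$sigma, off_mat,
                       instability = instability, check.names = FALSE,
                       stringsAsFactors = FALSE, row.names = NULL),
    target = config$target,
    loading_shifts = stats::setNames(u, sample_ids),
    stability_order = pan$gene[order(instability, pan$gene)],
    seed = as.integer(seed))
  list(ct = ct, meta = meta, truth = truth)
}

#' Mask Ct entries at random
#'
#' Each entry is masked independently with probability `rate`, emulating
#' undetected wells. Uses the current RNG stream (seed it, or pass `seed`).
#'
#' @param x a [ct_matrix()].
#' @param rate masking probability in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @param meta optional metadata; when given, a warning lists genes left
#'   with fewer than 2 observed values in any group.
#' @return a [ct_matrix()] with the realized number of masked entries in
#'   attribute `n_masked`.
#' @export
inject_missing <- function(x, rate, seed = NULL, meta = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (rate < 0 || rate > 0.5)
    stop("rate must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- x$ct
  if (rate > 0) {
    mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
    m[mask] <- NA_real_
  } else {
    mask <- matrix(FALSE, nrow(m), ncol(m))
  }
  out <- ct_matrix(m, efficiency = x$efficiency)
  attr(out, "n_masked") <- sum(mask)
  if (!is.null(meta)) {
    grp <- meta$group[match(colnames(m), meta$sample_id)]
    starved <- rownames(m)[vapply(rownames(m), function(g)
      any(tapply(!is.na(m[g, ]), grp, sum) < 2), logical(1))]
    if (length(starved))
      warning("gene(s) with fewer than 2 values in some group: ",
              paste(starved, collapse = ", "), call. = FALSE)
  }
  out
}
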