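#' Relative quantification by the 2^-ddCt method
#'
#' Quantifies a target gene relative to one or more reference genes,
#' calibrated to a control group. Per sample, the reference Ct is the
#' arithmetic mean of the reference genes' Ct values (equivalently the
#' geometric mean of their quantities); `dCt_s = Ct_target,s - refCt_s`;
#' `ddCt_s = dCt_s - mean(dCt over the calibrator group)` (default
#' `"group_mean"` calibration); and the relative quantity is
#' `RQ_s = 2^(-ddCt_s)`. Under mean-calibration the calibrator group's RQ
#' values have geometric mean 1. The alternative `"per_sample"` calibration
#' computes each sample's fold against every calibrator sample individually
#' and averages the folds.
#'
#' Per-sample loading shifts add the same constant to target and reference
#' Ct and cancel in `dCt`, so RQ is loading-invariant; what does *not*
#' cancel is any group-confounded or noisy behaviour of the chosen
#' reference, which is exactly the sensitivity this function exposes.
#'
#' @param x a [ct_matrix()] containing the target and reference genes.
#' @param target target gene id (must not be among the references).
#' @param references character vector of reference gene ids.
#' @param meta validated sample metadata.
#' @param calibrator_group level of `group_key` used as calibrator.
#' @param group_key metadata column defining groups.
#' @param compare length-2 character vector of group levels to contrast with
#'   the Mann-Whitney test; defaults to `c(<other>, calibrator_group)` when
#'   exactly two groups are present, otherwise no test is run.
#' @param calibration `"group_mean"` (default) or `"per_sample"`.
#' @return an object of class `ddct_result`: list with `samples`
#'   (data.frame `sample_id`, `group`, `delta_ct`, `rq`), `group_stats`
#'   (per-group `n`, `mean_rq`, `sd_rq`), `p_value` and `test_groups` (two-
#'   sided Mann-Whitney), `references`, `calibrator_group`, `calibration`,
#'   `excluded_samples` (samples missing target or reference Ct).
#' @export
delta_delta_ct <- function(x, target, references, meta, calibrator_group,
                           group_key = "group", compare = NULL,
                           calibration = c("group_mean", "per_sample")) {
  stopifnot(inherits(x, "ct_matrix"))
  calibration <- match.arg(calibration)
  validate_sample_meta(meta)
  if (target %in% references)
    stop("target must not be among the references", call. = FALSE)
  missing_genes <- setdiff(c(target, references), rownames(x$ct))
  if (length(missing_genes))
    stop("gene(s) not in Ct matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  grp <- meta[[group_key]][match(colnames(x$ct), meta$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata", call. = FALSE)
  if (!calibrator_group %in% grp)
    stop("calibrator group ", dQuote(calibrator_group),
         " has no samples", call. = FALSE)

  ref_ct <- colMeans(x$ct[references, , drop = FALSE])
  dct <- x$ct[target, ] - ref_ct
  ok <- !is.na(dct)
  excluded <- colnames(x$ct)[!ok]
  if (length(excluded))
    message(length(excluded), " sample(s) excluded (missing target or ",
            "reference Ct): ", paste(excluded, collapse = ", "))
  dct <- dct[ok]; grp <- grp[ok]

  cal <- dct[grp == calibrator_group]
  if (!length(cal))
    stop("calibrator group lost all samples to missing values", call. = FALSE)
  if (calibration == "group_mean") {
    rq <- 2^(-(dct - mean(cal)))
  } else {
    rq <- vapply(dct, function(d) mean(2^(-(d - cal))), numeric(1))
  }

  samples <- data.frame(sample_id = names(dct), group = grp,
                        delta_ct = unname(dct), rq = unname(rq),
                        stringsAsFactors = FALSE, row.names = NULL)
  gs <- do.call(rbind, lapply(split(samples, samples$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean_rq = mean(d$rq),
               sd_rq = stats::sd(d$rq), stringsAsFactors = FALSE)))
  rownames(gs) <- NULL

  p <- NA_real_; test_groups <- NULL
  if (is.null(compare)) {
    lev <- unique(grp)
    if (length(lev) == 2)
      compare <- c(setdiff(lev, calibrator_group), calibrator_group)
  }
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    a <- samples$rq[samples$group == compare[1]]
    b <- samples$rq[samples$group == compare[2]]
    if (length(a) >= 3 && length(b) >= 3) {
      mw <- mann_whitney(a, b)
      p <- mw$p_value
      test_groups <- compare
    }
  }
  structure(list(samples = samples, group_stats = gs, p_value = p,
                 test_groups = test_groups, references = references,
                 calibrator_group = calibrator_group,
                 calibration = calibration, excluded_samples = excluded),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> references: %s; calibrator: %s (%s)\n",
              paste(x$references, collapse = " + "), x$calibrator_group,
              x$calibration))
  gs <- x$group_stats
  gs$mean_rq <- signif(gs$mean_rq, 4); gs$sd_rq <- signif(gs$sd_rq, 4)
  print(gs, row.names = FALSE)
  if (!is.na(x$p_value))
    cat(sprintf("Mann-Whitney (%s vs %s): p = %.4g\n",
                x$test_groups[1], x$test_groups[2], x$p_value))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact-distribution p-value for small samples (both groups of size 8 or
#' fewer and no ties), normal approximation with tie correction otherwise.
#' When every value across both groups is identical the comparison is
#' degenerate: `p = 1` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors, each with at least 3 values.
#' @return list with `u` (U statistic for the first group), `p_value`,
#'   `exact`, `degenerate`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("both groups need at least 3 values", call. = FALSE)
  if (length(unique(c(a, b))) == 1)
    return(list(u = length(a) * length(b) / 2, p_value = 1,
                exact = FALSE, degenerate = TRUE))
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact, degenerate = FALSE)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' `length(groups) - 1` degrees of freedom. An input whose values are all
#' identical is degenerate: `H = 0`, `p = 1`, flagged.
#'
#' @param groups named list of numeric vectors (e.g. one gene's Ct values
#'   split by compartment); at least 2 groups of at least 2 values.
#' @return list with `h`, `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1)
    return(list(h = 0, df = length(groups) - 1L, p_value = 1,
                degenerate = TRUE))
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(vals, g)
  list(h = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, degenerate = FALSE)
}
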