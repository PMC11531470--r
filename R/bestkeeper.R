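#' BestKeeper descriptive stability statistics
#'
#' BestKeeper judges candidate references by the raw dispersion of their Ct
#' values and by how well each gene tracks the BestKeeper index, the
#' per-sample geometric mean Ct across all candidates. Unlike the delta-Ct,
#' geNorm and NormFinder statistics, raw Ct dispersion is *not* invariant to
#' per-sample loading shifts: a sample that received more RNA lowers every
#' gene's Ct and inflates every gene's SD. This is a documented contrast,
#' not a defect — BestKeeper deliberately measures total variation.
#'
#' Two dispersion flavours are offered: the sample standard deviation of Ct
#' (`"sd"`, the default) and the canonical BestKeeper mean absolute
#' deviation around the geometric mean Ct (`"mad"`).
#'
#' @param x a [ct_matrix()] with at least 2 genes and 3 samples; all Ct
#'   values must be strictly positive (geometric means).
#' @param dispersion `"sd"` or `"mad"`; the statistic used for ranking.
#' @return an object of class `bestkeeper_result`: list with
#'   * `genes`: data.frame of per-gene `n`, `geo_mean_ct`, `arith_mean_ct`,
#'     `min_ct`, `max_ct`, `sd_ct`, `mad_ct`, `cv_pct` (dispersion as % of
#'     the corresponding mean), `pearson_r` and `p_value` vs the index
#'     (`NA` with a `note` for constant genes), and `rank`;
#'   * `index`: named per-sample geometric mean Ct (samples complete in all
#'     genes only — the geometric mean is undefined with missing entries);
#'   * `dispersion`: the flavour used.
#' @export
bestkeeper_stats <- function(x, dispersion = c("sd", "mad")) {
  stopifnot(inherits(x, "ct_matrix"))
  dispersion <- match.arg(dispersion)
  m <- x$ct
  if (nrow(m) < 2) stop("BestKeeper needs at least 2 genes", call. = FALSE)
  if (ncol(m) < 3) stop("BestKeeper needs at least 3 samples", call. = FALSE)
  if (any(m[!is.na(m)] <= 0))
    stop("geometric means require strictly positive Ct values", call. = FALSE)

  complete <- colSums(is.na(m)) == 0
  index <- exp(colMeans(log(m[, complete, drop = FALSE])))

  per_gene <- lapply(rownames(m), function(g) {
    v <- m[g, ][!is.na(m[g, ])]
    gm <- exp(mean(log(v)))
    am <- mean(v)
    sdv <- stats::sd(v)
    madv <- mean(abs(v - gm))
    vi <- m[g, complete]
    note <- NA_character_
    if (length(vi) >= 3 && stats::sd(vi) > 0 && stats::sd(index) > 0) {
      htest <- stats::cor.test(vi, index, method = "pearson")
      r <- unname(htest$estimate); p <- htest$p.value
    } else {
      r <- NA_real_; p <- NA_real_
      note <- "correlation undefined (constant gene or index)"
    }
    data.frame(gene = g, n = length(v), geo_mean_ct = gm, arith_mean_ct = am,
               min_ct = min(v), max_ct = max(v), sd_ct = sdv, mad_ct = madv,
               cv_pct = if (dispersion == "sd") 100 * sdv / am
                        else 100 * madv / gm,
               pearson_r = r, p_value = p, note = note,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, per_gene)
  disp <- if (dispersion == "sd") genes$sd_ct else genes$mad_ct
  genes$rank <- rank(disp, ties.method = "average")
  genes <- genes[order(genes$rank, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, index = index, dispersion = dispersion),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat(sprintf("<bestkeeper_result> dispersion = %s, index over %d samples\n",
              x$dispersion, length(x$index)))
  df <- x$genes
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print(df[, setdiff(colnames(df), "note")], row.names = FALSE)
  invisible(x)
}
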