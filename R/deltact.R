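#' Pairwise delta-Ct statistics for all gene pairs
#'
#' The comparative delta-Ct method judges candidate references by how
#' consistently each pair of genes co-varies: for an ordered pair (a, b) the
#' per-sample difference `dCt_s = Ct_a,s - Ct_b,s` is formed over
#' pairwise-complete samples, and its mean and sample standard deviation
#' (n-1 denominator) are reported. A per-sample loading shift adds the same
#' constant to both genes of a sample and cancels in the difference, so the
#' statistics reflect relative (not absolute) stability.
#'
#' @param x a [ct_matrix()] with at least two genes.
#' @param include_self also emit the degenerate gene-vs-itself rows
#'   (mean 0, sd 0)? Default `FALSE`.
#' @return data.frame with one row per ordered pair: `gene_a`, `gene_b`,
#'   `n_samples` (pairwise-complete count), `mean_delta`, `sd_delta`
#'   (cycles), and `defined` (`FALSE` when fewer than 2 complete samples —
#'   such pairs are flagged, never silently dropped).
#' @seealso [deltact_scores()]
#' @export
pairwise_deltas <- function(x, include_self = FALSE) {
  stopifnot(inherits(x, "ct_matrix"))
  m <- x$ct
  genes <- rownames(m)
  if (length(genes) < 2 && !include_self)
    stop("need at least 2 genes", call. = FALSE)
  pairs <- expand.grid(gene_b = genes, gene_a = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[, c("gene_a", "gene_b")]
  if (!include_self) pairs <- pairs[pairs$gene_a != pairs$gene_b, ]
  stat <- function(a, b) {
    d <- m[a, ] - m[b, ]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2) c(n, NA_real_, NA_real_)
    else c(n, mean(d), stats::sd(d))
  }
  res <- t(mapply(stat, pairs$gene_a, pairs$gene_b))
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    n_samples = as.integer(res[, 1]),
                    mean_delta = res[, 2], sd_delta = res[, 3],
                    defined = res[, 1] >= 2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Delta-Ct stability scores from a pairwise table
#'
#' Aggregates a pairwise delta-Ct table into one score per gene: the
#' arithmetic mean of the SDs of its deltas against every other gene
#' ("mean STD"). The gene with the smallest mean STD is the most stable;
#' ranks ascend with the score and exact ties receive the average rank.
#'
#' @param pairs a data.frame as produced by [pairwise_deltas()] (columns
#'   `gene_a`, `gene_b`, `sd_delta`; self pairs, if present, are ignored).
#'   A hand-assembled table of published pairwise SDs works equally well.
#' @return data.frame with `gene`, `mean_sd` (cycles) and `rank`, ordered by
#'   rank.
#' @export
deltact_scores <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_a", "gene_b", "sd_delta") %in% colnames(pairs)))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  genes <- unique(pairs$gene_a)
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  # every gene must face every other gene with a defined sd
  for (g in genes) {
    partners <- pairs$gene_b[pairs$gene_a == g]
    miss <- setdiff(setdiff(genes, g), partners)
    if (length(miss))
      stop(sprintf("gene %s lacks pairs against: %s", g,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  undef <- is.na(pairs$sd_delta)
  if (any(undef))
    stop("undefined pair(s) (fewer than 2 complete samples): ",
         paste(sprintf("(%s, %s)", pairs$gene_a[undef], pairs$gene_b[undef]),
               collapse = ", "), call. = FALSE)
  mean_sd <- vapply(genes, function(g)
    mean(pairs$sd_delta[pairs$gene_a == g]), numeric(1))
  rk <- rank(mean_sd, ties.method = "average")
  out <- data.frame(gene = genes, mean_sd = unname(mean_sd), rank = unname(rk),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$gene), , drop = FALSE]
}
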