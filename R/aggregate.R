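#' Ranks from stability scores
#'
#' @param scores named numeric vector of per-gene stability scores.
#' @param ascending `TRUE` (default) when smaller scores mean more stable —
#'   rank 1 is then the smallest score. Exact ties receive the average of
#'   the ranks they cover.
#' @return named numeric vector of ranks.
#' @export
ranks_from_scores <- function(scores, ascending = TRUE) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("`scores` must be uniquely named by gene", call. = FALSE)
  bad <- names(scores)[!is.finite(scores)]
  if (length(bad))
    stop("missing/non-finite score for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rank(if (ascending) scores else -scores, ties.method = "average")
}

#' Comprehensive (RefFinder-style) rank aggregation
#'
#' Combines the per-method ranks of several stability methods into one
#' comprehensive score per gene: the geometric mean of its method ranks.
#' A gene ranked 1 by every method scores exactly 1; the score lies in
#' `[1, n_genes]`. Final ranks ascend with the score (average rank on ties).
#'
#' @param method_ranks named list, one element per method, each a named
#'   numeric vector of ranks covering the same gene set (e.g. from
#'   [ranks_from_scores()], or the tied-pair geNorm ranks of
#'   [genorm_rank()]).
#' @return an object of class `aggregate_ranking`: a data.frame with
#'   `gene`, one `rank_<method>` column per method, `comprehensive_score`
#'   and `final_rank`, ordered by final rank. The methods used are stored in
#'   the `methods` attribute.
#' @export
comprehensive_rank <- function(method_ranks) {
  if (!is.list(method_ranks) || is.null(names(method_ranks)))
    stop("`method_ranks` must be a named list of rank vectors", call. = FALSE)
  if (length(method_ranks) < 2)
    stop("configuration error: rank aggregation needs at least 2 methods",
         call. = FALSE)
  genes <- sort(names(method_ranks[[1]]))
  for (m in names(method_ranks)) {
    r <- method_ranks[[m]]
    if (is.null(names(r)) || !setequal(names(r), genes))
      stop("method ", m, " does not cover the same gene set", call. = FALSE)
    if (any(!is.finite(r)))
      stop("method ", m, " has missing ranks for: ",
           paste(names(r)[!is.finite(r)], collapse = ", "), call. = FALSE)
  }
  rank_mat <- vapply(method_ranks, function(r) r[genes],
                     numeric(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes),
                     dimnames = list(genes, names(method_ranks)))
  score <- exp(rowMeans(log(rank_mat)))
  out <- data.frame(gene = genes, rank_mat, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[-1] <- paste0("rank_", names(method_ranks))
  out$comprehensive_score <- unname(score)
  out$final_rank <- rank(score, ties.method = "average")
  out <- out[order(out$final_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "methods") <- names(method_ranks)
  class(out) <- c("aggregate_ranking", "data.frame")
  out
}

#' Run all stability methods and aggregate their rankings
#'
#' Convenience front door: runs any subset of the four stability methods on
#' one Ct matrix and combines them with [comprehensive_rank()]. geNorm's
#' tied final pair enters the aggregation as average rank 1.5 for both
#' genes; NormFinder runs grouped when `meta` and `group_key` identify at
#' least two groups and `grouped = TRUE`.
#'
#' @param x a [ct_matrix()].
#' @param meta sample metadata (needed for grouped NormFinder).
#' @param methods subset of `c("deltact", "genorm", "bestkeeper",
#'   "normfinder")`; at least two.
#' @param grouped run NormFinder in grouped mode?
#' @param group_key metadata column for grouping.
#' @param dispersion BestKeeper dispersion flavour, `"sd"` or `"mad"`.
#' @return list with one element per method (the method's full result
#'   object) plus `aggregate`, the [comprehensive_rank()] table.
#' @export
rank_references <- function(x, meta = NULL,
                            methods = c("deltact", "genorm", "bestkeeper",
                                        "normfinder"),
                            grouped = FALSE, group_key = "group",
                            dispersion = "sd") {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 2)
    stop("configuration error: need at least 2 methods to aggregate",
         call. = FALSE)
  out <- list()
  ranks <- list()
  if ("deltact" %in% methods) {
    sc <- deltact_scores(pairwise_deltas(x))
    out$deltact <- sc
    ranks$deltact <- stats::setNames(sc$rank, sc$gene)
  }
  if ("genorm" %in% methods) {
    gr <- genorm_rank(x)
    out$genorm <- gr
    ranks$genorm <- gr$ranks
  }
  if ("bestkeeper" %in% methods) {
    bk <- bestkeeper_stats(x, dispersion = dispersion)
    out$bestkeeper <- bk
    ranks$bestkeeper <- stats::setNames(bk$genes$rank, bk$genes$gene)
  }
  if ("normfinder" %in% methods) {
    nf <- normfinder_stability(x, meta = meta, grouped = grouped,
                               group_key = group_key)
    out$normfinder <- nf
    ranks$normfinder <- stats::setNames(nf$stability$rank, nf$stability$gene)
  }
  out$aggregate <- comprehensive_rank(ranks)
  out
}
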