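# NormFinder-style model-based stability.
#
# Model (log scale; Ct is already a log2 quantity, rescaled by log2(E) for
# non-perfect efficiencies): y_ij = alpha_i + beta_j + e_ij within a group,
# with Var(e_ij) = sigma2_i. Sample-centring removes beta_j; row-centring
# the remainder leaves residuals whose variance mixes sigma2_i with the
# other genes' noise:
#   E[s2_i] = sigma2_i * (1 - 2/k) + mean(sigma2)/k
# which inverts to the bias-corrected estimator used below. k > 2 genes are
# required for the inversion to exist.

.y_scale <- function(x) sweep(x$ct, 1, log2(x$efficiency), "*")

# core estimator on a complete numeric matrix (genes x samples)
.intragroup_var <- function(y) {
  k <- nrow(y); n <- ncol(y)
  if (k <= 2)
    stop("intragroup variance needs at least 3 genes (bias correction)",
         call. = FALSE)
  if (n < 2) stop("intragroup variance needs at least 2 samples", call. = FALSE)
  z <- sweep(y, 2, colMeans(y))        # remove per-sample shift
  r <- sweep(z, 1, rowMeans(z))        # remove per-gene level
  s2 <- rowSums(r^2) / (n - 1)
  est <- pmax(0, k / (k - 2) * (s2 - mean(s2) / (k - 1)))
  stats::setNames(est, rownames(y))   # pmax drops names from scalar arg
}

#' NormFinder intragroup variance
#'
#' Bias-corrected per-gene variance estimates for one homogeneous group of
#' samples under the additive log-scale model (see Details in
#' [normfinder_stability()]). Requires a complete Ct block; handle missing
#' values first via the `na_action` policy of [normfinder_stability()] or by
#' dropping incomplete samples with [subset_ct()].
#'
#' @param x a [ct_matrix()] restricted to one group; at least 3 genes and 2
#'   samples, no missing entries.
#' @return named per-gene variance estimates (squared cycles), floored at 0.
#' @export
intragroup_variance <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  if (anyNA(x$ct))
    stop("missing Ct entries: drop incomplete samples or impute first ",
         "(see na_action in normfinder_stability)", call. = FALSE)
  .intragroup_var(.y_scale(x))
}

#' NormFinder stability values
#'
#' Model-based stability under the additive log-scale model
#' `y_ij = alpha_i + beta_j + d_ig + e_ij`: per-sample shifts `beta_j`
#' (RNA loading) are removed by sample-centring; what remains per gene is
#' its intragroup noise `sigma2_ig` and, in grouped mode, a systematic
#' intergroup deviation `d_ig`. The stability value combines both so that a
#' gene must be quiet *and* unbiased across groups to rank well.
#'
#' Ungrouped: the stability value is simply `sqrt(sigma2_i)`.
#'
#' Grouped: `d_ig` is the group mean of the sample-centred values minus the
#' (equal-weight, or size-weighted) across-group mean; the intergroup
#' variance `gamma2` is estimated by method of moments — the dispersion of
#' `d_ig` across genes within each group minus the mean sampling variance
#' `sigma2_ig / n_g`, averaged over groups and floored at 0. The deviations
#' are shrunk toward 0 by `gamma2 / (gamma2 + sigma2_ig/n_g)` and the
#' stability value is
#' `rho_i = mean_g( |d~_ig| + sqrt( (sigma2_ig/n_g) * gamma2 / (gamma2 + sigma2_ig/n_g) ) )`.
#' When `gamma2 = 0` the deviations vanish and the ranking degenerates to
#' the pure intragroup ordering.
#'
#' @param x a [ct_matrix()], at least 3 genes.
#' @param meta sample metadata (required when `grouped = TRUE`).
#' @param grouped estimate intergroup deviations across the levels of
#'   `group_key`? Needs at least 2 groups with at least 2 samples each.
#' @param group_key metadata column defining groups.
#' @param weight_by_size weight groups by sample size instead of equally
#'   (both in the across-group mean and in `rho`)? Default `FALSE`.
#' @param na_action `"drop_samples"` (default; incomplete samples are
#'   dropped per group with a message) or `"impute"` (per-gene group-mean
#'   imputation).
#' @return an object of class `normfinder_result`: list with `stability`
#'   (data.frame `gene`, `rho`, `rank`), `sigma2` (genes x groups matrix),
#'   `d` and `d_shrunk` (genes x groups, grouped mode), `gamma2`, `grouped`,
#'   `groups` (sizes), `dropped_samples`.
#' @export
normfinder_stability <- function(x, meta = NULL, grouped = FALSE,
                                 group_key = "group",
                                 weight_by_size = FALSE,
                                 na_action = c("drop_samples", "impute")) {
  stopifnot(inherits(x, "ct_matrix"))
  na_action <- match.arg(na_action)
  genes <- rownames(x$ct)
  k <- length(genes)
  if (k <= 2)
    stop("NormFinder needs at least 3 genes", call. = FALSE)

  if (grouped) {
    if (is.null(meta)) stop("grouped mode requires `meta`", call. = FALSE)
    validate_sample_meta(meta)
    lev <- meta[[group_key]][match(colnames(x$ct), meta$sample_id)]
    if (anyNA(lev))
      stop("samples missing from metadata", call. = FALSE)
    groups <- split(colnames(x$ct), lev)
  } else {
    groups <- list(all = colnames(x$ct))
  }

  dropped <- character(0)
  blocks <- lapply(groups, function(s) {
    y <- .y_scale(x)[, s, drop = FALSE]
    if (anyNA(y)) {
      if (na_action == "drop_samples") {
        bad <- colnames(y)[colSums(is.na(y)) > 0]
        dropped <<- c(dropped, bad)
        y <- y[, setdiff(colnames(y), bad), drop = FALSE]
      } else {
        for (i in seq_len(nrow(y)))
          y[i, is.na(y[i, ])] <- mean(y[i, ], na.rm = TRUE)
      }
    }
    y
  })
  if (length(dropped))
    message(length(dropped), " incomplete sample(s) dropped: ",
            paste(dropped, collapse = ", "))
  n_g <- vapply(blocks, ncol, integer(1))
  if (grouped) {
    if (length(blocks) < 2)
      stop("grouped mode needs at least 2 groups", call. = FALSE)
    small <- names(blocks)[n_g < 2]
    if (length(small))
      stop("group(s) below minimum size (2): ",
           paste(small, collapse = ", "), call. = FALSE)
  } else if (n_g[1] < 2) {
    stop("need at least 2 complete samples", call. = FALSE)
  }

  sigma2 <- vapply(blocks, .intragroup_var, numeric(k))
  sigma2 <- matrix(sigma2, nrow = k, dimnames = list(genes, names(blocks)))

  if (!grouped) {
    rho <- sqrt(sigma2[, 1])
    st <- data.frame(gene = genes, rho = unname(rho),
                     rank = rank(rho, ties.method = "average"),
                     stringsAsFactors = FALSE)
    st <- st[order(st$rank, st$gene), ]; rownames(st) <- NULL
    return(structure(list(stability = st, sigma2 = sigma2, d = NULL,
                          d_shrunk = NULL, gamma2 = NA_real_,
                          grouped = FALSE, groups = n_g,
                          dropped_samples = dropped),
                     class = "normfinder_result"))
  }

  G <- length(blocks)
  w <- if (weight_by_size) n_g / sum(n_g) else rep(1 / G, G)
  # group means of sample-centred values
  zbar <- vapply(blocks, function(y) {
    z <- sweep(y, 2, colMeans(y))
    rowMeans(z)
  }, numeric(k))
  d <- zbar - drop(zbar %*% w)            # deviations, weighted-mean-centred

  samp_var <- sweep(sigma2, 2, n_g, "/")  # sigma2_ig / n_g
  # method-of-moments intergroup variance: dispersion of d across genes
  # minus its mean sampling variance, floored at 0 per group (a noisy
  # small-n group must not cancel real intergroup signal), then averaged
  per_group_moment <- vapply(seq_len(G), function(g)
    max(0, sum(d[, g]^2) / (k - 1) - mean(samp_var[, g])), numeric(1))
  gamma2 <- sum(w * per_group_moment)

  if (gamma2 > 0) {
    shrink <- gamma2 / (gamma2 + samp_var)
    d_shrunk <- d * shrink
    rho_terms <- abs(d_shrunk) + sqrt(samp_var * shrink)
    rho <- drop(rho_terms %*% w)
  } else {
    # no intergroup signal: deviations shrink to 0 and the ranking
    # degenerates to the pure-intragroup ordering
    d_shrunk <- d * 0
    rho <- drop(sqrt(samp_var) %*% w)
  }

  st <- data.frame(gene = genes, rho = unname(rho),
                   rank = rank(rho, ties.method = "average"),
                   stringsAsFactors = FALSE)
  st <- st[order(st$rank, st$gene), ]; rownames(st) <- NULL
  structure(list(stability = st, sigma2 = sigma2, d = d,
                 d_shrunk = d_shrunk, gamma2 = gamma2, grouped = TRUE,
                 groups = n_g, dropped_samples = dropped),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("<normfinder_result> %s, groups: %s\n",
              if (x$grouped) "grouped" else "ungrouped",
              paste(sprintf("%s (n=%d)", names(x$groups), x$groups),
                    collapse = ", ")))
  if (x$grouped) cat(sprintf("intergroup variance gamma2 = %.4g\n", x$gamma2))
  df <- x$stability
  df$rho <- signif(df$rho, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
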