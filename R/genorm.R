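# log2 relative quantities with per-gene minimum Ct as calibrator:
# q_is = (Ctmin_i - Ct_is) * log2(E_i).  The calibrator cancels in every
# ratio, so it affects nothing but the reported normalization factors.
.log2_quantity <- function(x) {
  m <- x$ct
  le <- log2(x$efficiency)
  qn <- sweep(-m, 1, apply(m, 1, min, na.rm = TRUE), "+")
  sweep(qn, 1, le, "*")
}

#' geNorm pairwise variation between two genes
#'
#' The geNorm building block: for genes j and k, the per-sample log2-ratio
#' of their relative quantities `A_jk,s = q_j,s - q_k,s` (at shared
#' efficiency 2 this equals `Ct_k,s - Ct_j,s`), and `V_jk` is its sample
#' standard deviation over pairwise-complete samples. Two genes carrying the
#' same biological signal have a constant ratio and `V_jk = 0`.
#'
#' @param x a [ct_matrix()].
#' @param j,k gene ids.
#' @return `V_jk`, a non-negative scalar (dimensionless log2 units).
#' @export
pairwise_variation <- function(x, j, k) {
  stopifnot(inherits(x, "ct_matrix"))
  bad <- setdiff(c(j, k), rownames(x$ct))
  if (length(bad))
    stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  q <- .log2_quantity(x)
  a <- q[j, ] - q[k, ]
  a <- a[!is.na(a)]
  if (length(a) < 2)
    stop(sprintf("pair (%s, %s) has fewer than 2 complete samples", j, k),
         call. = FALSE)
  stats::sd(a)
}

# full V matrix (NA diagonal), pairwise-complete samples
.v_matrix <- function(x) {
  q <- .log2_quantity(x)
  k <- nrow(q)
  V <- matrix(NA_real_, k, k, dimnames = list(rownames(q), rownames(q)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- q[i, ] - q[j, ]
    a <- a[!is.na(a)]
    if (length(a) < 2)
      stop(sprintf("pair (%s, %s) has fewer than 2 complete samples",
                   rownames(q)[i], rownames(q)[j]), call. = FALSE)
    V[i, j] <- V[j, i] <- stats::sd(a)
  }
  V
}

#' geNorm stability ranking
#'
#' Computes each gene's M-value — the mean of its pairwise variations
#' `V_jk` against all other retained genes — then iteratively excludes the
#' gene with the highest M and recomputes, until two genes remain. Those two
#' cannot be separated by the algorithm (their mutual ratio is all that is
#' left) and share the top rank. Ties at exclusion are broken by removing
#' the lexicographically smallest gene id; any tie-break taken is recorded.
#'
#' The optimal-reference-number statistic `V(n/n+1)` is the sample SD of
#' `log2(NF_n / NF_(n+1))`, where `NF_n` is the per-sample geometric mean of
#' the relative quantities of the n most stable genes. The conventional
#' V < 0.15 guideline is annotation only; nothing is enforced.
#'
#' @param x a [ct_matrix()] with at least 3 genes.
#' @return an object of class `genorm_result`: list with `m_values`
#'   (first-iteration M per gene), `m_at_exclusion` (M of each gene in the
#'   round it was excluded; for the final pair, their shared final M),
#'   `exclusion_order` (least stable first), `final_pair` (lexicographic),
#'   `ranks` (final pair tied at 1.5, then reverse exclusion order),
#'   `v_series` (named `V2/3`, `V3/4`, ...), `tie_breaks`.
#' @export
genorm_rank <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  genes <- rownames(x$ct)
  k <- length(genes)
  if (k < 3) stop("geNorm needs at least 3 genes", call. = FALSE)
  V <- .v_matrix(x)
  m_first <- rowMeans(V, na.rm = TRUE)

  retained <- genes
  exclusion_order <- character(0)
  m_at_exclusion <- stats::setNames(numeric(k), genes)
  tie_breaks <- character(0)
  while (length(retained) > 2) {
    M <- rowMeans(V[retained, retained, drop = FALSE], na.rm = TRUE)
    worst <- max(M)
    cand <- sort(names(M)[M >= worst - 1e-12])
    if (length(cand) > 1)
      tie_breaks <- c(tie_breaks,
                      sprintf("tie at M=%.6g among {%s}; excluded %s",
                              worst, paste(cand, collapse = ", "), cand[1]))
    drop_g <- cand[1]
    m_at_exclusion[drop_g] <- M[drop_g]
    exclusion_order <- c(exclusion_order, drop_g)
    retained <- setdiff(retained, drop_g)
  }
  final_pair <- sort(retained)
  m_final <- rowMeans(V[final_pair, final_pair, drop = FALSE], na.rm = TRUE)
  m_at_exclusion[final_pair] <- m_final

  # ranks: final pair tied (average of 1 and 2), then reverse exclusion
  ranks <- stats::setNames(numeric(k), genes)
  ranks[final_pair] <- 1.5
  ranks[rev(exclusion_order)] <- seq_along(exclusion_order) + 2

  # V(n/n+1) from normalization factors over the stability ordering
  stable_order <- c(final_pair, rev(exclusion_order))
  q <- .log2_quantity(x)
  complete <- colSums(is.na(q)) == 0
  v_series <- numeric(0)
  if (k >= 3 && sum(complete) >= 2) {
    qs <- q[, complete, drop = FALSE]
    log_nf <- function(n) colMeans(qs[stable_order[1:n], , drop = FALSE])
    v_series <- vapply(2:(k - 1), function(n)
      stats::sd(log_nf(n) - log_nf(n + 1)), numeric(1))
    names(v_series) <- sprintf("V%d/%d", 2:(k - 1), 3:k)
  }
  structure(list(m_values = m_first, m_at_exclusion = m_at_exclusion,
                 exclusion_order = exclusion_order, final_pair = final_pair,
                 ranks = ranks, v_series = v_series, tie_breaks = tie_breaks),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>\n")
  cat("final pair:", paste(x$final_pair, collapse = " + "), "\n")
  cat("exclusion order (least stable first):",
      paste(x$exclusion_order, collapse = " > "), "\n")
  cat("first-iteration M:\n")
  print(round(sort(x$m_values), 4))
  if (length(x$v_series)) {
    cat("pairwise variation V(n/n+1) (V < 0.15 is the conventional",
        "sufficient-references guideline, reported as annotation only):\n")
    print(round(x$v_series, 4))
  }
  invisible(x)
}
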