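# Fixture builders and independent brute-force oracles. The oracles are
# written as plain loops over the defining formulas, deliberately sharing no
# code with the package implementations they check.

make_ct <- function(m, efficiency = 2) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  ct_matrix(m, efficiency = efficiency)
}

random_ct <- function(k, n, seed, sd_range = c(0.3, 2)) {
  set.seed(seed)
  sds <- runif(k, sd_range[1], sd_range[2])
  m <- matrix(0, k, n)
  for (i in seq_len(k)) m[i, ] <- 20 + 2 * i + rnorm(n, 0, sds[i])
  make_ct(m)
}

# delta-Ct: loop over ordered pairs, pairwise-complete samples
brute_deltact <- function(m) {
  genes <- rownames(m)
  mean_sd <- numeric(0)
  for (g in genes) {
    sds <- c()
    for (h in setdiff(genes, g)) {
      d <- c()
      for (s in colnames(m))
        if (!is.na(m[g, s]) && !is.na(m[h, s])) d <- c(d, m[g, s] - m[h, s])
      sds <- c(sds, sd(d))
    }
    mean_sd[g] <- mean(sds)
  }
  mean_sd
}

# geNorm: naive recomputation of first-iteration M, exclusion order and
# final pair (ties broken by smallest gene id), at efficiency 2
brute_genorm <- function(m) {
  vjk <- function(a, b) {
    d <- c()
    for (s in colnames(m))
      if (!is.na(m[a, s]) && !is.na(m[b, s])) d <- c(d, m[b, s] - m[a, s])
    sd(d)
  }
  mval <- function(genes) {
    out <- c()
    for (g in genes) {
      vs <- c()
      for (h in setdiff(genes, g)) vs <- c(vs, vjk(g, h))
      out[g] <- mean(vs)
    }
    out
  }
  genes <- rownames(m)
  m_first <- mval(genes)
  order_out <- c()
  while (length(genes) > 2) {
    M <- mval(genes)
    worst <- sort(names(M)[abs(M - max(M)) < 1e-12])[1]
    order_out <- c(order_out, worst)
    genes <- setdiff(genes, worst)
  }
  list(m_first = m_first, exclusion_order = order_out,
       final_pair = sort(genes))
}

# NormFinder ungrouped: direct three-step formula, scalar loops
brute_normfinder_sigma2 <- function(y) {
  k <- nrow(y); n <- ncol(y)
  z <- y
  for (j in 1:n) z[, j] <- y[, j] - mean(y[, j])
  s2 <- numeric(k)
  for (i in 1:k) {
    r <- z[i, ] - mean(z[i, ])
    s2[i] <- sum(r^2) / (n - 1)
  }
  out <- numeric(k)
  for (i in 1:k) out[i] <- max(0, k / (k - 2) * (s2[i] - mean(s2) / (k - 1)))
  names(out) <- rownames(y)
  out
}

# rank oracle: sort-based with average ties
rank_oracle <- function(scores) {
  ord <- sort(scores)
  out <- numeric(length(scores))
  names(out) <- names(scores)
  for (g in names(scores))
    out[g] <- mean(which(ord == scores[g]))
  out
}

# exact two-sided Mann-Whitney by enumeration of all group assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mu <- n * (length(pooled) - n) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Kruskal-Wallis H by the rank-sum formula with tie correction
brute_kw_h <- function(groups) {
  vals <- unlist(groups)
  r <- rank(vals)
  N <- length(vals)
  sizes <- vapply(groups, length, integer(1))
  ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
  h <- 0
  for (g in seq_along(groups)) {
    rg <- sum(r[starts[g]:ends[g]])
    h <- h + rg^2 / sizes[[g]]
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  t_counts <- table(vals)
  h / (1 - sum(t_counts^3 - t_counts) / (N^3 - N))
}

# a deterministic small metadata fixture for QC tests
qc_meta_fixture <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:10),
    cohort = c(rep("pdx", 6), rep("cell_line", 2), rep("healthy_control", 2)),
    compartment = c(rep("spleen", 3), rep("bm", 3), rep("cell_line", 2),
                    rep("pbmc", 2)),
    group = c(rep("spleen", 3), rep("bm", 3), rep("cell_line", 2),
              rep("pbmc", 2)),
    viability_pct = c(30, 20, 80, 90, 26, 24, 95, 10, 70, 99),
    cd19_pct = c(70, 90, 55, 61, 60, 95, NA, NA, NA, NA),
    rna_quality_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, TRUE),
    donor_id = sprintf("d%02d", 1:10),
    stringsAsFactors = FALSE
  )
}
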