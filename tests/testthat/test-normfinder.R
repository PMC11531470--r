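test_that("intragroup variance vanishes for noiseless additive data", {
  shifts <- c(0, 1.5, -2, 0.5)
  m <- outer(c(20, 24, 28), rep(1, 4)) + outer(rep(1, 3), shifts)
  dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:4))
  expect_equal(unname(intragroup_variance(make_ct(m))), rep(0, 3))
})

test_that("estimator equals the direct three-step formula on integers", {
  m <- matrix(c(20, 22, 21, 23,
                25, 24, 26, 25,
                30, 31, 29, 32), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(intragroup_variance(make_ct(m)), brute_normfinder_sigma2(m))
  for (seed in 71:73) {
    x <- random_ct(5, 9, seed = seed)
    expect_equal(intragroup_variance(x), brute_normfinder_sigma2(x$ct))
  }
})

test_that("estimator preconditions are enforced by name", {
  x <- random_ct(2, 5, seed = 74)
  expect_error(intragroup_variance(x), "at least 3 genes")
  y <- random_ct(4, 5, seed = 75)
  y$ct[1, 2] <- NA
  expect_error(intragroup_variance(ct_matrix(y$ct)), "na_action")
})

test_that("variance recovery is unbiased under the additive model", {
  # moderate-size check; the full k=6, n=50, 500-replicate calibration runs
  # with the cohort-level recovery suite
  k <- 6; n <- 40; reps <- 200
  sig <- seq(0.3, 1.3, length.out = k)
  set.seed(81)
  est <- matrix(0, reps, k)
  for (r in 1:reps) {
    m <- 22 + matrix(rnorm(k * n, sd = sig), k, n) +
      outer(rep(1, k), rnorm(n, 0, 1))
    dimnames(m) <- list(paste0("g", 1:k), paste0("s", 1:n))
    est[r, ] <- intragroup_variance(make_ct(m))
  }
  z <- (colMeans(est) - sig^2) / (apply(est, 2, sd) / sqrt(reps))
  expect_true(all(abs(z) < 3))
})

test_that("ungrouped stability is sqrt(sigma2) with oracle-matched ranking", {
  x <- random_ct(5, 10, seed = 82)
  nf <- normfinder_stability(x)
  o <- sqrt(brute_normfinder_sigma2(x$ct))
  expect_equal(setNames(nf$stability$rho, nf$stability$gene)[names(o)], o)
  expect_equal(setNames(nf$stability$rank, nf$stability$gene)[names(o)],
               rank_oracle(o))
})

test_that("outputs are invariant to sample shifts and equivariant to gene order", {
  x <- random_ct(5, 8, seed = 83)
  shifted <- ct_matrix(pmin(pmax(sweep(x$ct, 2, rnorm(8, 0, 2), "+"), 0), 50))
  expect_equal(normfinder_stability(x)$stability,
               normfinder_stability(shifted)$stability)
  perm <- subset_ct(x, genes = rev(rownames(x$ct)))
  a <- normfinder_stability(x)$stability
  b <- normfinder_stability(perm)$stability
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)
})

test_that("deviation contrasts are centred and shrinkage behaves at limits", {
  pan <- default_panel()
  pan$sigma <- rep(0.5, 6)
  pan[, grep("offset_", names(pan))] <- 0
  pan$offset_bm[6] <- 2
  cfg <- sim_config(group_sizes = c(bm = 20, pbmc = 20), panel = pan,
                    target = NULL, qc_fail_frac = 0)
  sim <- simulate_cohort(cfg, seed = 90)
  nf <- normfinder_stability(sim$ct, sim$meta, grouped = TRUE)
  expect_equal(unname(colSums(nf$d)), c(0, 0))        # per-group gene sum
  expect_equal(unname(rowSums(nf$d)), rep(0, 6))      # per-gene group sum
  expect_true(all(abs(nf$d_shrunk) <= abs(nf$d) + 1e-12))
  expect_true(nf$gamma2 > 0)

  # two identical groups, no group effect: deviations shrink toward zero and
  # the grouped ranking matches the ungrouped one
  pan0 <- pan
  pan0$offset_bm <- 0
  pan0$sigma <- seq(0.3, 1.3, length.out = 6)  # well-separated ordering
  cfg0 <- sim_config(group_sizes = c(bm = 60, pbmc = 60), panel = pan0,
                     target = NULL, qc_fail_frac = 0)
  sim0 <- simulate_cohort(cfg0, seed = 91)
  g0 <- normfinder_stability(sim0$ct, sim0$meta, grouped = TRUE)
  u0 <- normfinder_stability(sim0$ct)
  expect_lt(max(abs(g0$d_shrunk)), 0.2)
  expect_equal(g0$stability$gene, u0$stability$gene)
})

test_that("a gene with a +2-cycle effect in one group ranks last when grouped", {
  pan <- default_panel()
  pan$sigma <- rep(0.5, 6)
  pan[, grep("offset_", names(pan))] <- 0
  pan$offset_bm[6] <- 2
  hits <- 0
  for (i in 1:100) {
    cfg <- sim_config(group_sizes = c(bm = 20, pbmc = 20), panel = pan,
                      target = NULL, qc_fail_frac = 0)
    sim <- simulate_cohort(cfg, seed = 3000 + i)
    nf <- normfinder_stability(sim$ct, sim$meta, grouped = TRUE)
    hits <- hits + (nf$stability$gene[6] == pan$gene[6])
  }
  expect_gte(hits, 95)
})

test_that("grouped stability tracks designed instability |d| + sigma", {
  pan <- default_panel()
  pan$sigma <- c(0.2, 0.6, 0.4, 1.0, 0.6, 1.2)
  pan[, grep("offset_", names(pan))] <- 0
  d1 <- c(0, 0, 1.2, -1.2, 2.4, -2.4)
  pan$offset_bm <- d1
  pan$offset_pbmc <- -d1
  truth <- abs(d1) + pan$sigma
  sp <- numeric(100)
  for (i in 1:100) {
    cfg <- sim_config(group_sizes = c(bm = 30, pbmc = 30), panel = pan,
                      target = NULL, qc_fail_frac = 0)
    sim <- simulate_cohort(cfg, seed = 4000 + i)
    nf <- normfinder_stability(sim$ct, sim$meta, grouped = TRUE)
    rho <- nf$stability$rho[match(pan$gene, nf$stability$gene)]
    sp[i] <- cor(truth, rho, method = "spearman")
  }
  expect_gte(mean(sp), 0.9)
})

test_that("missing-data policies drop or impute as configured", {
  x <- random_ct(4, 8, seed = 95)
  x$ct[2, 3] <- NA
  x <- ct_matrix(x$ct)
  expect_message(nf <- normfinder_stability(x), "dropped")
  expect_equal(unname(nf$groups), 7L)
  nf2 <- normfinder_stability(x, na_action = "impute")
  expect_equal(unname(nf2$groups), 8L)
})
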