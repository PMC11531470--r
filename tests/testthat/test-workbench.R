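wb_inputs <- function(seed = 171) {
  sim <- simulate_cohort(sim_config(), seed = seed)
  list(sim = sim, panel = sim$truth$panel$gene)
}

test_that("rank bundle contains all method tables, aggregate and log", {
  w <- wb_inputs()
  out <- file.path(tempfile(), "bundle")
  res <- run_rank(w$sim$ct, w$sim$meta, out, genes = w$panel)
  expect_length(res$failures, 0)
  for (f in c("deltact_scores.tsv", "deltact_pairs.tsv", "genorm.tsv",
              "genorm_v.tsv", "bestkeeper.tsv", "normfinder.tsv",
              "aggregate.tsv", "qc_exclusions.tsv", "run_log.txt",
              "MANIFEST"))
    expect_true(file.exists(file.path(out, f)), label = f)
  man <- readLines(file.path(out, "MANIFEST"))
  expect_true(all(grepl("\tok$", man)))
  agg <- read.delim(file.path(out, "aggregate.tsv"), check.names = FALSE)
  expect_setequal(agg$gene, w$panel)
  # QC-excluded samples do not enter the analysis
  log <- readLines(file.path(out, "run_log.txt"))
  excl <- res$qc$excluded$sample_id
  if (length(excl)) {
    pairs <- read.delim(file.path(out, "deltact_pairs.tsv"))
    expect_lte(max(pairs$n_samples), nrow(w$sim$meta) - length(excl))
  }
  expect_true(any(grepl("^qc:", log)))
})

test_that("fewer than two methods is refused as a configuration error", {
  w <- wb_inputs()
  expect_error(run_rank(w$sim$ct, w$sim$meta, tempfile(),
                        methods = "deltact"),
               "configuration error")
})

test_that("a failing method is recorded while the rest of the bundle lands", {
  w <- wb_inputs()
  tiny <- subset_ct(w$sim$ct, genes = w$panel[1:2])  # genorm needs >= 3
  out <- tempfile()
  res <- run_rank(tiny, w$sim$meta, out,
                  methods = c("deltact", "genorm", "bestkeeper"))
  expect_true("genorm" %in% res$failures)
  man <- readLines(file.path(out, "MANIFEST"))
  expect_true(any(grepl("genorm.tsv\tFAILED", man)))
  expect_true(file.exists(file.path(out, "deltact_scores.tsv")))
})

test_that("identical config and seed reproduce a byte-identical bundle", {
  digest_dir <- function(d) {
    fs <- sort(list.files(d, recursive = TRUE))
    vapply(fs, function(f)
      paste(as.character(tools::md5sum(file.path(d, f))), collapse = ""),
      character(1))
  }
  out1 <- tempfile(); out2 <- tempfile()
  for (out in c(out1, out2)) {
    sim <- simulate_cohort(sim_config(), seed = 99)
    run_rank(sim$ct, sim$meta, out, genes = sim$truth$panel$gene,
             grouped = TRUE)
    run_express(sim$ct, sim$meta, file.path(out, "express"),
                target = "miR-181a-like",
                reference_sets = list(stable = "miR-532-like",
                                      pair = c("miR-532-like",
                                               "miR-103a-like"),
                                      confounded = "SNORD44-like",
                                      noisy = "5sRNA-like"),
                calibrator_group = "pbmc", compare = c("bm", "pbmc"))
  }
  d1 <- digest_dir(out1); d2 <- digest_dir(out2)
  expect_identical(names(d1), names(d2))
  expect_identical(unname(d1), unname(d2))
})

test_that("express bundle sweeps reference sets and reports group stats", {
  w <- wb_inputs()
  out <- tempfile()
  panels <- run_express(w$sim$ct, w$sim$meta, out,
                        target = "miR-181a-like",
                        reference_sets = list(stable = "miR-532-like",
                                              noisy = "5sRNA-like"),
                        calibrator_group = "pbmc", compare = c("bm", "pbmc"))
  expect_named(panels, c("stable", "noisy"))
  expect_true(file.exists(file.path(out, "rq_stable.tsv")))
  js <- jsonlite::read_json(file.path(out, "express_summary.json"))
  expect_equal(js$target, "miR-181a-like")
  sd_bm <- function(p) {
    gs <- p$group_stats
    gs$sd_rq[gs$group == "bm"]
  }
  expect_gt(sd_bm(panels$noisy), sd_bm(panels$stable))
  expect_error(run_express(w$sim$ct, w$sim$meta, tempfile(),
                           target = "nope", reference_sets = "miR-532-like",
                           calibrator_group = "pbmc"),
               "nope")
})
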