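#' Construct a Ct matrix
#'
#' A `ct_matrix` holds quantification-cycle (Ct) values for a panel of
#' candidate reference genes measured across a cohort of samples, together
#' with per-gene amplification efficiencies. It is the single input type
#' consumed by all stability methods in this package.
#'
#' @param ct numeric matrix of Ct values, genes in rows and samples in
#'   columns, with row and column names. Entries may be `NA` (undetected
#'   wells); present values must be finite and lie in `[0, 50]` cycles.
#' @param efficiency per-gene amplification efficiency, a single number or a
#'   vector (optionally named by gene) recycled across genes. Must lie in
#'   `(1, 2]`; 2 means perfect doubling per cycle.
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (the numeric matrix) and `efficiency` (named per-gene vector).
#' @examples
#' m <- matrix(c(20, 21, 19.5, NA), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ct_matrix(m)
#' @export
ct_matrix <- function(ct, efficiency = 2) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "),
         call. = FALSE)
  vals <- ct[!is.na(ct)]
  if (any(!is.finite(vals)))
    stop("Ct values must be finite or NA", call. = FALSE)
  if (any(vals < 0 | vals > 50))
    stop("Ct values must lie within [0, 50] cycles", call. = FALSE)
  k <- nrow(ct)
  if (length(efficiency) == 1L) efficiency <- rep(efficiency, k)
  if (length(efficiency) != k)
    stop("`efficiency` must have length 1 or one value per gene", call. = FALSE)
  if (any(!is.finite(efficiency)) || any(efficiency <= 1) || any(efficiency > 2))
    stop("amplification efficiencies must lie in (1, 2]", call. = FALSE)
  names(efficiency) <- rownames(ct)
  structure(list(ct = ct, efficiency = efficiency), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d genes x %d samples, %d missing\n",
              nrow(x$ct), ncol(x$ct), sum(is.na(x$ct))))
  cat("genes:  ", paste(utils::head(rownames(x$ct), 8), collapse = ", "),
      if (nrow(x$ct) > 8) ", ..." else "", "\n", sep = "")
  cat("samples:", paste(utils::head(colnames(x$ct), 8), collapse = ", "),
      if (ncol(x$ct) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Gene and sample ids of a Ct matrix
#' @param x a [ct_matrix()].
#' @return character vector of labels.
#' @export
gene_ids <- function(x) rownames(x$ct)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$ct)

# tokens treated as a missing Ct value in input files
.missing_tokens <- c("NA", "", "Undetermined", "undetermined")

#' Read a Ct table from delimited text
#'
#' Two dialects are supported. `wide`: a header row of sample ids with the
#' first column holding gene ids (header `gene`), one row per gene. `long`:
#' columns `gene`, `sample`, `ct`, one record per well. The tokens `"NA"`,
#' `""` and `"Undetermined"` are read as missing values. The field separator
#' is inferred from the file extension (`.csv` = comma, otherwise tab)
#' unless given.
#'
#' @param path path to the delimited text file.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field separator; default inferred from the extension.
#' @param efficiency passed to [ct_matrix()].
#' @return a validated [ct_matrix()]. Gene/sample order follows first
#'   appearance in the file.
#' @export
read_ct_table <- function(path, dialect = c("wide", "long"), sep = NULL,
                          efficiency = 2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = character(0))
  parse_num <- function(tok, where) {
    out <- rep(NA_real_, length(tok))
    tok <- trimws(tok)
    keep <- !is.na(tok) & !(tok %in% .missing_tokens)
    suppressWarnings(num <- as.numeric(tok[keep]))
    if (any(is.na(num))) {
      bad <- which(keep)[which(is.na(num))[1]]
      stop(sprintf("non-numeric Ct token %s at %s", dQuote(tok[bad]),
                   where(bad)), call. = FALSE)
    }
    out[keep] <- num
    out
  }
  if (dialect == "wide") {
    genes <- trimws(raw[[1]])
    if (anyDuplicated(genes))
      stop("duplicate gene ids in file: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           call. = FALSE)
    samples <- colnames(raw)[-1]
    if (anyDuplicated(samples))
      stop("duplicate sample ids in file: ",
           paste(unique(samples[duplicated(samples)]), collapse = ", "),
           call. = FALSE)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      jj <- j  # freeze for the error locator
      m[, j] <- parse_num(raw[[j + 1]], function(i)
        sprintf("row %d, column %s", i + 1L, dQuote(samples[jj])))
    }
    ct_matrix(m, efficiency = efficiency)
  } else {
    need <- c("gene", "sample", "ct")
    if (!all(need %in% colnames(raw)))
      stop("long dialect requires columns gene, sample, ct", call. = FALSE)
    g <- trimws(raw$gene); s <- trimws(raw$sample)
    if (anyDuplicated(paste(g, s, sep = "\r")))
      stop("duplicate (gene, sample) records in long file", call. = FALSE)
    v <- parse_num(raw$ct, function(i) sprintf("row %d, column \"ct\"", i + 1L))
    genes <- unique(g); samples <- unique(s)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(g, genes), match(s, samples))] <- v
    ct_matrix(m, efficiency = efficiency)
  }
}

#' Write a Ct table to delimited text
#'
#' Inverse of [read_ct_table()]; values are written at full precision
#' (17 significant digits) so that a read/write/read cycle is bit-identical.
#'
#' @param x a [ct_matrix()].
#' @param path output path; `.csv` extension selects comma separation.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field separator; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, dialect = c("wide", "long"), sep = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  if (dialect == "wide") {
    df <- data.frame(gene = rownames(x$ct),
                     apply(x$ct, 2, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", colnames(x$ct))
  } else {
    idx <- expand.grid(gene = rownames(x$ct), sample = colnames(x$ct),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(gene = idx$gene, sample = idx$sample,
                     ct = fmt(x$ct[cbind(idx$gene, idx$sample)]),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cohort_levels <- c("cell_line", "pdx", "healthy_control")
.compartment_levels <- c("spleen", "bm", "cns", "pbmc", "cell_line")

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata contract used throughout the package:
#' columns `sample_id`, `cohort` (cell_line / pdx / healthy_control),
#' `compartment` (spleen / bm / cns / pbmc / cell_line), `group`,
#' `viability_pct`, `cd19_pct` (may be `NA` for non-PDX samples),
#' `rna_quality_ok`, `donor_id`.
#'
#' @param meta a data.frame of per-sample metadata.
#' @return `meta`, invisibly, after validation.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "cohort", "compartment", "group", "viability_pct",
            "cd19_pct", "rna_quality_ok", "donor_id")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (!all(meta$cohort %in% .cohort_levels))
    stop("cohort must be one of: ", paste(.cohort_levels, collapse = ", "),
         call. = FALSE)
  if (!all(meta$compartment %in% .compartment_levels))
    stop("compartment must be one of: ",
         paste(.compartment_levels, collapse = ", "), call. = FALSE)
  pct_ok <- function(v) all(is.na(v) | (v >= 0 & v <= 100))
  if (!pct_ok(meta$viability_pct) || !pct_ok(meta$cd19_pct))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  if (!is.logical(meta$rna_quality_ok))
    stop("rna_quality_ok must be logical", call. = FALSE)
  invisible(meta)
}

#' Read sample metadata from delimited text
#'
#' @param path path to a TSV/CSV with the columns described in
#'   [validate_sample_meta()].
#' @param sep field separator; default inferred from the extension.
#' @return a validated data.frame.
#' @export
read_sample_meta <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  meta <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, quote = "\"",
                            na.strings = c("NA", ""))
  meta$rna_quality_ok <- as.logical(meta$rna_quality_ok)
  validate_sample_meta(meta)
  meta
}

#' Cohort quality-control filtering
#'
#' Partitions samples into kept and excluded sets. A sample is kept iff its
#' viability exceeds `min_viability`, its human-CD19 positivity exceeds
#' `min_cd19` (this criterion applies to PDX samples only; cell lines and
#' healthy-control PBMCs are not CD19-gated), and — when `require_rna_ok` —
#' its RNA quality flag is `TRUE`. Each excluded sample is annotated with the
#' first criterion it failed, tested in the order viability, CD19, RNA.
#'
#' @param meta validated sample metadata (see [validate_sample_meta()]).
#' @param min_viability viability threshold in percent (default 25; samples
#'   must be strictly above it).
#' @param min_cd19 CD19 threshold in percent for PDX samples (default 60,
#'   strict).
#' @param require_rna_ok drop samples whose RNA quality flag is `FALSE`?
#' @return a list with `kept` (character vector of sample ids, input order)
#'   and `excluded` (data.frame with `sample_id`, `reason`).
#' @export
qc_filter <- function(meta, min_viability = 25, min_cd19 = 60,
                      require_rna_ok = TRUE) {
  validate_sample_meta(meta)
  stopifnot(min_viability >= 0, min_viability <= 100,
            min_cd19 >= 0, min_cd19 <= 100)
  if (any(is.na(meta$viability_pct)))
    stop("missing viability_pct for sample(s): ",
         paste(meta$sample_id[is.na(meta$viability_pct)], collapse = ", "),
         call. = FALSE)
  is_pdx <- meta$cohort == "pdx"
  if (any(is_pdx & is.na(meta$cd19_pct)))
    stop("missing cd19_pct for PDX sample(s): ",
         paste(meta$sample_id[is_pdx & is.na(meta$cd19_pct)], collapse = ", "),
         call. = FALSE)
  reason <- rep(NA_character_, nrow(meta))
  fail_v <- !(meta$viability_pct > min_viability)
  fail_c <- is_pdx & !(meta$cd19_pct > min_cd19)
  fail_r <- require_rna_ok & !meta$rna_quality_ok
  reason[fail_r] <- "rna_quality"
  reason[fail_c] <- "cd19"
  reason[fail_v] <- "viability"   # earliest criterion wins
  kept <- meta$sample_id[is.na(reason)]
  excluded <- data.frame(sample_id = meta$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}

#' Subset a Ct matrix by gene and sample labels
#'
#' @param x a [ct_matrix()].
#' @param genes,samples labels to keep (default: all). Selection is
#'   order-preserving with respect to the requested labels.
#' @return a [ct_matrix()].
#' @export
subset_ct <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(genes)) genes <- rownames(x$ct)
  if (is.null(samples)) samples <- colnames(x$ct)
  bad_g <- setdiff(genes, rownames(x$ct))
  if (length(bad_g))
    stop("unknown gene(s): ", paste(bad_g, collapse = ", "), call. = FALSE)
  bad_s <- setdiff(samples, colnames(x$ct))
  if (length(bad_s))
    stop("unknown sample(s): ", paste(bad_s, collapse = ", "), call. = FALSE)
  ct_matrix(x$ct[genes, samples, drop = FALSE],
            efficiency = x$efficiency[genes])
}

#' Split a Ct matrix by a metadata key
#'
#' Partitions the samples of `x` according to a metadata column (e.g.
#' `compartment` or `group`) and returns one Ct matrix per level.
#'
#' @param x a [ct_matrix()].
#' @param meta validated sample metadata covering every sample of `x`.
#' @param key metadata column to split on.
#' @return named list of [ct_matrix()] objects, one per level (level order =
#'   first appearance among the samples of `x`).
#' @export
group_split_ct <- function(x, meta, key = "group") {
  stopifnot(inherits(x, "ct_matrix"))
  validate_sample_meta(meta)
  if (!key %in% colnames(meta))
    stop("unknown metadata key: ", key, call. = FALSE)
  s <- colnames(x$ct)
  miss <- setdiff(s, meta$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lev <- meta[[key]][match(s, meta$sample_id)]
  out <- lapply(unique(lev), function(l) subset_ct(x, samples = s[lev == l]))
  names(out) <- unique(lev)
  out
}
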