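as_keys <- function(x, class_filter = NULL) {
  if (is.character(x)) return(unique(x))
  if (inherits(x, "rp_callset")) x <- pass_calls(x, class_filter)
  unique(variant_key(as.data.frame(x)))
}

key_position <- function(keys) sub("^([^:]+:[0-9]+):.*$", "\\1", keys)

as_positions <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(unique(x))
  unique(paste(x$chrom, x$pos, sep = ":"))
}

#' Confusion counts of a call set against a truth set
#'
#' Counts true positives (PASS calls matching a truth variant on chromosome,
#' position and trimmed alleles), false positives (PASS calls not in the
#' truth) and false negatives (truth variants not recovered). When a
#' comparable-position universe is supplied -- the positions covered on both
#' the call side and the truth side -- the counts are computed only over it,
#' so that a truth variant at a position the cell never covered does not count
#' against the caller. True negatives are reported only in that case (the
#' comparable positions with neither a call nor a truth variant); without an
#' explicit universe scRNA-seq has no natural TN denominator and `tn` is `NA`.
#'
#' @param calls an `rp_callset`, a data.frame of calls, or variant keys.
#' @param truth truth variants: `rp_truth_set`, data.frame, or variant keys.
#' @param comparable optional position universe: a data.frame with
#'   `chrom`/`pos` or a character vector of `"chrom:pos"`.
#' @param class_filter optional call classes to restrict to.
#' @return an object of class `rp_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(calls, truth, comparable = NULL, class_filter = NULL) {
  ck <- as_keys(calls, class_filter)
  tk <- as_keys(truth)
  cmp <- as_positions(comparable)
  if (!is.null(cmp)) {
    ck <- ck[key_position(ck) %in% cmp]
    tk <- tk[key_position(tk) %in% cmp]
  }
  tp <- sum(ck %in% tk)
  fp <- length(ck) - tp
  fn <- sum(!tk %in% ck)
  tn <- if (is.null(cmp)) NA_integer_ else
    length(cmp) - length(unique(key_position(union(ck, tk))))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "rp_confusion")
}

#' @export
print.rp_confusion <- function(x, ...) {
  cat("<rp_confusion> TP=", x$tp, " FP=", x$fp, " FN=", x$fn,
      " TN=", ifelse(is.na(x$tn), "NA", x$tn), "\n", sep = "")
  invisible(x)
}

ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Sensitivity, positive predictive value and false discovery rate
#'
#' `sensitivity = TP / (TP + FN)`, `ppv = TP / (TP + FP)`, `fdr = 1 - ppv`.
#' A zero denominator yields `NA` with a warning rather than 0.
#'
#' @param x an `rp_confusion`.
#' @return a single numeric value.
#' @export
sensitivity <- function(x) ratio_or_na(x$tp, x$tp + x$fn, "sensitivity")

#' @rdname sensitivity
#' @export
ppv <- function(x) ratio_or_na(x$tp, x$tp + x$fp, "PPV")

#' @rdname sensitivity
#' @export
fdr <- function(x) 1 - ppv(x)

#' Pairwise variant overlap between cells
#'
#' All-to-all comparison of per-cell call sets: one row per unordered pair
#' (`n * (n - 1) / 2` rows), with the shared variant count and the Jaccard
#' fraction `|A intersect B| / |A union B|` (0 when both sets are empty).
#' Isogenic cells should share most of their variants, so consistently high
#' overlap indicates a caller that is not just sampling noise.
#'
#' @param callsets named list of per-cell call sets (`rp_callset` objects or
#'   variant-key vectors).
#' @param class_filter optional classes to restrict `rp_callset` inputs to.
#' @return data.frame with columns `cell_a`, `cell_b`, `shared`, `fraction`;
#'   attribute `denominator = "jaccard"`.
#' @export
pairwise_overlap <- function(callsets, class_filter = NULL) {
  stopifnot(length(callsets) >= 2)
  keys <- lapply(callsets, as_keys, class_filter = class_filter)
  ids <- names(keys)
  if (is.null(ids)) ids <- paste0("cell", seq_along(keys))
  pairs <- utils::combn(length(keys), 2)
  shared <- integer(ncol(pairs)); frac <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- keys[[pairs[1, j]]]; b <- keys[[pairs[2, j]]]
    s <- length(intersect(a, b)); u <- length(union(a, b))
    shared[j] <- s
    frac[j] <- if (u == 0) 0 else s / u
  }
  structure(data.frame(cell_a = ids[pairs[1, ]], cell_b = ids[pairs[2, ]],
                       shared = shared, fraction = frac,
                       stringsAsFactors = FALSE),
            denominator = "jaccard")
}

#' Ensemble intersection of caller outputs
#'
#' Keeps the variants reported by at least `min_support` of the supplied call
#' sets -- the consensus rule used to build a trustworthy reference list from
#' several independent callers.
#'
#' @param vcfs list of variant-key vectors (or objects coercible via the same
#'   rules as [confusion()]); at least `min_support` sets.
#' @param min_support minimum number of supporting sets (default 2).
#' @return character vector of kept variant keys.
#' @export
ensemble_intersection <- function(vcfs, min_support = 2L) {
  if (length(vcfs) < min_support) {
    stop("need at least min_support = ", min_support, " call sets, got ",
         length(vcfs))
  }
  keys <- lapply(vcfs, as_keys)
  counts <- table(unlist(keys))
  sort(names(counts)[counts >= min_support])
}

#' Per-cell quality-control filter
#'
#' Flags cells for removal when (i) their percentage of reads aligned outside
#' exons exceeds the median across cells by more than `sd_mult` standard
#' deviations, (ii) their log-scaled expression profile does not correlate
#' with the pooled profile (Pearson correlation p-value above `cor_alpha`),
#' or (iii) their read count falls below `min_reads`. With fewer than three
#' cells the median/SD rule is undefined and QC is skipped with a warning.
#'
#' @param metrics data.frame with columns `cell`, `outside_exon_pct` and
#'   optionally `read_count`.
#' @param expr optional expression matrix (features x cells, columns named as
#'   in `metrics$cell`).
#' @param pooled optional pooled reference profile; defaults to the row means
#'   of `expr`.
#' @param min_reads read-count floor (default 0: disabled).
#' @param sd_mult multiplier on the standard deviation for the outside-exon
#'   rule (default 1).
#' @param cor_alpha p-value above which a cell is considered uncorrelated
#'   (default 0.05).
#' @return data.frame with columns `cell`, `keep`, `reasons` (comma-joined
#'   among `"outside-exons"`, `"correlation"`, `"read-count"`).
#' @export
cell_qc <- function(metrics, expr = NULL, pooled = NULL, min_reads = 0,
                    sd_mult = 1, cor_alpha = 0.05) {
  stopifnot(all(c("cell", "outside_exon_pct") %in% names(metrics)))
  n <- nrow(metrics)
  reasons <- vector("list", n)
  if (n < 3) {
    warning("fewer than 3 cells: QC skipped, all cells kept")
    return(data.frame(cell = metrics$cell, keep = TRUE, reasons = "",
                      stringsAsFactors = FALSE))
  }
  cut_oe <- stats::median(metrics$outside_exon_pct) +
    sd_mult * stats::sd(metrics$outside_exon_pct)
  for (i in seq_len(n)) {
    r <- character()
    if (metrics$outside_exon_pct[i] > cut_oe) r <- c(r, "outside-exons")
    if (!is.null(expr)) {
      prof <- expr[, metrics$cell[i]]
      ref <- if (is.null(pooled)) rowMeans(expr) else pooled
      ct <- stats::cor.test(log1p(prof), log1p(ref), method = "pearson")
      if (ct$p.value > cor_alpha) r <- c(r, "correlation")
    }
    if ("read_count" %in% names(metrics) && min_reads > 0 &&
        metrics$read_count[i] < min_reads) {
      r <- c(r, "read-count")
    }
    reasons[[i]] <- r
  }
  data.frame(cell = metrics$cell,
             keep = lengths(reasons) == 0,
             reasons = vapply(reasons, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}
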