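decision_frame <- function(queries, verdict, source) {
  data.frame(chrom = queries$chrom, pos = queries$pos, ref = queries$ref,
             alt = queries$alt, verdict = verdict, source = source,
             stringsAsFactors = FALSE)
}

#' Confirm variants against an external caller's VCF
#'
#' Emulates per-site confirmation by an orthogonal caller (in the original
#' workflow, GATK HaplotypeCaller run at specific locations one at a time):
#' a query is `CONFIRM`ed iff a record with the same chromosome, position and
#' parsimoniously trimmed REF/ALT alleles exists in the support VCF, and
#' `REJECT`ed otherwise. Matching is allele-aware: a different ALT at the same
#' position does not confirm.
#'
#' @param queries an `rp_candidates` data.frame.
#' @param support_vcf path to any caller's VCF output for the same cell.
#' @return data.frame of decisions: `chrom`, `pos`, `ref`, `alt`,
#'   `verdict` (`CONFIRM`/`REJECT`), `source` (`EXTERNAL_VCF`).
#' @export
external_vcf_validator <- function(queries, support_vcf) {
  keys <- read_vcf_keys(support_vcf)
  verdict <- ifelse(variant_key(queries) %in% keys, "CONFIRM", "REJECT")
  decision_frame(queries, verdict, "EXTERNAL_VCF")
}

#' Confirm variants with a binomial sequencing-error test
#'
#' Self-contained fallback validator: a query is `CONFIRM`ed iff it has at
#' least `min_alt` supporting reads and the one-sided binomial tail
#' probability of observing that many or more alternate reads out of
#' `ref_depth + alt_depth` trials under the per-base error rate is below
#' `alpha`. This asks whether the alternate reads are explainable as
#' sequencing error alone.
#'
#' @param queries an `rp_candidates` data.frame (or any data.frame with
#'   `ref_depth`/`alt_depth`).
#' @param error_rate assumed per-base error probability (default 0.01).
#' @param alpha tail-probability threshold (default 0.001).
#' @param min_alt minimum alternate-read count (default 2).
#' @return data.frame of decisions with `source = "INTERNAL_STAT"`.
#' @export
internal_stat_validator <- function(queries, error_rate = 0.01,
                                    alpha = 0.001, min_alt = 2L) {
  n <- queries$ref_depth + queries$alt_depth
  k <- queries$alt_depth
  p <- rep(1, length(n))
  ok <- n > 0 & k > 0
  p[ok] <- stats::pbinom(k[ok] - 1L, n[ok], error_rate, lower.tail = FALSE)
  verdict <- ifelse(k >= min_alt & p < alpha, "CONFIRM", "REJECT")
  decision_frame(queries, verdict, "INTERNAL_STAT")
}

# resolve the validator argument of call_cell into a function(queries)->decisions
resolve_validator <- function(validator, config) {
  if (is.null(validator)) {
    function(q) internal_stat_validator(q, error_rate = config$error_rate,
                                        alpha = config$alpha,
                                        min_alt = config$min_alt)
  } else if (is.character(validator)) {
    path <- validator
    function(q) external_vcf_validator(q, path)
  } else if (is.function(validator)) {
    validator
  } else {
    stop("validator must be NULL, a VCF path, or a function")
  }
}
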