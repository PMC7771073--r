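#' Caller configuration
#'
#' Bundles the tunable thresholds of the calling pipeline.
#'
#' @param tolerance absolute tolerance on folded allele fractions for the
#'   bimodal filter, in fraction units (default 0.05 = 5 percentage points).
#' @param min_hom_depth inclusive minimum total depth for a homozygous-looking
#'   call (default 10).
#' @param tpm_min strict lower TPM bound for an isoform to count as expressed
#'   (default 1).
#' @param hom_ref_read_allowance reference reads tolerated in a
#'   homozygous-looking site (default 0, the strict reading of "full read
#'   coverage supporting the alternate allele").
#' @param error_rate,alpha,min_alt parameters of the internal binomial
#'   validator (see [internal_stat_validator()]).
#' @return a classed list (`rp_config`).
#' @export
rp_config <- function(tolerance = 0.05, min_hom_depth = 10L, tpm_min = 1.0,
                      hom_ref_read_allowance = 0L, error_rate = 0.01,
                      alpha = 0.001, min_alt = 2L) {
  structure(list(tolerance = tolerance, min_hom_depth = as.integer(min_hom_depth),
                 tpm_min = tpm_min,
                 hom_ref_read_allowance = as.integer(hom_ref_read_allowance),
                 error_rate = error_rate, alpha = alpha,
                 min_alt = as.integer(min_alt)),
            class = "rp_config")
}

#' Call variants in one cell
#'
#' The full partition-and-filter pipeline on one cell's candidates:
#'
#' 1. Candidates are split by zygosity. Homozygous-looking sites (no reference
#'    reads beyond the allowance) pass iff their depth is at least
#'    `min_hom_depth`.
#' 2. Heterozygous candidates are assigned to their highest-TPM expressed
#'    isoform. Within each isoform carrying at least two candidates, the
#'    bimodal allele-fraction model is fitted and candidates consistent with
#'    the modal fraction pass as bimodally-distributed heterozygous calls.
#' 3. Heterozygous candidates with no expressed isoform, on isoforms that
#'    support no model, or falling outside the fitted distribution carry no
#'    exploitable allele-fraction structure and are handed to the validator
#'    (an external caller's VCF, or the internal binomial test).
#'
#' The passing calls from the three paths are combined and deduplicated on
#' (chrom, pos, ref, alt). SNVs and indels flow through identical logic. The
#' function is a pure function of its inputs.
#'
#' @param candidates an `rp_candidates` data.frame (e.g. from
#'   [read_candidate_vcf()] or [enumerate_candidates()]).
#' @param isoforms an `rp_isoforms` object (expression set, or supply `quant`).
#' @param quant optional named TPM vector to attach via [set_expression()].
#' @param validator `NULL` for the internal binomial validator, a path to a
#'   support VCF, or a `function(queries)` returning a decision frame.
#' @param config an [rp_config()].
#' @return an object of class `rp_callset`: list with `calls` (a data.frame
#'   with per-candidate `class` in `HOMOZYGOUS_LOOKING`/`HET_BIMODAL`/
#'   `HET_NONBIMODAL`, `status` in `PASS`/`FILTERED`, `af`, `isoform_id`),
#'   `config`, and `models` (the fitted per-isoform bimodal models).
#' @export
call_cell <- function(candidates, isoforms, quant = NULL, validator = NULL,
                      config = rp_config()) {
  stopifnot(inherits(config, "rp_config"))
  if (!is.null(quant)) isoforms <- set_expression(isoforms, quant)
  vfun <- resolve_validator(validator, config)
  df <- as.data.frame(candidates)
  n <- nrow(df)
  cls <- character(n); status <- rep("FILTERED", n)
  iso_id <- rep(NA_character_, n)
  models <- list()
  if (n > 0) {
    zyg <- classify_zygosity(df, config$hom_ref_read_allowance)
    hom <- zyg == "HOMOZYGOUS_LOOKING"
    cls[hom] <- "HOMOZYGOUS_LOOKING"
    status[hom & df$total_depth >= config$min_hom_depth] <- "PASS"

    het <- which(!hom)
    if (length(het)) {
      iso <- assign_to_isoform(df[het, , drop = FALSE], isoforms,
                               tpm_min = config$tpm_min)
      iso_id[het] <- iso
      frac <- allele_fraction(df[het, , drop = FALSE])
      to_validate <- rep(TRUE, length(het))
      for (tid in unique(iso[!is.na(iso)])) {
        grp <- which(iso == tid)
        model <- fit_bimodal_model(frac[grp], tolerance = config$tolerance)
        if (is.null(model)) next
        models[[tid]] <- model
        ok <- abs(fold_fraction(frac[grp]) - model$mode) <=
          model$tolerance + rp_eps
        cls[het[grp[ok]]] <- "HET_BIMODAL"
        status[het[grp[ok]]] <- "PASS"
        to_validate[grp[ok]] <- FALSE
      }
      vq <- het[to_validate]
      cls[vq] <- "HET_NONBIMODAL"
      if (length(vq)) {
        dec <- vfun(df[vq, , drop = FALSE])
        verdict <- dec$verdict[match(variant_key(df[vq, , drop = FALSE]),
                                     variant_key(dec))]
        status[vq[verdict == "CONFIRM"]] <- "PASS"
      }
    }
    # deduplicate the PASS set on (chrom, pos, ref, alt)
    key <- variant_key(df)
    p <- which(status == "PASS")
    dup <- p[duplicated(key[p])]
    status[dup] <- "FILTERED"
  }
  calls <- df
  calls$af <- ifelse(df$ref_depth + df$alt_depth > 0,
                     df$alt_depth / (df$ref_depth + df$alt_depth), NA_real_)
  calls$class <- cls
  calls$status <- status
  calls$isoform_id <- iso_id
  rownames(calls) <- NULL
  structure(list(calls = calls, config = config, models = models),
            class = "rp_callset")
}

#' @export
print.rp_callset <- function(x, ...) {
  np <- sum(x$calls$status == "PASS")
  cat("<rp_callset> ", nrow(x$calls), " candidates, ", np, " PASS\n", sep = "")
  if (nrow(x$calls)) {
    print(table(class = x$calls$class, status = x$calls$status))
  }
  invisible(x)
}

#' @export
summary.rp_callset <- function(object, ...) {
  calls <- object$calls
  out <- list(
    n_candidates = nrow(calls),
    n_pass = sum(calls$status == "PASS"),
    by_class = if (nrow(calls)) table(calls$class, calls$status) else NULL,
    n_models = length(object$models),
    n_indels = sum(calls$is_indel)
  )
  class(out) <- "summary.rp_callset"
  out
}

#' @export
print.summary.rp_callset <- function(x, ...) {
  cat("Call set: ", x$n_candidates, " candidates, ", x$n_pass, " PASS (",
      x$n_indels, " indels), ", x$n_models,
      " isoform bimodal model(s)\n", sep = "")
  if (!is.null(x$by_class)) print(x$by_class)
  invisible(x)
}

#' Passing calls of a call set
#'
#' @param x an `rp_callset`.
#' @param class_filter optional subset of classes to keep
#'   (`"HOMOZYGOUS_LOOKING"`, `"HET_BIMODAL"`, `"HET_NONBIMODAL"`).
#' @return data.frame of PASS calls.
#' @export
pass_calls <- function(x, class_filter = NULL) {
  stopifnot(inherits(x, "rp_callset"))
  calls <- x$calls[x$calls$status == "PASS", , drop = FALSE]
  if (!is.null(class_filter)) {
    calls <- calls[calls$class %in% class_filter, , drop = FALSE]
  }
  calls
}
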