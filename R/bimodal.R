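#' Fold an allele fraction onto (0, 0.5]
#'
#' A heterozygous variant on a transcript expressed unevenly from the two
#' chromosomes shows an allele fraction of either `f` or `1 - f` depending on
#' which haplotype carries the alternate allele. Folding (`min(f, 1 - f)`)
#' maps both modes of this bimodal distribution onto a single value so that
#' variants sharing a transcript can be clustered.
#'
#' @param f numeric vector of allele fractions in (0, 1).
#' @return numeric vector in (0, 0.5].
#' @export
fold_fraction <- function(f) pmin(f, 1 - f)

# numeric slack for closed-boundary comparisons on folded fractions
rp_eps <- 1e-9

#' Fit the per-isoform bimodal allele-fraction model
#'
#' Given the allele fractions of the heterozygous candidates assigned to one
#' isoform, finds the largest subset whose folded fractions all lie within
#' `tolerance` of the subset's own mean folded value. That mean is the modal
#' fraction: the share of the isoform's transcripts coming from one
#' chromosome. A model needs support from at least two variants; with fewer,
#' or when no two fractions are mutually consistent, `NULL` is returned and
#' the variants fall through to the validator path.
#'
#' Ties on subset size are broken by smaller spread (max minus min folded
#' value), then by smaller mode. The search is an exact branch-and-bound over
#' the sorted folded values (the optimal subset need not be contiguous in
#' sorted order, so window scans are insufficient); it is seeded with the best
#' contiguous window to tighten pruning.
#'
#' @param fractions numeric vector of allele fractions in (0, 1).
#' @param tolerance absolute tolerance on the folded fraction, in fraction
#'   units (default 0.05, i.e. 5 percentage points).
#' @return an object of class `rp_bimodal_model` (fields `mode`, `tolerance`,
#'   `support`, `members` = indices into `fractions`), or `NULL`.
#' @examples
#' fit_bimodal_model(c(0.7, 0.3, 0.5))   # mode 0.3, the 0.5 variant excluded
#' @export
fit_bimodal_model <- function(fractions, tolerance = 0.05) {
  n <- length(fractions)
  if (n < 2) return(NULL)
  stopifnot(tolerance > 0, tolerance < 0.5)
  folded <- fold_fraction(fractions)
  o <- order(folded)
  x <- folded[o]

  best <- list(size = 0L, spread = Inf, mode = Inf, sel = integer())
  consider <- function(sel) {
    vals <- x[sel]
    m <- mean(vals)
    if (max(vals) - m > tolerance + rp_eps) return()
    if (m - min(vals) > tolerance + rp_eps) return()
    sz <- length(sel); sp <- max(vals) - min(vals)
    if (sz > best$size ||
        (sz == best$size && (sp < best$spread - rp_eps ||
                             (abs(sp - best$spread) <= rp_eps &&
                              m < best$mode - rp_eps)))) {
      best <<- list(size = sz, spread = sp, mode = m, sel = sel)
    }
  }
  # seed: best contiguous window (cheap lower bound for the search)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] - x[i] > 2 * tolerance + rp_eps) break
      consider(i:j)
    }
  }
  # exact search: depth-first include/exclude over sorted values
  recurse <- function(i, sel, s) {
    k <- length(sel)
    if (k > 0 && s / k - x[sel[1]] > tolerance + rp_eps) return()  # mean only grows
    if (i > n) {
      if (k >= 2) consider(sel)
      return()
    }
    if (k + (n - i + 1L) < best$size) return()  # cannot beat best size
    if (k > 0 && x[i] - x[sel[1]] > 2 * tolerance + rp_eps) {
      # no further value can join this selection
      if (k >= 2) consider(sel)
      return()
    }
    recurse(i + 1L, c(sel, i), s + x[i])
    recurse(i + 1L, sel, s)
  }
  recurse(1L, integer(), 0)

  if (best$size < 2) return(NULL)
  structure(list(mode = best$mode, tolerance = tolerance,
                 support = best$size, members = sort(o[best$sel])),
            class = "rp_bimodal_model")
}

#' @export
print.rp_bimodal_model <- function(x, ...) {
  cat(sprintf(
    "<rp_bimodal_model> modal folded fraction %.3f (modes %.3f / %.3f), tolerance %.3f, support %d\n",
    x$mode, x$mode, 1 - x$mode, x$tolerance, x$support))
  invisible(x)
}

#' Filter heterozygous variants against an isoform's bimodal model
#'
#' A variant passes iff its folded allele fraction lies within the model's
#' tolerance of the modal fraction (closed boundary: a distance exactly equal
#' to the tolerance passes). Variants falling outside the distribution are the
#' likely false positives that allele-specific expression lets the caller
#' remove.
#'
#' @param x an `rp_candidates` data.frame, or a numeric vector of allele
#'   fractions.
#' @param model an `rp_bimodal_model`.
#' @return list with elements `pass` and `fail`, subsets of `x` (the two are
#'   disjoint and their union is the input).
#' @export
filter_bimodal <- function(x, model) {
  stopifnot(inherits(model, "rp_bimodal_model"))
  f <- if (is.numeric(x)) x else allele_fraction(x)
  ok <- abs(fold_fraction(f) - model$mode) <= model$tolerance + rp_eps
  if (is.numeric(x)) {
    list(pass = x[ok], fail = x[!ok])
  } else {
    list(pass = x[ok, , drop = FALSE], fail = x[!ok, , drop = FALSE])
  }
}
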