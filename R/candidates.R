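#' Construct a set of candidate variants
#'
#' A candidate variant is one putative site at which at least one read differs
#' from the reference: chromosome, 1-based position, reference and alternate
#' alleles, and per-allele read depths. Candidates are the atoms of the caller:
#' they are partitioned into homozygous-looking and heterozygous sites, and the
#' heterozygous ones are judged against the allele-fraction structure of the
#' isoform that carries them.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (VCF convention).
#' @param ref,alt character vectors of reference/alternate alleles
#'   (`A`/`C`/`G`/`T` strings, length >= 1; unequal lengths mark an indel).
#' @param ref_depth,alt_depth integer vectors: reads supporting the reference
#'   and the alternate allele. Every candidate must have `alt_depth >= 1`.
#' @param total_depth integer vector of total covering reads; defaults to
#'   `ref_depth + alt_depth` and must never be smaller than that sum.
#' @param base_quality optional numeric vector, mean phred of the supporting
#'   bases (`NA` when unknown).
#' @param normalize logical; trim alleles to their parsimonious representation
#'   (see [normalize_variants()]).
#' @return A `data.frame` of class `rp_candidates` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `ref_depth`, `alt_depth`, `total_depth`, `base_quality`,
#'   `is_indel`.
#' @examples
#' rp_candidates("chr1", 100, "A", "G", ref_depth = 6, alt_depth = 14)
#' @export
rp_candidates <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          ref_depth = integer(), alt_depth = integer(),
                          total_depth = NULL, base_quality = NULL,
                          normalize = TRUE) {
  n <- length(pos)
  if (is.null(total_depth)) total_depth <- ref_depth + alt_depth
  if (is.null(base_quality)) base_quality <- rep(NA_real_, n)
  x <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    ref_depth = as.integer(ref_depth),
    alt_depth = as.integer(alt_depth),
    total_depth = as.integer(total_depth),
    base_quality = as.numeric(base_quality),
    stringsAsFactors = FALSE
  )
  if (normalize && n > 0) x <- normalize_variants(x)
  x$is_indel <- nchar(x$ref) != nchar(x$alt)
  class(x) <- c("rp_candidates", "data.frame")
  validate_candidates(x)
  x
}

validate_candidates <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(x$pos < 1L)
  if (length(bad)) stop("candidate position < 1 at row ", bad[1])
  bad <- which(x$alt_depth < 1L)
  if (length(bad)) {
    stop("candidate without alternate-allele support (alt_depth < 1) at ",
         x$chrom[bad[1]], ":", x$pos[bad[1]])
  }
  bad <- which(x$ref_depth + x$alt_depth > x$total_depth)
  if (length(bad)) {
    stop("ref_depth + alt_depth exceeds total_depth at ",
         x$chrom[bad[1]], ":", x$pos[bad[1]])
  }
  bad <- which(nchar(x$ref) < 1L | nchar(x$alt) < 1L)
  if (length(bad)) stop("empty allele at row ", bad[1])
  invisible(x)
}

#' Reduce variants to their parsimonious representation
#'
#' Trims the common suffix, then the common prefix, of each REF/ALT pair while
#' keeping at least one base in each allele, advancing the position past
#' trimmed prefix bases. This makes indel records comparable across sources
#' that pad alleles differently. Full left-alignment against the reference
#' sequence is not attempted (no reference is available at read time); trimmed
#' representation is the package's matching currency.
#'
#' @param x a data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return the same data.frame with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(x) {
  ref <- x$ref; alt <- x$alt; pos <- x$pos
  # trim shared suffix
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    act <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(act)) break
    ref[act] <- substr(ref[act], 1L, nchar(ref[act]) - 1L)
    alt[act] <- substr(alt[act], 1L, nchar(alt[act]) - 1L)
  }
  # trim shared prefix, advancing pos
  repeat {
    act <- nchar(ref) > 1L & nchar(alt) > 1L &
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    if (!any(act)) break
    ref[act] <- substr(ref[act], 2L, nchar(ref[act]))
    alt[act] <- substr(alt[act], 2L, nchar(alt[act]))
    pos[act] <- pos[act] + 1L
  }
  x$ref <- ref; x$alt <- alt; x$pos <- as.integer(pos)
  x
}

#' Canonical key for a variant
#'
#' `chrom:pos:ref:alt` after parsimonious trimming; the identity used for
#' deduplication, validator lookup and truth-set matching.
#'
#' @param x a data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param normalize trim alleles first (default `TRUE`).
#' @return character vector of keys.
#' @export
variant_key <- function(x, normalize = TRUE) {
  if (nrow(x) == 0) return(character())
  if (normalize) x <- normalize_variants(x)
  paste(x$chrom, x$pos, toupper(x$ref), toupper(x$alt), sep = ":")
}

#' Observed allele fraction of a candidate
#'
#' The fraction of allele-informative reads supporting the alternate allele,
#' `alt_depth / (ref_depth + alt_depth)`. For a heterozygous variant on a
#' transcript expressed 30:70 from the two chromosomes this sits near 0.3 or
#' 0.7; for a homozygous-looking site it is 1.
#'
#' @param x an `rp_candidates` data.frame (or anything with `ref_depth` and
#'   `alt_depth` columns).
#' @return numeric vector in (0, 1].
#' @export
allele_fraction <- function(x) {
  denom <- x$ref_depth + x$alt_depth
  if (any(denom <= 0)) {
    i <- which(denom <= 0)[1]
    stop("allele fraction undefined: zero allelic depth at ",
         x$chrom[i], ":", x$pos[i])
  }
  x$alt_depth / denom
}

#' Partition candidates into homozygous-looking and heterozygous
#'
#' A site whose reads all support the alternate allele could be a homozygous
#' variant or a heterozygous variant whose other allele is not expressed
#' (monoallelic expression / allelic dropout), hence the hedged label
#' "homozygous-looking". A small reference-read allowance can absorb
#' sequencing error at high depth; the strict default is 0.
#'
#' @param x an `rp_candidates` data.frame.
#' @param hom_ref_read_allowance maximum number of reference-supporting reads
#'   a site may show and still be called homozygous-looking (default 0).
#' @return character vector, `"HOMOZYGOUS_LOOKING"` or `"HETEROZYGOUS"`.
#' @export
classify_zygosity <- function(x, hom_ref_read_allowance = 0L) {
  ifelse(x$ref_depth <= hom_ref_read_allowance,
         "HOMOZYGOUS_LOOKING", "HETEROZYGOUS")
}

#' Depth filter for homozygous-looking candidates
#'
#' Homozygous-looking sites carry no allele-fraction information, so they are
#' screened on raw evidence alone: a site passes iff its total read depth is
#' at least `min_depth` (inclusive).
#'
#' @param x an `rp_candidates` data.frame of homozygous-looking sites.
#' @param min_depth inclusive depth threshold (default 10).
#' @return list with elements `pass` and `fail`, both `rp_candidates`.
#' @export
filter_homozygous_looking <- function(x, min_depth = 10L) {
  keep <- x$total_depth >= min_depth
  list(pass = x[keep, , drop = FALSE], fail = x[!keep, , drop = FALSE])
}
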