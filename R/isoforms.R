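#' Construct a transcript/isoform model table
#'
#' Internal representation of transcript structure: a `transcripts` table (one
#' row per isoform: `transcript_id`, `gene_id`, `chrom`, `strand`, `tpm`) and
#' an `exons` table (`transcript_id`, `start0`, `end0`). Exon intervals are
#' 0-based half-open internally; GTF's 1-based inclusive intervals are
#' converted at the boundary. Exons of one transcript must be sorted and
#' non-overlapping.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` and optionally `tpm`.
#' @param exons data.frame with columns `transcript_id`, `start0`, `end0`.
#' @return an object of class `rp_isoforms`.
#' @export
rp_isoforms <- function(transcripts, exons) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand") %in%
                  names(transcripts)))
  stopifnot(all(c("transcript_id", "start0", "end0") %in% names(exons)))
  if (!"tpm" %in% names(transcripts)) transcripts$tpm <- NA_real_
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicated transcript_id: ",
         transcripts$transcript_id[duplicated(transcripts$transcript_id)][1])
  }
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start0), , drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript non-overlap check on sorted exons
  if (nrow(exons) > 1) {
    same <- exons$transcript_id[-1] == exons$transcript_id[-nrow(exons)]
    bad <- which(same & exons$start0[-1] < exons$end0[-nrow(exons)])
    if (length(bad)) {
      stop("overlapping exons in transcript ", exons$transcript_id[bad[1] + 1])
    }
  }
  if (any(exons$end0 <= exons$start0)) stop("empty or inverted exon interval")
  tpm <- transcripts$tpm
  if (any(!is.na(tpm) & tpm < 0)) stop("negative TPM")
  obj <- list(transcripts = transcripts, exons = exons)
  class(obj) <- "rp_isoforms"
  obj
}

#' @export
print.rp_isoforms <- function(x, ...) {
  cat("<rp_isoforms> ", nrow(x$transcripts), " transcripts, ",
      nrow(x$exons), " exons",
      if (all(is.na(x$transcripts$tpm))) " (expression unset)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Read transcript annotation from a GTF file
#'
#' Imports `exon` features (via \pkg{rtracklayer}), groups them by
#' `transcript_id`, and converts the 1-based inclusive GTF intervals to the
#' internal 0-based half-open convention. Expression (`tpm`) is left unset;
#' attach it with [set_expression()].
#'
#' @param path GTF file.
#' @return an `rp_isoforms` object with `tpm = NA`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) {
    return(rp_isoforms(
      data.frame(transcript_id = character(), gene_id = character(),
                 chrom = character(), strand = character(), tpm = numeric()),
      data.frame(transcript_id = character(), start0 = integer(),
                 end0 = integer())))
  }
  tid <- as.character(gr$transcript_id)
  if (is.null(gr$transcript_id) || anyNA(tid)) {
    stop("GTF exon feature without a transcript_id attribute")
  }
  gid <- if (is.null(gr$gene_id)) rep(NA_character_, length(gr)) else
    as.character(gr$gene_id)
  ex <- data.frame(
    transcript_id = tid,
    start0 = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
    end0 = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  first <- !duplicated(tid)
  tx <- data.frame(
    transcript_id = tid[first],
    gene_id = gid[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    tpm = NA_real_,
    stringsAsFactors = FALSE
  )
  rp_isoforms(tx, ex)
}

#' Attach expression values to an isoform table
#'
#' @param isoforms an `rp_isoforms` object.
#' @param quant named numeric vector of TPM by transcript id, as returned by
#'   [read_quant_table()]. Transcripts absent from `quant` get `tpm = 0`.
#' @return the `rp_isoforms` object with `tpm` filled in.
#' @export
set_expression <- function(isoforms, quant) {
  stopifnot(inherits(isoforms, "rp_isoforms"))
  tpm <- unname(quant[isoforms$transcripts$transcript_id])
  tpm[is.na(tpm)] <- 0
  isoforms$transcripts$tpm <- as.numeric(tpm)
  isoforms
}

#' Assign candidate variants to their dominant expressed isoform
#'
#' For each candidate, among isoforms whose exons contain the position and
#' whose expression exceeds `tpm_min` (strict), the isoform with maximal TPM
#' is chosen: one site gets one verdict, and the dominant isoform contributes
#' most of the covering reads. Sites in no expressed exon get `NA`.
#'
#' @param x an `rp_candidates` data.frame.
#' @param isoforms an `rp_isoforms` object with `tpm` set.
#' @param tpm_min strict lower TPM bound for an isoform to count as expressed
#'   (default 1: `TPM > 1`).
#' @return character vector of transcript ids (or `NA`) parallel to `x`.
#' @export
assign_to_isoform <- function(x, isoforms, tpm_min = 1.0) {
  stopifnot(inherits(isoforms, "rp_isoforms"))
  n <- nrow(x)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  tx <- isoforms$transcripts
  keep <- !is.na(tx$tpm) & tx$tpm > tpm_min
  tx <- tx[keep, , drop = FALSE]
  if (nrow(tx) == 0) return(out)
  ex <- isoforms$exons[isoforms$exons$transcript_id %in% tx$transcript_id, ,
                       drop = FALSE]
  ex$chrom <- tx$chrom[match(ex$transcript_id, tx$transcript_id)]
  ex$tpm <- tx$tpm[match(ex$transcript_id, tx$transcript_id)]
  # interval overlap: candidate pos (1-based) in [start0, end0) <=> pos0 in exon
  hits <- IRanges::findOverlaps(
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos)),
    GenomicRanges::GRanges(ex$chrom,
                           IRanges::IRanges(ex$start0 + 1L, ex$end0)))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # pick max tpm per candidate; deterministic tie-break on transcript_id
  ord <- order(qi, -ex$tpm[si], ex$transcript_id[si])
  qi <- qi[ord]; si <- si[ord]
  first <- !duplicated(qi)
  out[qi[first]] <- ex$transcript_id[si[first]]
  out
}
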