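#' Construct an aligned read set
#'
#' In-memory container backing both candidate enumeration and the spike-in
#' simulator: one row per mapped, non-duplicate read with its chromosome,
#' 1-based leftmost position, bases and base qualities. Reads are stored
#' ungapped (match-only alignments), which is what the fixture generator
#' produces; [read_sam()] rejects anything with a more complex CIGAR.
#'
#' @param qname read names.
#' @param chrom chromosome per read.
#' @param pos 1-based leftmost aligned position.
#' @param seq read bases (character vector).
#' @param qual base-quality string per read (phred+33); defaults to uniform
#'   high quality.
#' @return a `data.frame` of class `rp_reads`.
#' @export
rp_reads <- function(qname = character(), chrom = character(),
                     pos = integer(), seq = character(), qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  x <- data.frame(qname = as.character(qname), chrom = as.character(chrom),
                  pos = as.integer(pos), seq = toupper(as.character(seq)),
                  qual = as.character(qual), stringsAsFactors = FALSE)
  if (nrow(x) && any(nchar(x$seq) != nchar(x$qual))) {
    stop("read sequence and quality lengths differ")
  }
  class(x) <- c("rp_reads", "data.frame")
  x
}

#' @export
print.rp_reads <- function(x, ...) {
  cat("<rp_reads> ", nrow(x), " reads on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

# per-chromosome sorted index for covering-read lookups
reads_index <- function(reads) {
  sp <- split(seq_len(nrow(reads)), reads$chrom)
  lapply(sp, function(idx) {
    start <- reads$pos[idx]
    len <- nchar(reads$seq[idx])
    o <- order(start)
    list(row = idx[o], start = start[o], end = (start + len - 1L)[o],
         maxlen = max(len))
  })
}

# rows of reads covering chrom:pos (1-based), via the sorted index
covering_rows <- function(index, chrom, pos) {
  ix <- index[[chrom]]
  if (is.null(ix)) return(integer())
  hi <- findInterval(pos, ix$start)
  if (hi == 0L) return(integer())
  lo <- findInterval(pos - ix$maxlen, ix$start) + 1L
  cand <- lo:hi
  cand <- cand[ix$end[cand] >= pos]
  ix$row[cand]
}

#' Per-site pileup of an aligned read set
#'
#' @param reads an `rp_reads` object.
#' @param chrom,pos site (1-based).
#' @param index optional prebuilt index (internal reuse).
#' @return data.frame with one row per covering read: `row` (index into
#'   `reads`), `base`, `qual` (phred score).
#' @export
pileup_at <- function(reads, chrom, pos, index = NULL) {
  if (is.null(index)) index <- reads_index(reads)
  rows <- covering_rows(index, chrom, pos)
  off <- pos - reads$pos[rows] + 1L
  data.frame(
    row = rows,
    base = substr(reads$seq[rows], off, off),
    qual = as.integer(charToRaw(paste(substr(reads$qual[rows], off, off),
                                      collapse = ""))) - 33L,
    stringsAsFactors = FALSE
  )
}

#' Read-depth vector of one chromosome
#'
#' @param reads an `rp_reads` object.
#' @param chrom chromosome name.
#' @param len chromosome length (defaults to the rightmost covered base).
#' @return integer vector of depth at positions `1..len`.
#' @export
coverage_vector <- function(reads, chrom, len = NULL) {
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  ends <- if (nrow(r)) r$pos + nchar(r$seq) - 1L else integer()
  if (is.null(len)) len <- if (length(ends)) max(ends) else 0L
  delta <- integer(len + 1L)
  if (nrow(r)) {
    s <- pmin(r$pos, len + 1L)
    e <- pmin(ends + 1L, len + 1L)
    ts <- tabulate(s, nbins = len + 1L)
    te <- tabulate(e, nbins = len + 1L)
    delta <- ts - te
  }
  cumsum(delta)[seq_len(len)]
}

#' Positions viable for variant spike-in
#'
#' A site is viable when its read depth is at least `min_depth`, mirroring the
#' simulator's placement rule (spiked variants must sit where real coverage
#' can express them).
#'
#' @param reads an `rp_reads` object.
#' @param min_depth inclusive depth threshold (default 20).
#' @return data.frame with columns `chrom`, `pos` (1-based), `depth`.
#' @export
viable_sites <- function(reads, min_depth = 20L) {
  out <- lapply(sort(unique(reads$chrom)), function(ch) {
    cov <- coverage_vector(reads, ch)
    p <- which(cov >= min_depth)
    if (length(p) == 0) return(NULL)
    data.frame(chrom = ch, pos = p, depth = cov[p], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), depth = integer())
  }
  rownames(out) <- NULL
  out
}

#' Enumerate candidate variants from alignments
#'
#' Compares every read against the reference and aggregates mismatching bases
#' into per-site, per-allele candidates (the in-memory equivalent of a
#' mismatch pileup). SNVs only: reads are ungapped.
#'
#' @param reads an `rp_reads` object.
#' @param reference named character vector of chromosome sequences.
#' @param min_alt_depth minimum supporting reads for a candidate (default 1).
#' @return an `rp_candidates` data.frame sorted by (chrom, pos, alt).
#' @export
enumerate_candidates <- function(reads, reference, min_alt_depth = 1L) {
  mm_chrom <- character(); mm_pos <- integer()
  mm_ref <- character(); mm_alt <- character()
  for (ch in unique(reads$chrom)) {
    if (is.na(reference[ch])) stop("chromosome absent from reference: ", ch)
    sel <- which(reads$chrom == ch)
    starts <- reads$pos[sel]
    lens <- nchar(reads$seq[sel])
    refsub <- substring(reference[[ch]], starts, starts + lens - 1L)
    differs <- which(refsub != reads$seq[sel])
    for (j in differs) {
      a <- utf8ToInt(reads$seq[sel[j]])
      b <- utf8ToInt(refsub[j])
      at <- which(a != b)
      mm_chrom <- c(mm_chrom, rep(ch, length(at)))
      mm_pos <- c(mm_pos, starts[j] + at - 1L)
      mm_ref <- c(mm_ref, strsplit(refsub[j], "")[[1]][at])
      mm_alt <- c(mm_alt, strsplit(reads$seq[sel[j]], "")[[1]][at])
    }
  }
  if (length(mm_pos) == 0) return(rp_candidates())
  key <- paste(mm_chrom, mm_pos, mm_alt, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.integer(vapply(parts, `[`, "", 2))
  alt <- vapply(parts, `[`, "", 3)
  ref <- substring(reference[chrom], pos, pos)
  # total depth and per-site alt totals to recover ref_depth
  depth <- integer(length(pos))
  for (ch in unique(chrom)) {
    s <- chrom == ch
    cov <- coverage_vector(reads, ch, len = max(pos[s]))
    depth[s] <- cov[pos[s]]
  }
  site <- paste(chrom, pos, sep = "\r")
  alt_tot <- stats::ave(agg$Freq, site, FUN = sum)
  keep <- agg$Freq >= min_alt_depth
  o <- order(chrom, pos, alt)
  keep <- keep[o]
  rp_candidates(chrom[o][keep], pos[o][keep], ref[o][keep], alt[o][keep],
                ref_depth = (depth - alt_tot)[o][keep],
                alt_depth = agg$Freq[o][keep],
                total_depth = depth[o][keep])
}

#' Write an aligned read set as SAM
#'
#' Plain-text SAM with `@SQ` header lines and match-only CIGARs, suitable for
#' `samtools`/\pkg{Rsamtools} consumption.
#'
#' @param reads an `rp_reads` object.
#' @param path output file.
#' @param seqlengths named integer vector of chromosome lengths; defaults to
#'   the rightmost covered base per chromosome.
#' @return invisibly, the path.
#' @export
write_sam <- function(reads, path, seqlengths = NULL) {
  chroms <- sort(unique(reads$chrom))
  if (is.null(seqlengths)) {
    seqlengths <- vapply(chroms, function(ch) {
      r <- reads[reads$chrom == ch, , drop = FALSE]
      max(r$pos + nchar(r$seq) - 1L)
    }, integer(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", names(seqlengths), "\tLN:", seqlengths)),
             con)
  if (nrow(reads)) {
    writeLines(paste(reads$qname, 0L, reads$chrom, reads$pos, 60L,
                     paste0(nchar(reads$seq), "M"), "*", 0L, 0L,
                     reads$seq, reads$qual, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM/BAM file into an aligned read set
#'
#' Parses via \pkg{Rsamtools} (SAM text is converted with `asBam` first).
#' Unmapped, secondary, supplementary and duplicate reads are dropped; only
#' match-only (`<n>M`) CIGARs are accepted, matching the container's ungapped
#' model.
#'
#' @param path SAM or BAM file.
#' @return an `rp_reads` object.
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual", "cigar"), flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(b$pos) == 0) return(rp_reads())
  ok <- grepl("^[0-9]+M$", b$cigar)
  if (!all(ok)) {
    stop("non match-only CIGAR in ", path, " (first: ",
         b$cigar[!ok][1], "); only ungapped alignments are supported")
  }
  rp_reads(b$qname, as.character(b$rname), b$pos,
           as.character(b$seq), as.character(b$qual))
}
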