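# Independent oracles and small fixture builders used across the suite.

# exhaustive-subset oracle for the bimodal fit: flat bitmask enumeration of
# every subset, same tie-break contract (size desc, spread asc, mode asc)
oracle_bimodal <- function(f, tol = 0.05, eps = 1e-9) {
  x <- pmin(f, 1 - f)
  n <- length(x)
  if (n < 2) return(NULL)
  best <- NULL
  for (m in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) < 2) next
    v <- x[sel]
    mu <- mean(v)
    if (max(v) - mu > tol + eps || mu - min(v) > tol + eps) next
    cand <- list(size = length(sel), spread = max(v) - min(v), mode = mu)
    if (is.null(best) || cand$size > best$size ||
        (cand$size == best$size &&
         (cand$spread < best$spread - eps ||
          (abs(cand$spread - best$spread) <= eps &&
           cand$mode < best$mode - eps)))) {
      best <- cand
    }
  }
  best
}

# naive per-position depth count, independent of coverage_vector
naive_depth <- function(reads, chrom, pos) {
  sum(reads$chrom == chrom & reads$pos <= pos &
        reads$pos + nchar(reads$seq) - 1L >= pos)
}

# binomial upper tail by direct summation (oracle for the internal validator)
binom_tail_direct <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

# one-transcript isoform table with given exons (1-based inclusive) and tpm
make_isoforms <- function(..., gene = NULL, chrom = "chr1", tpm = NULL) {
  specs <- list(...)
  ids <- names(specs)
  if (is.null(gene)) gene <- paste0("g_", ids)
  if (is.null(tpm)) tpm <- rep(NA_real_, length(specs))
  tx <- data.frame(transcript_id = ids, gene_id = gene,
                   chrom = rep(chrom, length.out = length(ids)),
                   strand = "+", tpm = tpm, stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(ids, function(id) {
    m <- specs[[id]]
    data.frame(transcript_id = id, start0 = m[, 1] - 1L, end0 = m[, 2],
               stringsAsFactors = FALSE)
  }))
  rp_isoforms(tx, ex)
}

# candidates at given fractions on one chromosome, depth-controlled
cands_at <- function(pos, frac, depth = 20L, chrom = "chr1",
                     ref = "A", alt = "G") {
  alt_d <- as.integer(round(depth * frac))
  rp_candidates(rep(chrom, length(pos)), pos, rep(ref, length(pos)),
                rep(alt, length(pos)),
                ref_depth = depth - alt_d, alt_depth = alt_d,
                total_depth = rep(depth, length(pos)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# minimal hand-written VCF body wrapper
vcf_text <- function(records, format_cols = TRUE) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"d\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    if (format_cols)
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcell1"
    else "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records)
}
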