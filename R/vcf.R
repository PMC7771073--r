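rpclass_tags <- c(HOMOZYGOUS_LOOKING = "HOMLOOK",
                  HET_BIMODAL = "HETBIM",
                  HET_NONBIMODAL = "HETNB")

# quick structural scan so malformed lines are reported with their line number
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 8L]
    if (length(bad)) {
      stop("malformed VCF record (fewer than 8 fields) at line ", bad[1],
           " of ", path)
    }
  }
  invisible(length(body))
}

split_num_list <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(v) suppressWarnings(as.numeric(v)))
}

#' Read candidate variants from a VCF file
#'
#' Parses a VCF into an [rp_candidates] table, one candidate per ALT allele
#' (multi-allelic records are split; record order is preserved). Per-allele
#' depths are recovered according to the dialect:
#'
#' * `"mpileup"` (samtools/bcftools): the per-sample `AD` field when present,
#'   otherwise `DP4` (`ref = fwd+rev reference reads`, `alt = fwd+rev
#'   alternate reads`). `DP4` pools all alternate alleles, so a multi-allelic
#'   record with only `DP4` is a hard error.
#' * `"generic"` (GATK-style): the per-sample `AD` field (first sample), or an
#'   `AD` INFO key.
#'
#' Symbolic alleles (`<*>`, `<NON_REF>`) and ALT alleles with zero supporting
#' reads are dropped: a candidate is by definition a site with at least one
#' supporting read. A record with no recoverable depths is a hard error naming
#' the record.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param dialect `"mpileup"` or `"generic"`.
#' @return an `rp_candidates` data.frame.
#' @export
read_candidate_vcf <- function(path, dialect = c("mpileup", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such VCF: ", path)
  if (!grepl("\\.gz$", path)) check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && !is.matrix(fix)) {  # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(rp_candidates())
  }
  nrec <- nrow(fix)
  ad_fmt <- tryCatch(
    if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "AD")[, 1] else
      rep(NA_character_, nrec),
    error = function(e) rep(NA_character_, nrec))
  ad_info <- vcfR::extract.info(v, element = "AD")
  dp4 <- vcfR::extract.info(v, element = "DP4")
  if (is.null(dp4)) dp4 <- rep(NA_character_, nrec)
  dp_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
  ad_str <- ifelse(!is.na(ad_fmt), ad_fmt, ad_info)

  chrom <- character(); pos <- integer(); ref <- character(); alt <- character()
  rd <- integer(); ad_ <- integer(); td <- integer()
  alts_all <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  for (i in seq_len(nrec)) {
    alts <- alts_all[[i]]
    keep_sym <- !grepl("^<", alts)
    rec_name <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    ad_i <- if (!is.na(ad_str[i])) split_num_list(ad_str[i])[[1]] else NULL
    if (!is.null(ad_i)) {
      if (length(ad_i) != length(alts) + 1L || anyNA(ad_i)) {
        stop("AD field does not match allele count at ", rec_name)
      }
      refd <- ad_i[1]
      altd <- ad_i[-1]
    } else if (dialect == "mpileup" && !is.na(dp4[i])) {
      d4 <- split_num_list(dp4[i])[[1]]
      if (length(d4) != 4L || anyNA(d4)) stop("malformed DP4 at ", rec_name)
      if (sum(keep_sym) > 1L) {
        stop("multi-allelic record with only DP4 at ", rec_name,
             ": per-allele depths not recoverable, an AD field is required")
      }
      refd <- d4[1] + d4[2]
      altd <- rep(d4[3] + d4[4], length(alts))
    } else {
      stop("no per-allele depths (AD", if (dialect == "mpileup") " or DP4",
           ") at ", rec_name)
    }
    keep <- keep_sym & altd >= 1
    if (!any(keep)) next
    k <- which(keep)
    tot <- if (!is.na(dp_info[i])) dp_info[i] else refd + sum(altd[k])
    tot <- max(tot, refd + altd[k])  # per-candidate invariant floor
    chrom <- c(chrom, rep(fix[i, "CHROM"], length(k)))
    pos <- c(pos, rep(as.integer(fix[i, "POS"]), length(k)))
    ref <- c(ref, rep(fix[i, "REF"], length(k)))
    alt <- c(alt, alts[k])
    rd <- c(rd, rep(as.integer(refd), length(k)))
    ad_ <- c(ad_, as.integer(altd[k]))
    td <- c(td, as.integer(pmax(tot, refd + altd[k])))
  }
  rp_candidates(chrom, pos, ref, alt, rd, ad_, total_depth = td)
}

#' Read the variant keys of a VCF
#'
#' Lightweight extraction of `chrom:pos:ref:alt` keys (multi-allelic records
#' split, alleles parsimoniously trimmed) without requiring depth fields.
#' Used for validator lookups and call-set comparisons.
#'
#' @param path VCF file.
#' @return character vector of normalized variant keys.
#' @export
read_vcf_keys <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && !is.matrix(fix)) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) return(character())
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n <- lengths(alts)
  df <- data.frame(
    chrom = rep(fix[, "CHROM"], n),
    pos = rep(as.integer(fix[, "POS"]), n),
    ref = rep(fix[, "REF"], n),
    alt = unlist(alts),
    stringsAsFactors = FALSE
  )
  df <- df[!grepl("^<", df$alt), , drop = FALSE]
  unique(variant_key(df))
}

#' Write a classified call set as VCF
#'
#' Emits a sorted single-sample VCF v4.2. Each record carries INFO tags
#' `RPCLASS` (`HOMLOOK`/`HETBIM`/`HETNB`), `AF` (observed allele fraction) and
#' optionally `ISO` (supporting isoform); per-allele depths go into the
#' sample's `AD`/`DP` fields so that [read_candidate_vcf()] round-trips
#' positions, alleles and depths exactly. `FILTER` is `PASS` or `rp_filtered`.
#'
#' @param calls an `rp_callset` (from [call_cell()]) or an `rp_candidates`
#'   data.frame (all written as PASS with class `HETNB` absent).
#' @param path output file.
#' @param sample_name sample column name (default `"CELL"`).
#' @return invisibly, the path.
#' @export
write_callset_vcf <- function(calls, path, sample_name = "CELL") {
  df <- if (inherits(calls, "rp_callset")) calls$calls else as.data.frame(calls)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=redpanda",
    "##INFO=<ID=RPCLASS,Number=1,Type=String,Description=\"Variant class: HOMLOOK, HETBIM or HETNB\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Observed alternate allele fraction\">",
    "##INFO=<ID=ISO,Number=1,Type=String,Description=\"Supporting isoform (bimodal filtering unit)\">",
    "##FILTER=<ID=rp_filtered,Description=\"Removed by depth, bimodal or validator filtering\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">"
  )
  if (nrow(df) > 0) {
    hdr <- c(hdr, paste0("##contig=<ID=", sort(unique(df$chrom)), ">"))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  writeLines(hdr, con)
  if (nrow(df) > 0) {
    df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
    cls <- if ("class" %in% names(df)) unname(rpclass_tags[df$class]) else
      rep(NA_character_, nrow(df))
    status <- if ("status" %in% names(df)) df$status else rep("PASS", nrow(df))
    af <- df$alt_depth / (df$ref_depth + df$alt_depth)
    info <- paste0(
      ifelse(is.na(cls), "", paste0("RPCLASS=", cls, ";")),
      "AF=", formatC(af, digits = 6, format = "g"))
    if ("isoform_id" %in% names(df)) {
      has_iso <- !is.na(df$isoform_id)
      info[has_iso] <- paste0(info[has_iso], ";ISO=", df$isoform_id[has_iso])
    }
    gt <- ifelse(df$ref_depth == 0, "1/1", "0/1")
    lines <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".",
                   ifelse(status == "PASS", "PASS", "rp_filtered"),
                   info, "GT:AD:DP",
                   paste0(gt, ":", df$ref_depth, ",", df$alt_depth, ":",
                          df$total_depth),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
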