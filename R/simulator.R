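# sample that never falls into the scalar-x trap of base sample()
resample <- function(x, size) x[sample.int(length(x), size)]

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spike-in design configuration
#'
#' The per-cell composition of the simulated truth set: 650 homozygous and 280
#' non-bimodally-distributed heterozygous variants planted at unrestricted
#' viable (>= 20x) sites, plus bimodally-distributed heterozygous variants on
#' 23 expressed isoforms carrying 2-5 variants each (about 70 in total, mean
#' about 3 per isoform) -- roughly 1000 truth variants per cell.
#'
#' @param n_hom homozygous truth variants (default 650).
#' @param n_het_nb non-bimodal heterozygous truth variants (default 280).
#' @param n_isoforms_bim expressed isoforms receiving bimodal variants
#'   (default 23).
#' @param per_isoform_weights sampling weights for the per-isoform variant
#'   count; names are counts. The default `c("2"=.30,"3"=.45,"4"=.16,"5"=.09)`
#'   has mean 3.04, so 23 isoforms yield about 70 bimodal variants.
#' @param min_depth minimum read depth for a site to be spikeable (default 20).
#' @param min_viable_span an isoform is usable for bimodal spiking only if it
#'   has more than this many viable exonic positions (default 250).
#' @param tpm_min strict TPM bound defining "expressed" (default 1).
#' @param seed RNG seed making the plan reproducible.
#' @return a classed list (`rp_spike_config`).
#' @export
spike_config <- function(n_hom = 650L, n_het_nb = 280L, n_isoforms_bim = 23L,
                         per_isoform_weights = c("2" = 0.30, "3" = 0.45,
                                                 "4" = 0.16, "5" = 0.09),
                         min_depth = 20L, min_viable_span = 250L,
                         tpm_min = 1.0, seed = 1L) {
  stopifnot(n_hom > 0, n_het_nb > 0, n_isoforms_bim > 0, min_depth > 0)
  if (abs(sum(per_isoform_weights) - 1) > 1e-8) {
    stop("per_isoform_weights must sum to 1")
  }
  if (is.null(names(per_isoform_weights))) {
    stop("per_isoform_weights must be named by variant count")
  }
  structure(list(n_hom = as.integer(n_hom), n_het_nb = as.integer(n_het_nb),
                 n_isoforms_bim = as.integer(n_isoforms_bim),
                 per_isoform_weights = per_isoform_weights,
                 min_depth = as.integer(min_depth),
                 min_viable_span = as.integer(min_viable_span),
                 tpm_min = tpm_min, seed = as.integer(seed)),
            class = "rp_spike_config")
}

majority_base <- function(reads, index, chrom, pos) {
  p <- pileup_at(reads, chrom, pos, index = index)
  names(sort(table(p$base), decreasing = TRUE))[1]
}

#' Plan a variant spike-in
#'
#' Draws a truth set of the three variant classes against an existing read
#' set. Homozygous (`HOM`, target fraction 1) and non-bimodal heterozygous
#' (`HET_NB`, target fraction 0.5) sites are drawn uniformly from all viable
#' positions. For the bimodal class, `n_isoforms_bim` isoforms are drawn among
#' the expressed (TPM > `tpm_min`) isoforms having more than `min_viable_span`
#' viable exonic positions; each receives 2-5 variants (per the configured
#' weights) sharing one folded fraction drawn uniformly in [0.1, 0.4], each
#' record independently placed at `f` or `1 - f`. Reference bases are taken
#' from the read consensus; alternate alleles are drawn uniformly from the
#' three non-reference bases. The plan is deterministic given the seed.
#'
#' @param reads an `rp_reads` object.
#' @param isoforms an `rp_isoforms` object (expression set, or supply `quant`).
#' @param quant optional named TPM vector.
#' @param config an [spike_config()].
#' @return an object of class `rp_truth_set`: a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`, `class` (`HOM`/`HET_NB`/`HET_BIM`),
#'   `target_fraction`, `isoform_id`, with the configuration attached as
#'   attribute `config`.
#' @export
plan_spike <- function(reads, isoforms, quant = NULL, config = spike_config()) {
  stopifnot(inherits(config, "rp_spike_config"))
  if (!is.null(quant)) isoforms <- set_expression(isoforms, quant)
  viable <- viable_sites(reads, config$min_depth)
  tx <- isoforms$transcripts
  expressed <- tx[!is.na(tx$tpm) & tx$tpm > config$tpm_min, , drop = FALSE]
  # viable positions inside each expressed isoform's exons
  ex <- isoforms$exons[isoforms$exons$transcript_id %in%
                         expressed$transcript_id, , drop = FALSE]
  ex$chrom <- expressed$chrom[match(ex$transcript_id, expressed$transcript_id)]
  vgr <- GenomicRanges::GRanges(viable$chrom,
                                IRanges::IRanges(viable$pos, viable$pos))
  egr <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$start0 + 1L, ex$end0))
  hits <- IRanges::findOverlaps(vgr, egr)
  site_tx <- split(S4Vectors::queryHits(hits),
                   ex$transcript_id[S4Vectors::subjectHits(hits)])
  eligible <- names(site_tx)[lengths(site_tx) > config$min_viable_span]
  if (length(eligible) < config$n_isoforms_bim) {
    stop("need ", config$n_isoforms_bim, " expressed isoforms with more than ",
         config$min_viable_span, " viable positions, found ", length(eligible))
  }
  with_seed(config$seed, {
    idx <- reads_index(reads)
    chosen_tx <- resample(eligible, config$n_isoforms_bim)
    kvals <- as.integer(names(config$per_isoform_weights))
    used <- rep(FALSE, nrow(viable))
    bim <- vector("list", length(chosen_tx))
    for (i in seq_along(chosen_tx)) {
      tid <- chosen_tx[i]
      k <- sample(kvals, 1, prob = config$per_isoform_weights)
      f <- stats::runif(1, 0.1, 0.4)
      avail <- setdiff(site_tx[[tid]], which(used))
      if (length(avail) < k) {
        stop("isoform ", tid, " ran out of unused viable positions")
      }
      rows <- resample(avail, k)
      used[rows] <- TRUE
      hi <- stats::runif(k) < 0.5
      bim[[i]] <- data.frame(
        chrom = viable$chrom[rows], pos = viable$pos[rows],
        class = "HET_BIM",
        target_fraction = ifelse(hi, 1 - f, f),
        isoform_id = tid, stringsAsFactors = FALSE)
    }
    bim <- do.call(rbind, bim)
    navail <- sum(!used)
    nfree <- config$n_hom + config$n_het_nb
    if (navail < nfree) {
      stop("need ", nfree, " unrestricted viable sites, found ", navail)
    }
    rows <- resample(which(!used), nfree)
    free <- data.frame(
      chrom = viable$chrom[rows], pos = viable$pos[rows],
      class = rep(c("HOM", "HET_NB"), c(config$n_hom, config$n_het_nb)),
      target_fraction = rep(c(1.0, 0.5), c(config$n_hom, config$n_het_nb)),
      isoform_id = NA_character_, stringsAsFactors = FALSE)
    truth <- rbind(free[free$class == "HOM", ], bim,
                   free[free$class == "HET_NB", ])
    truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
    truth$ref <- vapply(seq_len(nrow(truth)), function(i)
      majority_base(reads, idx, truth$chrom[i], truth$pos[i]), "")
    bases <- c("A", "C", "G", "T")
    truth$alt <- vapply(truth$ref, function(r)
      sample(setdiff(bases, r), 1), "")
    truth <- truth[, c("chrom", "pos", "ref", "alt", "class",
                       "target_fraction", "isoform_id")]
    rownames(truth) <- NULL
    structure(truth, class = c("rp_truth_set", "data.frame"), config = config)
  })
}

#' @export
print.rp_truth_set <- function(x, ...) {
  cat("<rp_truth_set> ", nrow(x), " planned variants: ", sep = "")
  print(table(x$class))
  invisible(x)
}

#' Insert planned variants into the alignments
#'
#' At each homozygous truth site every covering read is rewritten to carry the
#' alternate base; at each heterozygous site `round(depth * target_fraction)`
#' reads drawn without replacement are rewritten. Base qualities and all other
#' read content are untouched. A truth site whose depth has dropped below the
#' plan's viability threshold is a hard error.
#'
#' @param reads the `rp_reads` object the truth set was planned on.
#' @param truth an `rp_truth_set` from [plan_spike()].
#' @param seed RNG seed for the read draws.
#' @return the modified `rp_reads` object.
#' @export
apply_spike <- function(reads, truth, seed = 1L) {
  stopifnot(inherits(truth, "rp_truth_set"))
  cfg <- attr(truth, "config")
  min_depth <- if (!is.null(cfg)) cfg$min_depth else 1L
  idx <- reads_index(reads)
  seqs <- reads$seq
  with_seed(seed, {
    for (i in seq_len(nrow(truth))) {
      rows <- covering_rows(idx, truth$chrom[i], truth$pos[i])
      depth <- length(rows)
      if (depth < min_depth) {
        stop("truth site ", truth$chrom[i], ":", truth$pos[i],
             " is no longer viable (depth ", depth, " < ", min_depth, ")")
      }
      n_alt <- if (truth$class[i] == "HOM") depth else
        as.integer(round(depth * truth$target_fraction[i]))
      pick <- if (n_alt >= depth) rows else resample(rows, n_alt)
      off <- truth$pos[i] - reads$pos[pick] + 1L
      substr(seqs[pick], off, off) <- truth$alt[i]
    }
  })
  reads$seq <- seqs
  reads
}

#' Generate a self-contained synthetic fixture
#'
#' Builds, from nothing but a seed, everything a calling run needs: a random
#' reference, non-overlapping multi-exon isoforms laid out along it, reads
#' tiled over every exon at approximately the requested depth with uniform
#' high base quality, and a quantification vector in which a configurable
#' subset of isoforms is expressed (TPM > 1). Coverage and expression are
#' deliberately decoupled: all exons receive reads so that the unrestricted
#' spike-in classes can land outside the expressed set, as they do in
#' transcriptome-scale data. Output is byte-identical for a fixed seed.
#'
#' @param genome_size total reference length in bp.
#' @param n_chrom number of chromosomes the genome is split into.
#' @param n_isoforms number of single-isoform genes to lay out.
#' @param n_expressed how many isoforms receive TPM > 1.
#' @param exons_per_isoform,exon_len,intron_len,gap gene geometry in bp.
#' @param read_len,depth read length and target coverage over exons.
#' @param seed RNG seed.
#' @return a list of class `rp_fixture`: `reference` (named character),
#'   `seqlengths`, `isoforms` (`rp_isoforms` with TPM set), `quant` (named
#'   numeric), `reads` (`rp_reads`).
#' @export
generate_fixture <- function(genome_size = 2e6, n_chrom = 2L,
                             n_isoforms = 600L, n_expressed = 23L,
                             exons_per_isoform = 3L, exon_len = 400L,
                             intron_len = 300L, gap = 400L,
                             read_len = 100L, depth = 30L, seed = 1L) {
  stopifnot(genome_size > 0, n_chrom >= 1, exon_len >= read_len, depth >= 1)
  n_expressed <- min(n_expressed, n_isoforms)
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    clen <- rep(floor(genome_size / n_chrom), n_chrom)
    names(clen) <- chroms
    reference <- vapply(clen, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
    gene_span <- exons_per_isoform * exon_len +
      (exons_per_isoform - 1L) * intron_len
    per_chrom <- floor((clen - gap) / (gene_span + gap))
    if (n_isoforms > 0 && sum(per_chrom) < n_isoforms) {
      stop("infeasible fixture: ", n_isoforms, " isoforms of span ", gene_span,
           " bp do not fit a ", genome_size, " bp genome")
    }
    if (n_isoforms == 0) {
      iso <- rp_isoforms(
        data.frame(transcript_id = character(), gene_id = character(),
                   chrom = character(), strand = character(), tpm = numeric()),
        data.frame(transcript_id = character(), start0 = integer(),
                   end0 = integer()))
      return(structure(list(reference = reference, seqlengths = clen,
                            isoforms = iso, quant = stats::setNames(numeric(), character()),
                            reads = rp_reads()),
                       class = "rp_fixture"))
    }
    chrom_of <- rep(chroms, per_chrom)[seq_len(n_isoforms)]
    rank_in <- stats::ave(seq_len(n_isoforms), chrom_of, FUN = seq_along)
    gstart0 <- gap + (rank_in - 1L) * (gene_span + gap)  # 0-based gene start
    tid <- sprintf("TX%04d", seq_len(n_isoforms))
    tx <- data.frame(
      transcript_id = tid,
      gene_id = sprintf("G%04d", seq_len(n_isoforms)),
      chrom = chrom_of,
      strand = sample(c("+", "-"), n_isoforms, replace = TRUE),
      tpm = NA_real_, stringsAsFactors = FALSE)
    eo <- seq_len(exons_per_isoform) - 1L
    ex <- data.frame(
      transcript_id = rep(tid, each = exons_per_isoform),
      start0 = as.integer(rep(gstart0, each = exons_per_isoform) +
                            rep(eo, n_isoforms) * (exon_len + intron_len)),
      stringsAsFactors = FALSE)
    ex$end0 <- ex$start0 + exon_len
    expressed <- sample(tid, n_expressed)
    tpm <- stats::setNames(stats::runif(n_isoforms, 0, 0.9), tid)
    tpm[expressed] <- stats::runif(n_expressed, 5, 500)
    tx$tpm <- unname(tpm[tx$transcript_id])
    iso <- rp_isoforms(tx, ex)
    # tile reads over every exon
    step <- read_len / depth
    ex$chrom <- tx$chrom[match(ex$transcript_id, tx$transcript_id)]
    starts <- lapply(seq_len(nrow(ex)), function(i)
      as.integer(round(seq(ex$start0[i] + 1L, ex$end0[i] - read_len + 1L,
                           by = step))))
    rchrom <- rep(ex$chrom, lengths(starts))
    rpos <- unlist(starts)
    rseq <- substring(reference[rchrom], rpos, rpos + read_len - 1L)
    reads <- rp_reads(sprintf("r%07d", seq_along(rpos)), rchrom, rpos, rseq)
    structure(list(reference = reference, seqlengths = clen, isoforms = iso,
                   quant = tpm, reads = reads),
              class = "rp_fixture")
  })
}

#' @export
print.rp_fixture <- function(x, ...) {
  cat("<rp_fixture> ", sum(x$seqlengths), " bp reference (",
      length(x$reference), " chromosome(s)), ",
      nrow(x$isoforms$transcripts), " isoforms (",
      sum(x$isoforms$transcripts$tpm > 1, na.rm = TRUE), " expressed), ",
      nrow(x$reads), " reads\n", sep = "")
  invisible(x)
}

#' Write a fixture to standard files
#'
#' Emits `reference.fa`, `annotation.gtf`, `quant.tsv` and `reads.sam` under
#' `dir` so that external tools (or the command-line interface) can consume
#' the fixture.
#'
#' @param fixture an `rp_fixture` from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             quant = file.path(dir, "quant.tsv"),
             reads = file.path(dir, "reads.sam"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$reference), paths["reference"])
  ex <- fixture$isoforms$exons
  tx <- fixture$isoforms$transcripts
  m <- match(ex$transcript_id, tx$transcript_id)
  gr <- GenomicRanges::GRanges(
    tx$chrom[m], IRanges::IRanges(ex$start0 + 1L, ex$end0),
    strand = tx$strand[m])
  gr$type <- "exon"
  gr$source <- "redpanda"
  gr$transcript_id <- ex$transcript_id
  gr$gene_id <- tx$gene_id[m]
  rtracklayer::export(gr, paths["annotation"], format = "gtf")
  utils::write.table(
    data.frame(Name = names(fixture$quant), TPM = unname(fixture$quant)),
    paths["quant"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_sam(fixture$reads, paths["reads"], seqlengths = fixture$seqlengths)
  paths
}

#' Write a truth set as VCF
#'
#' Sorted VCF v4.2 with INFO tags `RPTRUTH` (class) and `TF` (target
#' fraction), the reference list a benchmarking run scores against.
#'
#' @param truth an `rp_truth_set`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_truth_vcf <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=redpanda-simulator",
    "##INFO=<ID=RPTRUTH,Number=1,Type=String,Description=\"Truth class: HOM, HET_NB or HET_BIM\">",
    "##INFO=<ID=TF,Number=1,Type=Float,Description=\"Target allele fraction\">",
    "##INFO=<ID=ISO,Number=1,Type=String,Description=\"Isoform carrying a bimodal truth variant\">")
  if (nrow(truth)) {
    hdr <- c(hdr, paste0("##contig=<ID=", sort(unique(truth$chrom)), ">"))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  writeLines(hdr, con)
  if (nrow(truth)) {
    truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
    info <- paste0("RPTRUTH=", truth$class, ";TF=",
                   formatC(truth$target_fraction, digits = 6, format = "g"),
                   ifelse(is.na(truth$isoform_id), "",
                          paste0(";ISO=", truth$isoform_id)))
    writeLines(paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}
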