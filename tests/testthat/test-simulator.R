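small_fixture <- function(seed = 3, n_isoforms = 40, n_expressed = 12,
                          genome_size = 2e5) {
  generate_fixture(genome_size = genome_size, n_chrom = 2,
                   n_isoforms = n_isoforms, n_expressed = n_expressed,
                   seed = seed)
}

small_spike <- function(seed = 3) {
  spike_config(n_hom = 60, n_het_nb = 30, n_isoforms_bim = 8, seed = seed)
}

test_that("viable sites are exactly the positions at or above the depth floor", {
  # hand-built ragged coverage
  reads <- rp_reads(paste0("r", 1:25), rep("chr1", 25),
                    c(rep(1L, 20), rep(8L, 5)), rep(strrep("A", 10), 25))
  v <- viable_sites(reads, min_depth = 20L)
  # positions 1..7 have depth 20; 8..10 have 25; beyond 10 only 5
  expect_equal(v$pos, 1:10)
  expect_equal(v$depth[v$pos == 9], 25L)
  v19 <- rp_reads(paste0("q", 1:19), rep("chr1", 19), rep(1L, 19),
                  rep(strrep("C", 10), 19))
  expect_equal(nrow(viable_sites(v19, 20L)), 0L)  # 19x stays below the floor
})

test_that("coverage agrees with a naive per-position count", {
  set.seed(61)
  reads <- rp_reads(paste0("r", 1:80), rep("chr1", 80),
                    sample(500, 80, TRUE),
                    vapply(sample(20:60, 80, TRUE),
                           function(L) strrep("A", L), ""))
  cov <- coverage_vector(reads, "chr1")
  for (p in sample(length(cov), 40)) {
    expect_equal(cov[p], naive_depth(reads, "chr1", p))
  }
})

test_that("spike plans are deterministic in the seed and class-conserving", {
  fix <- small_fixture()
  t1 <- plan_spike(fix$reads, fix$isoforms, config = small_spike(seed = 9))
  t2 <- plan_spike(fix$reads, fix$isoforms, config = small_spike(seed = 9))
  t3 <- plan_spike(fix$reads, fix$isoforms, config = small_spike(seed = 10))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
  tab <- table(t1$class)
  expect_equal(unname(tab["HOM"]), 60L)
  expect_equal(unname(tab["HET_NB"]), 30L)
  expect_equal(sum(tab), nrow(t1))
  expect_false(any(duplicated(paste(t1$chrom, t1$pos))))
})

test_that("planned truth respects the class fraction contracts", {
  fix <- small_fixture()
  truth <- plan_spike(fix$reads, fix$isoforms, config = small_spike())
  expect_true(all(truth$target_fraction[truth$class == "HOM"] == 1))
  expect_true(all(truth$target_fraction[truth$class == "HET_NB"] == 0.5))
  bim <- truth[truth$class == "HET_BIM", ]
  expect_true(all(!is.na(bim$isoform_id)))
  for (tid in unique(bim$isoform_id)) {
    f <- bim$target_fraction[bim$isoform_id == tid]
    expect_gte(length(f), 2L)
    folded <- unique(round(pmin(f, 1 - f), 12))
    expect_length(folded, 1L)       # one folded fraction per isoform
    expect_gte(folded, 0.1)
    expect_lte(folded, 0.4)
  }
  # bimodal sites sit inside their isoform's exons and the isoform is expressed
  tx <- fix$isoforms$transcripts
  expect_true(all(tx$tpm[match(unique(bim$isoform_id), tx$transcript_id)] > 1))
})

test_that("a plan that cannot be satisfied fails loudly", {
  fix <- small_fixture()
  too_many <- spike_config(n_hom = 60, n_het_nb = 30, n_isoforms_bim = 500,
                           seed = 1)
  expect_error(plan_spike(fix$reads, fix$isoforms, config = too_many),
               "500 expressed isoforms")
  greedy <- spike_config(n_hom = 10^6, n_het_nb = 30, n_isoforms_bim = 8,
                         seed = 1)
  expect_error(plan_spike(fix$reads, fix$isoforms, config = greedy),
               "unrestricted viable sites")
})

test_that("applying the spike reproduces every target fraction", {
  fix <- small_fixture()
  truth <- plan_spike(fix$reads, fix$isoforms, config = small_spike())
  spiked <- apply_spike(fix$reads, truth, seed = 4)
  idx <- redpanda:::reads_index(spiked)
  for (i in seq_len(nrow(truth))) {
    p <- pileup_at(spiked, truth$chrom[i], truth$pos[i], index = idx)
    n_alt <- sum(p$base == truth$alt[i])
    depth <- nrow(p)
    if (truth$class[i] == "HOM") {
      expect_equal(n_alt, depth)
    } else {
      expect_lte(abs(n_alt - depth * truth$target_fraction[i]), 1)
      expect_equal(n_alt, round(depth * truth$target_fraction[i]))
    }
  }
  # qualities and untouched reads are preserved
  expect_identical(spiked$qual, fix$reads$qual)
  expect_identical(spiked$pos, fix$reads$pos)
})

test_that("a truth site without viable depth aborts the spike", {
  fix <- small_fixture()
  truth <- plan_spike(fix$reads, fix$isoforms, config = small_spike())
  bad <- truth
  bad$pos[1] <- 1L  # the gap before the first gene carries no reads
  expect_error(apply_spike(fix$reads, bad, seed = 4), "no longer viable")
})

test_that("fixtures are reproducible, exon-covered and bounded by the genome", {
  f1 <- small_fixture(seed = 8)
  f2 <- small_fixture(seed = 8)
  expect_identical(f1, f2)
  # interior exonic depth near the target, checked against the naive count
  ex <- f1$isoforms$exons[1, ]
  ch <- f1$isoforms$transcripts$chrom[1]
  mid <- as.integer((ex$start0 + ex$end0) / 2)
  d <- naive_depth(f1$reads, ch, mid)
  expect_gte(d, 28L)
  expect_lte(d, 32L)
  expect_error(generate_fixture(genome_size = 1e4, n_isoforms = 100, seed = 1),
               "infeasible")
  empty <- generate_fixture(genome_size = 1e4, n_isoforms = 0, seed = 1)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(nrow(empty$isoforms$transcripts), 0L)
  expect_length(empty$quant, 0L)
})

test_that("fixture files round-trip through the standard formats", {
  fix <- small_fixture(seed = 13, n_isoforms = 6, n_expressed = 3,
                       genome_size = 4e4)
  dir <- tempfile()
  paths <- write_fixture(fix, dir)
  expect_true(all(file.exists(paths)))
  ref <- Biostrings::readDNAStringSet(paths["reference"])
  expect_equal(sort(names(ref)), sort(names(fix$reference)))
  expect_equal(as.character(ref[["chr1"]]), fix$reference[["chr1"]])
  iso <- read_annotation(paths["annotation"])
  expect_equal(sort(iso$transcripts$transcript_id),
               sort(fix$isoforms$transcripts$transcript_id))
  got_ex <- iso$exons[order(iso$exons$transcript_id, iso$exons$start0), ]
  want_ex <- fix$isoforms$exons[order(fix$isoforms$exons$transcript_id,
                                      fix$isoforms$exons$start0), ]
  expect_equal(got_ex$start0, want_ex$start0)
  expect_equal(got_ex$end0, want_ex$end0)
  q <- read_quant_table(paths["quant"])
  expect_equal(q[names(fix$quant)], fix$quant)
  reads <- read_sam(paths["reads"])
  expect_equal(nrow(reads), nrow(fix$reads))
  o1 <- order(reads$qname); o2 <- order(fix$reads$qname)
  expect_equal(reads$pos[o1], fix$reads$pos[o2])
  expect_equal(reads$seq[o1], fix$reads$seq[o2])
})
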