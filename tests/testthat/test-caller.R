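test_that("variants go to the highest-TPM expressed isoform containing them", {
  iso <- make_isoforms(a = cbind(100, 200), b = cbind(150, 250),
                       c = cbind(400, 500), tpm = c(3, 8, 5))
  x <- rp_candidates(rep("chr1", 4), c(160, 110, 450, 300),
                     rep("A", 4), rep("G", 4), ref_depth = 10, alt_depth = 10)
  got <- assign_to_isoform(x, iso)
  # 160 sits in both a and b: exhaustive comparison of the overlapping pair
  overl <- iso$transcripts[iso$transcripts$transcript_id %in% c("a", "b"), ]
  expect_equal(got[1], overl$transcript_id[which.max(overl$tpm)])
  expect_equal(got[2], "a")     # only isoform containing 110
  expect_equal(got[3], "c")
  expect_true(is.na(got[4]))    # intronic/intergenic
})

test_that("TPM exactly at the threshold does not count as expressed", {
  iso <- make_isoforms(a = cbind(100, 200), tpm = 1.0)
  x <- rp_candidates("chr1", 150, "A", "G", 10, 10)
  expect_true(is.na(assign_to_isoform(x, iso, tpm_min = 1.0)))
  iso2 <- make_isoforms(a = cbind(100, 200), tpm = 1.0001)
  expect_equal(assign_to_isoform(x, iso2, tpm_min = 1.0), "a")
})

# a forced fixture where every stage's outcome is pinned:
# 5 hom (depth >= 10), 4 bimodal het at folded mode 0.3 on isoform "iso1",
# 2 het at 0.5 outside any expressed isoform, confirmed by the validator
forced_inputs <- function() {
  iso <- make_isoforms(iso1 = cbind(1000, 2000), tpm = 40)
  hom <- rp_candidates(rep("chr1", 5), seq(100, 500, by = 100),
                       rep("A", 5), rep("T", 5),
                       ref_depth = 0, alt_depth = c(10, 12, 15, 20, 30))
  bim <- cands_at(seq(1100, 1400, by = 100), c(0.7, 0.3, 0.7, 0.3), depth = 20)
  nb <- cands_at(c(5000, 6000), c(0.5, 0.5), depth = 20)
  list(iso = iso, cand = rbind(hom, bim, nb))
}

test_that("call_cell assembles the three paths into one PASS set", {
  inp <- forced_inputs()
  cs <- call_cell(inp$cand, inp$iso)
  calls <- cs$calls
  expect_equal(sum(calls$status == "PASS"), 11L)
  expect_equal(as.integer(table(calls$class[calls$status == "PASS"])[
    c("HOMOZYGOUS_LOOKING", "HET_BIMODAL", "HET_NONBIMODAL")]), c(5L, 4L, 2L))
  expect_equal(unique(calls$isoform_id[calls$class == "HET_BIMODAL"]), "iso1")
})

test_that("a mid-fraction variant on a bimodal isoform is filtered when rejected", {
  inp <- forced_inputs()
  intruder <- cands_at(1500, 0.5, depth = 20)
  cand <- rbind(inp$cand, intruder)
  reject_all <- function(q)
    data.frame(chrom = q$chrom, pos = q$pos, ref = q$ref, alt = q$alt,
               verdict = "REJECT", source = "TEST")
  cs <- call_cell(cand, inp$iso, validator = reject_all)
  got <- cs$calls[cs$calls$pos == 1500, ]
  expect_equal(got$class, "HET_NONBIMODAL")
  expect_equal(got$status, "FILTERED")
  # the bimodal quartet is untouched by the validator
  expect_equal(sum(cs$calls$status == "PASS" &
                     cs$calls$class == "HET_BIMODAL"), 4L)
})

test_that("all-homozygous input below the depth floor yields zero PASS calls", {
  x <- rp_candidates(rep("chr1", 4), 1:4 * 100, rep("A", 4), rep("G", 4),
                     ref_depth = 0, alt_depth = c(9, 5, 3, 8))
  cs <- call_cell(x, make_isoforms(a = cbind(1, 10), tpm = 5))
  expect_equal(sum(cs$calls$status == "PASS"), 0L)
})

test_that("every candidate gets exactly one class and one status", {
  set.seed(53)
  iso <- make_isoforms(a = cbind(100, 1000), b = cbind(2000, 3000),
                       tpm = c(20, 0.5))
  n <- 60
  x <- rp_candidates(rep("chr1", n), sample(3500, n),
                     sample(c("A", "C"), n, TRUE), sample(c("G", "T"), n, TRUE),
                     ref_depth = sample(0:20, n, TRUE),
                     alt_depth = sample(1:20, n, TRUE))
  cs <- call_cell(x, iso)
  expect_equal(nrow(cs$calls), n)
  expect_true(all(cs$calls$class %in%
                    c("HOMOZYGOUS_LOOKING", "HET_BIMODAL", "HET_NONBIMODAL")))
  expect_true(all(cs$calls$status %in% c("PASS", "FILTERED")))
  expect_equal(sum(table(cs$calls$class)), n)
})

test_that("call_cell is deterministic and deduplicates the PASS set", {
  inp <- forced_inputs()
  cs1 <- call_cell(inp$cand, inp$iso)
  cs2 <- call_cell(inp$cand, inp$iso)
  expect_identical(cs1$calls, cs2$calls)
  dup <- rbind(inp$cand, inp$cand[1, ])
  csd <- call_cell(dup, inp$iso)
  k <- variant_key(csd$calls[csd$calls$status == "PASS", ])
  expect_false(any(duplicated(k)))
})

test_that("raising the depth floor never grows the homozygous pass set", {
  set.seed(59)
  x <- rp_candidates(rep("chr1", 30), 1:30, rep("A", 30), rep("G", 30),
                     ref_depth = 0, alt_depth = sample(1:40, 30, TRUE))
  prev <- nrow(filter_homozygous_looking(x, 1L)$pass)
  for (d in c(5L, 10L, 20L, 40L)) {
    cur <- nrow(filter_homozygous_looking(x, d)$pass)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("bimodal PASS calls always reference an expressed isoform", {
  inp <- forced_inputs()
  cs <- call_cell(inp$cand, inp$iso)
  bim <- cs$calls[cs$calls$class == "HET_BIMODAL" & cs$calls$status == "PASS", ]
  tx <- inp$iso$transcripts
  expect_true(all(tx$tpm[match(bim$isoform_id, tx$transcript_id)] > 1))
})

test_that("indels flow through the same pipeline as SNVs", {
  iso <- make_isoforms(iso1 = cbind(1000, 2000), tpm = 40)
  snv <- cands_at(c(1100, 1200), c(0.3, 0.7), depth = 20)
  indel <- rp_candidates(rep("chr1", 2), c(1300, 1400), c("AT", "A"),
                         c("A", "AGG"), ref_depth = c(14, 6),
                         alt_depth = c(6, 14))
  cs <- call_cell(rbind(snv, indel), iso)
  got <- cs$calls[cs$calls$is_indel, ]
  expect_equal(got$class, rep("HET_BIMODAL", 2))
  expect_equal(got$status, rep("PASS", 2))
})
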