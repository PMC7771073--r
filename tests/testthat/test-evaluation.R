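keyset <- function(pos, chrom = "chr1", ref = "A", alt = "G") {
  paste(chrom, pos, ref, alt, sep = ":")
}

test_that("confusion counts recovered, extra and missed variants", {
  truth <- keyset(1:10)
  calls <- c(keyset(1:8), keyset(101:102))  # 8 recovered, 2 extra
  cf <- confusion(calls, truth)
  expect_equal(cf$tp, 8L)
  expect_equal(cf$fp, 2L)
  expect_equal(cf$fn, 2L)
  expect_true(is.na(cf$tn))
  zero <- confusion(character(), character())
  expect_equal(c(zero$tp, zero$fp, zero$fn), c(0L, 0L, 0L))
})

test_that("non-comparable positions are excluded from every count", {
  # six sites: truth at 1..4 (4 uncovered on the call side), calls at 3,4,5
  truth <- keyset(1:4)
  calls <- keyset(3:5)
  comparable <- paste("chr1", c(1, 2, 3, 5, 6, 50), sep = ":")  # 4 not comparable
  cf <- confusion(calls, truth, comparable = comparable)
  expect_equal(cf$tp, 1L)   # site 3
  expect_equal(cf$fp, 1L)   # site 5
  expect_equal(cf$fn, 2L)   # 1 and 2; site 4 excluded from fn
  expect_equal(cf$tn, 2L)   # 6 and 50
})

test_that("calls at comparable positions split exactly into tp and fp", {
  set.seed(71)
  truth <- keyset(sample(100, 40))
  calls <- keyset(sample(100, 50))
  comparable <- paste("chr1", sample(100, 80), sep = ":")
  cf <- confusion(calls, truth, comparable = comparable)
  n_cmp_calls <- sum(sub(":[^:]+:[^:]+$", "", calls) %in% comparable)
  expect_equal(cf$tp + cf$fp, n_cmp_calls)
})

test_that("sensitivity, PPV and FDR follow their definitions", {
  cf <- structure(list(tp = 8L, fp = 0L, fn = 2L, tn = NA), class = "rp_confusion")
  expect_equal(sensitivity(cf), 0.8)
  cf2 <- structure(list(tp = 9L, fp = 11L, fn = 0L, tn = NA),
                   class = "rp_confusion")
  expect_equal(ppv(cf2), 0.45)
  expect_equal(fdr(cf2), 0.55)
  degen <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = NA),
                     class = "rp_confusion")
  expect_warning(p <- ppv(degen), "undefined")
  expect_true(is.na(p))
})

test_that("pairwise overlap enumerates all unordered pairs symmetrically", {
  sets <- list(a = keyset(1:10), b = keyset(6:15), c = keyset(1:10),
               d = keyset(100:101))
  ov <- pairwise_overlap(sets)
  expect_equal(nrow(ov), 6L)  # 4 * 3 / 2
  ab <- ov[ov$cell_a == "a" & ov$cell_b == "b", ]
  expect_equal(ab$shared, 5L)
  expect_equal(ab$fraction, 5 / 15)
  expect_equal(ov[ov$cell_a == "a" & ov$cell_b == "c", "fraction"], 1.0)
  expect_equal(ov[ov$cell_a == "a" & ov$cell_b == "d", "shared"], 0L)
  expect_equal(ov[ov$cell_a == "a" & ov$cell_b == "d", "fraction"], 0)
  # reversing the input order flips labels, not values
  ov2 <- pairwise_overlap(rev(sets))
  f1 <- ov$fraction[ov$cell_a == "a" & ov$cell_b == "b"]
  f2 <- ov2$fraction[(ov2$cell_a == "b" & ov2$cell_b == "a") |
                       (ov2$cell_a == "a" & ov2$cell_b == "b")]
  expect_equal(f1, f2)
  expect_equal(attr(ov, "denominator"), "jaccard")
})

test_that("ensemble intersection is threshold counting", {
  sets <- list(keyset(c(1, 2, 3)), keyset(c(2, 3, 4)), keyset(c(3, 5)))
  kept <- ensemble_intersection(sets, min_support = 2L)
  expect_true(keyset(2) %in% kept)   # in 2 of 3
  expect_false(keyset(1) %in% kept)  # in 1 of 3
  expect_equal(kept, sort(keyset(c(2, 3))))
  expect_equal(ensemble_intersection(sets, 1L),
               sort(Reduce(union, sets)))
  expect_equal(ensemble_intersection(sets, 3L),
               sort(Reduce(intersect, sets)))
  expect_error(ensemble_intersection(sets[1], 2L), "at least")
})

test_that("ensemble intersection equals a counting oracle on random sets", {
  set.seed(73)
  for (t in 1:20) {
    m <- sample(3:6, 1)
    sets <- lapply(seq_len(m), function(i) keyset(sample(30, sample(5:20, 1))))
    ms <- sample(2:m, 1)
    got <- ensemble_intersection(sets, ms)
    counts <- table(unlist(lapply(sets, unique)))
    want <- sort(names(counts)[counts >= ms])
    expect_equal(got, want)
  }
})

test_that("cells far outside the exon profile are removed with a reason", {
  metrics <- data.frame(cell = paste0("c", 1:6),
                        outside_exon_pct = c(10, 11, 10.5, 9.8, 10.2, 40))
  qc <- cell_qc(metrics)
  expect_equal(qc$keep, c(rep(TRUE, 5), FALSE))
  expect_equal(qc$reasons[6], "outside-exons")
})

test_that("identical cells all pass QC", {
  metrics <- data.frame(cell = paste0("c", 1:4), outside_exon_pct = rep(12, 4))
  expr <- matrix(rep(c(5, 0, 9, 2, 7, 1), 4), ncol = 4,
                 dimnames = list(NULL, paste0("c", 1:4)))
  qc <- cell_qc(metrics, expr = expr)
  expect_true(all(qc$keep))
})

test_that("an uncorrelated expression profile is removed, matching the t-transform", {
  set.seed(79)
  base <- rexp(60, 1 / 50)
  expr <- sapply(1:5, function(i) pmax(base + rnorm(60, 0, 2), 0))
  expr <- cbind(expr, runif(60, 0, 150))  # one unrelated cell
  colnames(expr) <- paste0("c", 1:6)
  metrics <- data.frame(cell = colnames(expr), outside_exon_pct = 10)
  pooled <- rowMeans(expr[, 1:5])
  qc <- cell_qc(metrics, expr = expr, pooled = pooled)
  # oracle: p-value from the t-transform of r for the suspect cell
  r <- cor(log1p(expr[, 6]), log1p(pooled))
  tt <- r * sqrt(58) / sqrt(1 - r^2)
  p_oracle <- 2 * stats::pt(-abs(tt), df = 58)
  expect_equal(qc$keep[6], p_oracle <= 0.05)
  expect_false(qc$keep[6])
  expect_match(qc$reasons[6], "correlation")
  expect_true(all(qc$keep[1:5]))
})

test_that("QC needs at least three cells", {
  metrics <- data.frame(cell = c("a", "b"), outside_exon_pct = c(1, 2))
  expect_warning(qc <- cell_qc(metrics), "fewer than 3")
  expect_true(all(qc$keep))
})

test_that("read-count floor removes shallow cells when configured", {
  metrics <- data.frame(cell = paste0("c", 1:4),
                        outside_exon_pct = rep(10, 4),
                        read_count = c(1e6, 2e6, 5e4, 3e6))
  qc <- cell_qc(metrics, min_reads = 1e5)
  expect_equal(qc$keep, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(qc$reasons[3], "read-count")
})
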