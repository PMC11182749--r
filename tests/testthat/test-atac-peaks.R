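## BED-convention helper: build internal 1-based peaks from 0-based
## half-open coordinates so examples can be stated in BED terms.
bed_peaks <- function(chrom, start0, end) {
  data.frame(chrom = chrom, start = start0 + 1L, end = end,
             stringsAsFactors = FALSE)
}

test_that("replicate overlap rule keeps/merges exactly at the 50% boundary", {
  a <- bed_peaks("chr1", 100, 200)
  b <- bed_peaks("chr1", 150, 250)
  out <- reproducible_peaks(a, b)
  expect_equal(out, bed_peaks("chr1", 100, 250))   # overlap = 50% of shorter
  b2 <- bed_peaks("chr1", 190, 300)
  expect_equal(nrow(reproducible_peaks(a, b2)), 0L) # overlap 10 < 50%
})

test_that("replicate filtering matches an exhaustive all-pairs oracle", {
  a <- random_peaks(200, seed = 31)
  b <- random_peaks(200, seed = 32)
  out <- reproducible_peaks(a, b)
  ## oracle: loop over all pairs, keep qualifying intervals, merge
  kept <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L
    if (ov <= 0) next
    shorter <- min(a$end[i] - a$start[i] + 1L, b$end[j] - b$start[j] + 1L)
    if (ov >= 0.5 * shorter) {
      kept[[length(kept) + 1L]] <- a[i, ]
      kept[[length(kept) + 1L]] <- b[j, ]
    }
  }
  oracle <- merge_intervals_oracle(unique(do.call(rbind, kept)))
  expect_equal(out, oracle)
  ## symmetry as interval sets
  expect_equal(reproducible_peaks(b, a), out)
})

test_that("replicate filtering refuses unsorted input", {
  a <- bed_peaks("chr1", c(500, 100), c(600, 200))
  b <- bed_peaks("chr1", 100, 200)
  expect_error(reproducible_peaks(a, b), "sorted")
})

test_that("peak union merges across sets and is idempotent", {
  s1 <- bed_peaks("chr1", 100, 200)
  expect_equal(union_peaks(list(s1)), s1)
  s2 <- bed_peaks("chr1", 150, 250)
  expect_equal(union_peaks(list(s1, s2)), bed_peaks("chr1", 100, 250))
  sets <- lapply(41:43, function(s) random_peaks(120, seed = s))
  u <- union_peaks(sets)
  expect_equal(u, merge_intervals_oracle(do.call(rbind, sets)))
  expect_equal(union_peaks(list(u)), u)
})

test_that("peak annotation applies the TSS > proximal > genic > distal precedence", {
  tss <- data.frame(gene = "g1", chrom = "chr1", tss = 10000)
  gm <- data.frame(gene = "g1", chrom = "chr1", start = 9000, end = 20000)
  near <- data.frame(chrom = "chr1", start = 10200, end = 10400) # centre 300 bp
  expect_equal(as.character(annotate_peaks(near, tss, gm)$categories), "TSS")
  prox <- data.frame(chrom = "chr1", start = 12900, end = 13100) # 3 kb, in gene
  expect_equal(as.character(annotate_peaks(prox, tss, gm)$categories),
               "proximal")
  genic <- data.frame(chrom = "chr1", start = 17000, end = 17200) # 7 kb, in gene
  expect_equal(as.character(annotate_peaks(genic, tss, gm)$categories),
               "genic")
  far <- data.frame(chrom = "chr1", start = 50000, end = 50200)
  expect_equal(as.character(annotate_peaks(far, tss, gm)$categories),
               "distal")
})

test_that("annotation counts equal a brute-force per-peak classification", {
  peaks <- random_peaks(500, max_pos = 1e6, seed = 51)
  set.seed(52)
  tss <- data.frame(gene = sprintf("g%02d", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    tss = sample.int(1e6, 40))
  gm <- data.frame(gene = tss$gene, chrom = tss$chrom,
                   start = tss$tss, end = tss$tss + 20000)
  got <- annotate_peaks(peaks, tss, gm)
  oracle <- vapply(seq_len(nrow(peaks)), function(i) {
    ctr <- floor((peaks$start[i] + peaks$end[i]) / 2)
    d <- min(abs(ctr - tss$tss[tss$chrom == peaks$chrom[i]]), Inf)
    inside <- any(gm$chrom == peaks$chrom[i] & gm$start <= ctr & ctr <= gm$end)
    if (d <= 1000) "TSS" else if (d <= 5000) "proximal"
    else if (inside) "genic" else "distal"
  }, character(1))
  expect_equal(as.character(got$categories), oracle)
})

test_that("differential accessibility is null for identical groups", {
  m <- matrix(2^rnorm(400, 8, 0.5), 100, 4)
  m[, 3:4] <- m[, 1:2]
  da <- moderated_differential_accessibility(m, factor(rep(c("a", "b"),
                                                           each = 2)))
  expect_equal(da$logFC, rep(0, 100))
  expect_false(any(da$significant))
})

test_that("moderated t reduces to the classic two-sample t at d0 = 0", {
  set.seed(61)
  m <- 2^matrix(rnorm(150 * 6, 8, 0.4), 150, 6)
  gr <- factor(rep(c("a", "b"), each = 3))
  da <- moderated_differential_accessibility(m, gr, offset = 0,
                                             d0_override = 0)
  x <- log2(m)
  tt <- vapply(seq_len(nrow(x)), function(i)
    stats::t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)$statistic,
    numeric(1))
  expect_equal(da$t, unname(tt), tolerance = 1e-12)
  pp <- vapply(seq_len(nrow(x)), function(i)
    stats::t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)$p.value,
    numeric(1))
  expect_equal(da$p, unname(pp), tolerance = 1e-12)
})

test_that("empirical-Bayes moderation matches the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(62)
  s <- sqrt(1 / stats::rgamma(300, shape = 2, rate = 2))
  m <- 2^(matrix(rnorm(300 * 6, 8, 0.1), 300, 6) +
            matrix(rnorm(300 * 6), 300, 6) * s)
  gr <- factor(rep(c("a", "b"), each = 3))
  da <- moderated_differential_accessibility(m, gr, offset = 0)
  fit <- limma::eBayes(limma::lmFit(log2(m), stats::model.matrix(~gr)))
  expect_equal(attr(da, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(da, "s02"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(da$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(da$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("the DA test is calibrated and powered on planted simulations", {
  null <- simulate_atac_counts(n_peaks = 10000, planted_fc = 1, seed = 71)
  da0 <- moderated_differential_accessibility(null$density, null$groups)
  ci <- stats::qbinom(c(0.005, 0.995), 10000, 0.01) / 10000
  expect_gte(mean(da0$p < 0.01), ci[1])
  expect_lte(mean(da0$p < 0.01), ci[2])
  expect_lte(mean(da0$padj < 0.01), 0.01)     # BH null discoveries
  pw <- simulate_atac_counts(n_peaks = 4000, planted_fc = 4, frac_da = 0.05,
                             noise_sd = 0.25, seed = 72)
  da1 <- moderated_differential_accessibility(pw$density, pw$groups)
  expect_gte(mean(da1$significant[pw$labels$is_da]), 0.9)
})

test_that("top-by-fold-change ranks, bounds and breaks ties deterministically", {
  tab <- data.frame(peak = paste0("p", 1:5),
                    logFC = c(2, -1, 3, 2, 0.5),
                    chrom = "chr1", start = c(500, 100, 900, 200, 300),
                    end = c(600, 200, 1000, 300, 400))
  expect_equal(nrow(top_by_foldchange(tab, n = 5)), 5L)
  top3 <- top_by_foldchange(tab, n = 3)
  expect_equal(top3$peak, c("p3", "p4", "p1"))  # tie at 2 -> lower start first
  perm <- tab[c(4, 1, 5, 3, 2), ]
  expect_equal(top_by_foldchange(perm, n = 3)$peak, top3$peak)
  expect_equal(top_by_foldchange(tab, n = 2, direction = "down")$peak,
               c("p2", "p5"))
  expect_error(top_by_foldchange(tab, n = 10), "exceeds")
})
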