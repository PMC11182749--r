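test_that("peaks are assigned to the nearest TSS with deterministic ties", {
  tss <- data.frame(gene = c("b_gene", "a_gene"), chrom = "chr1",
                    tss = c(1000, 3000))
  one <- data.frame(chrom = "chr1", start = 1400, end = 1600, name = "p1")
  got <- assign_peaks_to_genes(one, tss, max_distance = 1e5)
  expect_equal(got$gene, "b_gene")
  expect_equal(got$distance, 500)
  ## centre exactly equidistant between the two TSS
  mid <- data.frame(chrom = "chr1", start = 1900, end = 2100, name = "p2")
  expect_equal(assign_peaks_to_genes(mid, tss)$gene, "a_gene")
  far <- data.frame(chrom = "chr1", start = 900000, end = 900100, name = "p3")
  expect_true(is.na(assign_peaks_to_genes(far, tss, max_distance = 1e5)$gene))
})

test_that("nearest-TSS assignment equals exhaustive search on random fixtures", {
  peaks <- random_peaks(1000, max_pos = 5e5, seed = 81)
  peaks$name <- sprintf("p%04d", seq_len(nrow(peaks)))
  set.seed(82)
  tss <- data.frame(gene = sprintf("g%03d", 1:150),
                    chrom = sample(c("chr1", "chr2"), 150, replace = TRUE),
                    tss = sample.int(5e5, 150))
  got <- assign_peaks_to_genes(peaks, tss, max_distance = 5e4)
  oracle <- vapply(seq_len(nrow(peaks)), function(i) {
    ctr <- floor((peaks$start[i] + peaks$end[i]) / 2)
    sub <- tss[tss$chrom == peaks$chrom[i], ]
    d <- abs(ctr - sub$tss)
    if (!length(d) || min(d) > 5e4) return(NA_character_)
    sort(sub$gene[d == min(d)])[1]
  }, character(1))
  expect_equal(got$gene, oracle)
})

test_that("motif scanning matches consensus, strand symmetry and brute force", {
  pwm <- list(id = "M1", name = "tf1",
              counts = matrix(c(97, 1, 1, 1,   # A
                                1, 97, 1, 1,   # C
                                1, 1, 97, 1,   # G
                                1, 1, 1, 97,   # T
                                97, 1, 1, 1),  # A
                              nrow = 4,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  hits <- scan_motifs(c(s1 = "ACGTA"), list(pwm))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$strand, "+")
  maxsc <- sum(apply(log2(sweep(pwm$counts + 0.01, 2,
                                colSums(pwm$counts + 0.01), "/") / 0.25),
                     2, max))
  expect_equal(hits$score, maxsc, tolerance = 1e-12)
  ## reverse complement of the consensus is found on the minus strand
  hits_rc <- scan_motifs(c(s1 = "TACGT"), list(pwm))
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, maxsc, tolerance = 1e-12)
  ## PWM longer than sequence: no hits, no error
  expect_equal(nrow(scan_motifs(c(s = "ACG"), list(pwm))), 0L)
  ## windows containing N are skipped
  expect_equal(nrow(scan_motifs(c(s = "ACGNA"), list(pwm))), 0L)
})

test_that("hit sets equal an all-window brute-force scan of random sequence", {
  set.seed(91)
  seqs <- c(r1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                       collapse = ""))
  pwms <- lapply(1:3, function(i) {
    counts <- matrix(stats::rpois(4 * 7, 10) + 1, 4, 7,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    list(id = paste0("M", i), name = paste0("tf", i), counts = counts)
  })
  got <- scan_motifs(seqs, pwms, score_fraction = 0.75)
  ## independent oracle: naive double loop, both strands
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rows <- list()
  for (p in pwms) {
    pr <- sweep(p$counts + 0.01, 2, colSums(p$counts + 0.01), "/")
    lod <- log2(pr / 0.25)
    w <- ncol(lod); L <- nchar(seqs)
    thr <- 0.75 * sum(apply(lod, 2, max))
    score1 <- function(sub) {
      ch <- strsplit(sub, "")[[1]]
      sum(vapply(seq_len(w), function(k) lod[ch[k], k], numeric(1)))
    }
    for (s in seq_len(L - w + 1)) {
      sub <- substr(seqs, s, s + w - 1)
      sc_f <- score1(sub); sc_r <- score1(rc(sub))
      if (sc_f >= thr)
        rows[[length(rows) + 1L]] <- data.frame(seqname = "r1", motif = p$id,
                                                start = s, strand = "+",
                                                score = sc_f)
      if (sc_r >= thr)
        rows[[length(rows) + 1L]] <- data.frame(seqname = "r1", motif = p$id,
                                                start = s, strand = "-",
                                                score = sc_r)
    }
  }
  oracle <- do.call(rbind, rows)
  key <- function(d) paste(d$motif, d$start, d$strand)
  expect_setequal(key(got), key(oracle))
  m <- match(key(got), key(oracle))
  expect_equal(got$score, oracle$score[m], tolerance = 1e-10)
  ## monotonicity: lowering the threshold never removes a hit
  more <- scan_motifs(seqs, pwms, score_fraction = 0.6)
  expect_true(all(key(got) %in% key(more)))
})

test_that("base GRN assembly respects provenance and many-to-many motifs", {
  p2g <- data.frame(peak = c("p1", "p2"), gene = c("g1", "g2"))
  empty <- data.frame(seqname = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0))
  t2m <- data.frame(tf = c("A", "B"), motif = c("m1", "m1"))
  b0 <- build_base_grn(p2g, empty, t2m)
  expect_equal(nrow(b0$pairs), 0L)
  hits <- data.frame(seqname = "p1", motif = "m1", start = 5L,
                     strand = "+", score = 10)
  b1 <- build_base_grn(p2g, hits, t2m)
  expect_equal(b1$pairs, data.frame(tf = c("A", "B"), gene = "g1"))
  expect_error(build_base_grn(p2g, transform(hits, motif = "mX"), t2m),
               "without TF mapping")
})

test_that("decoy-free synthetic genome round-trips to the planted incidence", {
  gen0 <- simulate_regulatory_genome(small_sim$truth, seed = 13,
                                     decoy_rate = 0)
  p2g <- assign_peaks_to_genes(gen0$peaks, gen0$tss)
  hits <- scan_motifs(gen0$peak_sequences, gen0$pwms)
  base <- build_base_grn(p2g, hits, gen0$tf2motif)
  truth_keys <- sort(paste(small_sim$truth$edges$tf,
                           small_sim$truth$edges$target))
  expect_equal(sort(paste(base$pairs$tf, base$pairs$gene)), truth_keys)
})

test_that("base GRN pair set is invariant under reverse-complementing input", {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  seqs_rc <- vapply(small_gen$peak_sequences, rc, character(1))
  hits_rc <- scan_motifs(seqs_rc, small_gen$pwms)
  base_rc <- build_base_grn(small_p2g, hits_rc, small_gen$tf2motif)
  expect_setequal(paste(base_rc$pairs$tf, base_rc$pairs$gene),
                  paste(small_base$pairs$tf, small_base$pairs$gene))
})
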