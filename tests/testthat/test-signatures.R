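test_that("rank-sum DE is null for identical groups", {
  set.seed(190)
  half <- matrix(rnorm(12), 4, 3)
  norm <- cbind(half, half)   # group B duplicates group A per gene
  rownames(norm) <- paste0("g", 1:4)
  ds <- make_norm_dataset(norm)
  de <- wilcoxon_de(ds, 1:3, 4:6)
  expect_equal(de$p, rep(1, 4))
  expect_equal(de$logFC, rep(0, 4))
})

test_that("exact p-values equal enumeration of all rank splits (4 vs 4)", {
  set.seed(191)
  norm <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("g", 1:3), NULL))
  ds <- make_norm_dataset(norm)
  de <- wilcoxon_de(ds, 1:4, 5:8)
  for (g in rownames(norm)) {
    v <- norm[g, ]
    u_obs <- sum(rank(v)[1:4]) - 10
    splits <- utils::combn(8, 4)
    u_all <- apply(splits, 2, function(ix) sum(rank(v)[ix]) - 10)
    p_exact <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(de$p[de$gene == g], p_exact, tolerance = 1e-12)
  }
})

test_that("rank-sum p-values agree with the stats reference in both regimes", {
  set.seed(192)
  ## no ties, exact regime
  norm <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(paste0("g", 1:5), NULL))
  ds <- make_norm_dataset(norm)
  de <- wilcoxon_de(ds, 1:10, 11:20)
  for (g in rownames(norm)) {
    ref <- stats::wilcox.test(norm[g, 1:10], norm[g, 11:20])
    expect_equal(de$p[de$gene == g], ref$p.value, tolerance = 1e-12)
    expect_equal(de$stat[de$gene == g], unname(ref$statistic))
  }
  ## ties force the corrected normal approximation
  normt <- matrix(sample(1:4, 5 * 30, TRUE), 5, 30,
                  dimnames = list(paste0("t", 1:5), NULL))
  dst <- make_norm_dataset(normt)
  det <- wilcoxon_de(dst, 1:15, 16:30)
  for (g in rownames(normt)) {
    ref <- suppressWarnings(stats::wilcox.test(normt[g, 1:15],
                                               normt[g, 16:30]))
    expect_equal(det$p[det$gene == g], ref$p.value, tolerance = 1e-12)
  }
})

test_that("a planted two-fold shift is detected at adjusted p < 0.05", {
  set.seed(193)
  n <- 100
  base <- matrix(rnorm(20 * 2 * n, 2, 0.5), 20, 2 * n,
                 dimnames = list(paste0("g", 1:20), NULL))
  base["g1", 1:n] <- base["g1", 1:n] + log(2)   # shifted group A
  ds <- make_norm_dataset(base)
  de <- wilcoxon_de(ds, 1:n, (n + 1):(2 * n))
  expect_lt(de$padj[de$gene == "g1"], 0.05)
  expect_gt(de$logFC[de$gene == "g1"], 0.5)
  expect_equal(de$padj, pmin(1, de$p * 20))
})

test_that("signature definition filters by thresholds and direction", {
  de <- data.frame(gene = paste0("g", 1:5),
                   logFC = c(1.2, 0.6, 0.4, -0.8, 0.9),
                   padj = c(0.01, 0.2, 0.01, 0.01, 0.04))
  sig <- define_signature_from_de(de)
  expect_setequal(sig$genes, c("g1", "g5"))
  dn <- define_signature_from_de(de, direction = "down")
  expect_equal(dn$genes, "g4")
  expect_error(define_signature_from_de(de, logfc_min = 5), "review")
  ## monotone in both thresholds
  set.seed(201)
  for (i in 1:20) {
    rde <- data.frame(gene = paste0("g", 1:50),
                      logFC = rnorm(50), padj = runif(50))
    pass <- function(l, p) tryCatch(
      define_signature_from_de(rde, logfc_min = l, padj_max = p)$genes,
      error = function(e) character(0))
    expect_true(all(pass(0.5, 0.05) %in% pass(0.25, 0.05)))
    expect_true(all(pass(0.5, 0.05) %in% pass(0.5, 0.2)))
  }
})

test_that("regulator signatures take top-PS TFs plus their strong targets", {
  grn <- make_grn(data.frame(regulator = c("A", "A", "B"),
                             target = c("t1", "t2", "t3"),
                             coefficient = c(0.5, 0.05, 0.4),
                             stability = 1, pvalue = 0), state = "PrP")
  sc <- data.frame(tf = c("A", "B"), mode = rep(c("OE", "KO"), each = 2),
                   sum_pos = c(5, 1, 0.1, 0.2), sum_neg = c(-1, -2, -6, -0.1))
  sig <- regulator_signature(sc, grn, top_n = 1)
  ## OE top by sum_pos -> A; KO top by most negative -> A; targets |w|>0.1
  expect_setequal(sig$genes, c("A", "t1"))
  sig_all <- regulator_signature(sc, grn, top_n = 2)
  expect_setequal(sig_all$genes, c("A", "B", "t1", "t3"))
  high <- regulator_signature(sc, grn, top_n = 2, connectivity_min = 10)
  expect_setequal(high$genes, c("A", "B"))
  ## random-table oracle
  set.seed(202)
  tfs <- paste0("TF", 1:12)
  rsc <- expand.grid(tf = tfs, mode = c("KO", "OE"),
                     stringsAsFactors = FALSE)
  rsc$sum_pos <- runif(24, 0, 5); rsc$sum_neg <- -runif(24, 0, 5)
  redges <- random_edges(150, c(tfs, paste0("t", 1:30)), seed = 203)
  rgrn <- make_grn(redges)
  got <- regulator_signature(rsc, rgrn, top_n = 3, polarity = "negative")
  oe <- rsc[rsc$mode == "OE", ]; ko <- rsc[rsc$mode == "KO", ]
  top_tfs <- union(oe$tf[order(oe$sum_neg)][1:3],
                   ko$tf[order(-ko$sum_pos)][1:3])
  tg <- redges$target[redges$regulator %in% top_tfs &
                        abs(redges$coefficient) > 0.1]
  expect_setequal(got$genes, union(top_tfs, tg))
})

test_that("rank signature score follows the capped Mann-Whitney formula", {
  ## a cell whose top-ranked genes are exactly the signature scores 1
  norm <- matrix(c(10, 9, 8, 1, 2, 3, 0.5, 0.2, 0.1, 0), ncol = 1,
                 dimnames = list(paste0("g", 1:10), "c1"))
  norm <- cbind(norm, norm)  # two identical cells (need >= 1 column each)
  colnames(norm) <- c("c1", "c2")
  ds <- make_norm_dataset(norm)
  expect_equal(unname(rank_signature_score(ds, paste0("g", 1:3),
                                           r_max = 5)["c1"]), 1)
  ## hand case: n = 2, r_max = 5, both genes beyond the cap -> 0.1
  sig <- c("g8", "g9")   # ranks 8, 9 -> capped at 6
  expect_equal(unname(rank_signature_score(ds, sig, r_max = 5)["c1"]), 0.1)
  expect_error(rank_signature_score(ds, "absent"), "no signature gene")
  expect_error(rank_signature_score(ds, "g1", r_max = 10), "smaller")
})

test_that("signature scores equal a direct capped-MWU oracle and are
           invariant under monotone transforms", {
  set.seed(211)
  norm <- matrix(rexp(60 * 8), 60, 8,
                 dimnames = list(paste0("g", 1:60), paste0("c", 1:8)))
  ds <- make_norm_dataset(norm)
  sig <- sample(rownames(norm), 7)
  rmax <- 20
  got <- rank_signature_score(ds, sig, r_max = rmax)
  for (ci in 1:8) {
    r <- rank(-norm[, ci])
    capped <- pmin(r[sig], rmax + 1)
    u <- sum(capped) - 7 * 8 / 2
    expect_equal(unname(got[ci]), min(1, max(0, 1 - u / (7 * rmax))),
                 tolerance = 1e-12)
  }
  ## monotone transform of each cell's expression leaves scores unchanged
  ds2 <- ds; ds2$norm <- sqrt(ds$norm) + 3
  expect_equal(rank_signature_score(ds2, sig, r_max = rmax), got)
  ## degrading a signature gene's rank never increases the score
  ds3 <- ds; ds3$norm[sig[1], ] <- min(ds$norm) - 1
  expect_true(all(rank_signature_score(ds3, sig, r_max = rmax) <= got + 1e-12))
})
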