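## State-contrast differential expression (rank-sum), signature
## definition from DE tables or perturbation scores, and per-cell
## rank-based (capped Mann-Whitney) signature scoring.

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided rank-sum test of group A versus group B on the
#' normalised layer, with Bonferroni correction across tested genes.
#' The log fold change is the difference of mean log-normalised
#' expression (A minus B). P-values use the exact rank-sum null
#' distribution when both groups have at most `exact_max` cells and
#' the gene has no tied values; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param dataset a [cell_dataset()].
#' @param groupA,groupB cell selectors (state names, cell ids, logical
#'   or integer indices); both groups need at least 3 cells.
#' @param genes genes to test (default all).
#' @param exact_max maximal per-group size for the exact distribution.
#' @return data.frame: `gene`, `logFC`, `stat` (Mann-Whitney U of
#'   group A), `p`, `padj` (Bonferroni), sorted by ascending p then
#'   gene name.
#' @export
wilcoxon_de <- function(dataset, groupA, groupB, genes = NULL,
                        exact_max = 50) {
  stopifnot(inherits(dataset, "cell_dataset"))
  ia <- resolve_cells(dataset, groupA)
  ib <- resolve_cells(dataset, groupB)
  if (length(ia) < 3 || length(ib) < 3)
    stopf("both groups need at least 3 cells")
  if (length(intersect(ia, ib)))
    stopf("groups overlap")
  genes <- genes %||% dataset$genes
  n1 <- length(ia); n2 <- length(ib); n <- n1 + n2
  xa <- dataset$norm[genes, ia, drop = FALSE]
  xb <- dataset$norm[genes, ib, drop = FALSE]
  logfc <- rowMeans(xa) - rowMeans(xb)
  stat <- numeric(length(genes)); p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    v <- c(xa[i, ], xb[i, ])
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    stat[i] <- U
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (!has_ties && max(n1, n2) <= exact_max) {
      p[i] <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                             stats::pwilcox(n1 * n2 - U, n2, n1)))
    } else {
      mu <- n1 * n2 / 2
      tiecor <- sum(ties^3 - ties) / (n * (n - 1))
      sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tiecor))
      if (sigma == 0) { p[i] <- 1; next }
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sigma     # continuity correction
      p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  out <- data.frame(gene = genes, logFC = logfc, stat = stat, p = p,
                    padj = pmin(1, p * length(genes)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Define a gene signature from a differential-expression table
#'
#' Genes passing both the log-fold-change and adjusted-p thresholds in
#' the stated direction (defaults: logFC > 0.5 and adjusted p < 0.05,
#' up-regulated).
#'
#' @param de table from [wilcoxon_de()].
#' @param logfc_min minimal |logFC| in the stated direction.
#' @param padj_max maximal adjusted p.
#' @param direction `"up"` or `"down"`.
#' @param name signature name.
#' @return list of class `signature_definition` with `name`, `genes`
#'   and `provenance`. Errors when no gene passes, prompting threshold
#'   review.
#' @export
define_signature_from_de <- function(de, logfc_min = 0.5, padj_max = 0.05,
                                     direction = c("up", "down"),
                                     name = "signature") {
  direction <- match.arg(direction)
  stopifnot(all(c("gene", "logFC", "padj") %in% names(de)))
  pass <- de$padj < padj_max &
    (if (direction == "up") de$logFC > logfc_min else de$logFC < -logfc_min)
  if (!any(pass))
    stopf("no gene passes (logFC %s %.2f, padj < %.3g); review thresholds",
          if (direction == "up") ">" else "< -", logfc_min, padj_max)
  structure(list(name = name, genes = sort(de$gene[pass]),
                 provenance = sprintf("DE %s: |logFC|>%.2f, padj<%.3g",
                                      direction, logfc_min, padj_max)),
            class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes (%s)\n", x$name, length(x$genes),
              x$provenance))
  invisible(x)
}

#' Regulator signature from perturbation scores and a state network
#'
#' Positive-regulator signatures take the TFs with the `top_n` highest
#' positive perturbation-score sums under overexpression or most
#' negative sums under knockout (union of both rankings); negative
#' regulators the converse. The signature is those TFs plus their
#' targets in the supplied network with |coefficient| above
#' `connectivity_min` (default 0.1, the "strong interaction"
#' threshold).
#'
#' @param scores perturbation score table (`tf`, `mode`, `sum_pos`,
#'   `sum_neg`) covering the network's TFs.
#' @param grn the state network supplying targets (e.g. the PrP GRN).
#' @param top_n TFs per ranking (default 10).
#' @param connectivity_min minimal |edge coefficient| for included
#'   targets.
#' @param polarity `"positive"` or `"negative"` regulators.
#' @return A `signature_definition`.
#' @export
regulator_signature <- function(scores, grn, top_n = 10,
                                connectivity_min = 0.1,
                                polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(grn, "state_grn"))
  oe <- scores[scores$mode == "OE", ]
  ko <- scores[scores$mode == "KO", ]
  pick <- function(df, col, decreasing) {
    if (nrow(df) == 0) return(character(0))
    df$tf[utils::head(order(df[[col]], decreasing = decreasing), top_n)]
  }
  tfs <- if (polarity == "positive") {
    union(pick(oe, "sum_pos", TRUE), pick(ko, "sum_neg", FALSE))
  } else {
    union(pick(oe, "sum_neg", FALSE), pick(ko, "sum_pos", TRUE))
  }
  e <- grn$edges
  targets <- unique(e$target[e$regulator %in% tfs &
                               abs(e$coefficient) > connectivity_min])
  structure(list(name = paste0(polarity, "_regulators"),
                 genes = sort(union(tfs, targets)),
                 provenance = sprintf(
                   "%s regulators: top %d by PS + targets with |coef|>%.2f in state '%s'",
                   polarity, top_n, connectivity_min, grn$state)),
            class = "signature_definition")
}

#' Per-cell rank-based signature score (capped Mann-Whitney)
#'
#' For each cell, all genes are ranked by decreasing expression
#' (average ranks for ties), signature-gene ranks are capped at
#' `r_max + 1`, and the score is
#' `1 - U' / (n * r_max)` clamped to [0, 1], with
#' `U' = sum(capped ranks) - n (n + 1) / 2` for `n` signature genes.
#' A cell whose top-ranked genes are exactly the signature scores 1.
#' The score is invariant under monotone transforms of a cell's
#' expression values.
#'
#' @param dataset a [cell_dataset()].
#' @param signature a `signature_definition` or a character vector of
#'   gene names; at least one gene must be present in the dataset.
#' @param r_max rank cap; must be below the gene count. Default
#'   `min(1500, n_genes - 1)`.
#' @param cells cell selector (default all).
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
rank_signature_score <- function(dataset, signature, r_max = NULL,
                                 cells = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"))
  genes <- if (inherits(signature, "signature_definition"))
    signature$genes else as.character(signature)
  genes <- intersect(genes, dataset$genes)
  if (length(genes) == 0) stopf("no signature gene present in the dataset")
  ng <- length(dataset$genes)
  r_max <- r_max %||% min(1500, ng - 1L)
  if (r_max >= ng) stopf("r_max must be smaller than the gene count (%d)", ng)
  idx <- resolve_cells(dataset, cells)
  n <- length(genes)
  sig_rows <- match(genes, dataset$genes)
  scores <- vapply(idx, function(ci) {
    r <- rank(-dataset$norm[, ci])
    capped <- pmin(r[sig_rows], r_max + 1)
    u <- sum(capped) - n * (n + 1) / 2
    clamp(1 - u / (n * r_max), 0, 1)
  }, numeric(1))
  stats::setNames(scores, dataset$cells$cell_id[idx])
}
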