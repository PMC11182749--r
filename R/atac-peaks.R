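## ATAC peak handling: replicate reproducibility, pan-peak union,
## genomic-feature annotation, and moderated differential accessibility.

## data.frame (1-based inclusive) -> GRanges, verifying sort order
peaks_to_granges <- function(peaks, require_sorted = FALSE, what = "peaks") {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start > peaks$end)) stopf("%s: start > end", what)
  if (require_sorted) {
    ord <- order(peaks$chrom, peaks$start, peaks$end)
    if (!identical(ord, seq_len(nrow(peaks))))
      stopf("%s must be sorted by (chrom, start, end); sort the input explicitly",
            what)
  }
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start, peaks$end))
}

granges_to_peaks <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Reproducible peaks between two biological replicates
#'
#' Keeps peak pairs whose overlap is at least `min_overlap` of the
#' shorter peak's length and merges each qualifying pair (chains of
#' qualifying overlaps merge into one interval), following the rule
#' that condition-specific peak lists contain peaks overlapping at
#' least 50% between biological replicates.
#'
#' @param repA,repB peak data.frames (`chrom`, `start`, `end`; 1-based
#'   inclusive), each sorted by (chrom, start, end).
#' @param min_overlap required overlap as a fraction of the shorter
#'   peak, in (0, 1].
#' @return Sorted data.frame of merged reproducible intervals.
#' @export
reproducible_peaks <- function(repA, repB, min_overlap = 0.5) {
  if (min_overlap <= 0 || min_overlap > 1)
    stopf("min_overlap must lie in (0, 1]")
  ga <- peaks_to_granges(repA, require_sorted = TRUE, what = "repA")
  gb <- peaks_to_granges(repB, require_sorted = TRUE, what = "repB")
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  qa <- ga[S4Vectors::queryHits(hits)]
  qb <- gb[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::width(GenomicRanges::pintersect(qa, qb))
  shorter <- pmin(GenomicRanges::width(qa), GenomicRanges::width(qb))
  keep <- ov >= min_overlap * shorter
  if (!any(keep))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  kept <- c(qa[keep], qb[keep])
  granges_to_peaks(GenomicRanges::reduce(kept))
}

#' Union (pan) peak list across peak sets
#'
#' Pools all intervals and merges overlapping ones into maximal
#' intervals; the pan list is the union of the condition-specific
#' lists.
#'
#' @param peaksets list of peak data.frames.
#' @return Sorted data.frame of merged intervals.
#' @export
union_peaks <- function(peaksets) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  if (length(peaksets) < 1) stopf("need at least one peak set")
  grl <- lapply(peaksets, peaks_to_granges)
  granges_to_peaks(GenomicRanges::reduce(do.call(c, grl)))
}

#' Annotate peaks by genomic feature category
#'
#' Classifies each peak by the distance from its centre to the nearest
#' transcription start site: `TSS` (within `tss_dist`), `proximal`
#' (within `proximal_dist`), `genic` (peak centre inside a gene body)
#' or `distal`, applying the first matching category in that order.
#'
#' @param peaks peak data.frame.
#' @param tss data.frame with `gene`, `chrom`, `tss` (1-based position).
#' @param gene_models optional data.frame with `gene`, `chrom`,
#'   `start`, `end` delimiting gene bodies; without it no peak can be
#'   `genic`.
#' @param tss_dist distance defining the `TSS` category (default 1 kb).
#' @param proximal_dist distance defining `proximal` (default 5 kb).
#' @return list with `categories` (factor per peak), `proportions` and
#'   `distance` (centre-to-nearest-TSS distance per peak).
#' @export
annotate_peaks <- function(peaks, tss, gene_models = NULL,
                           tss_dist = 1000, proximal_dist = 5000) {
  if (nrow(tss) == 0) stopf("TSS table is empty")
  centre <- floor((peaks$start + peaks$end) / 2)
  dist <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    tpos <- tss$tss[tss$chrom == ch]
    idx <- which(peaks$chrom == ch)
    if (length(tpos) == 0 || length(idx) == 0) next
    dist[idx] <- vapply(centre[idx], function(p) min(abs(p - tpos)),
                        numeric(1))
  }
  genic <- rep(FALSE, nrow(peaks))
  if (!is.null(gene_models) && nrow(gene_models) > 0) {
    gp <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(centre, centre))
    gm <- GenomicRanges::GRanges(gene_models$chrom,
                                 IRanges::IRanges(gene_models$start,
                                                  gene_models$end))
    genic <- GenomicRanges::countOverlaps(gp, gm) > 0
  }
  cat <- ifelse(dist <= tss_dist, "TSS",
                ifelse(dist <= proximal_dist, "proximal",
                       ifelse(genic, "genic", "distal")))
  categories <- factor(cat, levels = c("TSS", "proximal", "genic", "distal"))
  list(categories = categories,
       proportions = prop.table(table(categories)),
       distance = dist)
}

#' Moderated differential accessibility between two groups
#'
#' Two-group comparison of log2 read densities with empirical-Bayes
#' variance moderation: per-peak residual variances s^2 on d = n - 2
#' degrees of freedom are shrunk towards a prior (d0, s0^2) estimated
#' by moment matching of log s^2 against its theoretical scaled-F
#' distribution (trigamma inversion); the moderated t uses posterior
#' variance (d0 s0^2 + d s^2) / (d0 + d) on d0 + d degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted; a peak is significant when
#' |log2 FC| exceeds `log2(fc_threshold)` and the adjusted p-value is
#' below `padj_threshold` (defaults: >2-fold and p-adj < 0.01).
#'
#' @param density peaks x samples matrix of non-negative read
#'   densities.
#' @param groups factor (two levels) assigning samples to groups; the
#'   reported fold change is level 2 minus level 1.
#' @param fc_threshold linear fold-change significance threshold.
#' @param padj_threshold adjusted-p significance threshold.
#' @param offset added to densities before log2 (default 1) to keep
#'   sparse peaks finite; use 0 for already-stabilised densities.
#' @param d0_override force the prior degrees of freedom: `0` gives the
#'   ordinary two-sample t-statistic, `Inf` the fully pooled
#'   (z-like) statistic; `NULL` estimates d0 from the data.
#' @param peaks optional peak data.frame whose `chrom`, `start`, `end`
#'   are attached to the result (enables coordinate tie-breaking in
#'   [top_by_foldchange()]).
#' @return data.frame (one row per peak): `peak`, `logFC`, `t`, `p`,
#'   `padj`, `significant`, `direction`, plus coordinates when `peaks`
#'   is given. Attributes `d0` and `s02` carry the fitted prior.
#' @export
moderated_differential_accessibility <- function(density, groups,
                                                 fc_threshold = 2,
                                                 padj_threshold = 0.01,
                                                 offset = 1,
                                                 d0_override = NULL,
                                                 peaks = NULL) {
  density <- as.matrix(density)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("groups must have exactly two levels")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stopf("need at least 2 samples per group")
  if (any(density < 0)) stopf("densities must be non-negative")
  x <- log2(density + offset)
  x1 <- x[, groups == levels(groups)[1], drop = FALSE]
  x2 <- x[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m2 - m1
  d <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / d

  if (!is.null(d0_override) && d0_override == 0) {
    d0 <- 0; s02 <- NA_real_
    s2post <- s2
  } else {
    pos <- s2[s2 > 0]
    if (length(pos) == 0) {
      warnf("all within-group variances are zero; using pooled-variance branch")
      d0 <- Inf; s02 <- mean(s2)
      s2post <- rep(s02, length(s2))
    } else {
      s2e <- s2
      if (any(s2 == 0)) {
        warnf("%d peak(s) with zero within-group variance; floored for prior fit",
              sum(s2 == 0))
        s2e[s2 == 0] <- min(pos) / 2
      }
      z <- log(s2e)
      e <- z - digamma(d / 2) + log(d / 2)
      emean <- mean(e)
      evar <- stats::var(e) - trigamma(d / 2)
      if (!is.null(d0_override) && is.infinite(d0_override)) evar <- 0
      if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(emean)
      }
      s2post <- if (is.infinite(d0)) rep(s02, length(s2e))
                else (d0 * s02 + d * s2e) / (d0 + d)
    }
  }
  tstat <- logfc / sqrt(s2post * (1 / n1 + 1 / n2))
  dft <- d0 + d
  p <- if (is.infinite(dft)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = dft)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(peak = rownames(density) %||%
                      sprintf("peak_%05d", seq_len(nrow(density))),
                    logFC = logfc, t = tstat, p = p, padj = padj,
                    significant = abs(logfc) > log2(fc_threshold) &
                      padj < padj_threshold,
                    direction = sign(logfc),
                    stringsAsFactors = FALSE)
  if (!is.null(peaks)) {
    stopifnot(nrow(peaks) == nrow(out))
    out$chrom <- peaks$chrom; out$start <- peaks$start; out$end <- peaks$end
  }
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Top peaks ranked by fold change
#'
#' Selects the `n` peaks with the largest signed log fold change in the
#' requested direction (e.g. the top 4,000 gained peaks of a condition
#' without its own control), breaking ties deterministically by
#' (chrom, start) when coordinates are present, otherwise by peak name.
#'
#' @param table differential-accessibility table from
#'   [moderated_differential_accessibility()].
#' @param n number of peaks to keep (default 4000).
#' @param direction `"up"` (most positive logFC first) or `"down"`.
#' @return The selected rows of `table`, in rank order.
#' @export
top_by_foldchange <- function(table, n = 4000, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (n > nrow(table)) stopf("n exceeds table size (%d)", nrow(table))
  key <- if (direction == "up") -table$logFC else table$logFC
  ord <- if (all(c("chrom", "start") %in% names(table)))
    order(key, table$chrom, table$start) else order(key, table$peak)
  out <- table[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
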