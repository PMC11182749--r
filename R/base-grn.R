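## Candidate TF -> target network from open chromatin: peak-to-gene
## assignment by nearest TSS, log-odds PWM scanning of peak sequences
## on both strands, and assembly of the binary base GRN.

#' Assign peaks to genes by nearest transcription start site
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak
#' centre, unassigned (`NA`) beyond `max_distance`. Exact distance ties
#' resolve to the lexicographically first gene name, making the
#' assignment deterministic.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param tss data.frame with `gene`, `chrom`, `tss`; positions must be
#'   unique per chromosome.
#' @param max_distance maximal centre-to-TSS distance in bp (default
#'   100 kb).
#' @return data.frame with `peak`, `gene` (NA if unassigned) and
#'   `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, tss, max_distance = 1e5) {
  if (nrow(tss) == 0) stopf("TSS table is empty")
  centre <- floor((peaks$start + peaks$end) / 2)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sub <- tss[tss$chrom == ch, , drop = FALSE]
    idx <- which(peaks$chrom == ch)
    if (nrow(sub) == 0 || length(idx) == 0) next
    if (anyDuplicated(sub$tss))
      stopf("duplicate TSS position on %s: nearest-gene assignment ambiguous",
            ch)
    for (i in idx) {
      dd <- abs(centre[i] - sub$tss)
      dmin <- min(dd)
      if (dmin <= max_distance) {
        cand <- sort(sub$gene[dd == dmin])
        gene[i] <- cand[1]
        dist[i] <- dmin
      }
    }
  }
  data.frame(peak = peaks$name %||% sprintf("peak_%04d", seq_len(nrow(peaks))),
             gene = gene, distance = dist, stringsAsFactors = FALSE)
}

## log2-odds matrix of a count PWM against a uniform background
pwm_logodds <- function(pwm, pseudocount = 0.01, background = rep(0.25, 4)) {
  counts <- pwm$counts + pseudocount
  probs <- sweep(counts, 2L, colSums(counts), `/`)
  log2(probs / background)
}

#' Scan sequences for PWM motif hits on both strands
#'
#' Scores every window of each sequence with the log2-odds of the PWM
#' against a uniform background, on both strands (the reverse strand is
#' scanned by reverse-complementing the PWM, so reported positions are
#' forward-strand starts). A window is a hit when its score reaches
#' `score_fraction` of the motif's maximal attainable score. Windows
#' containing `N` are skipped.
#'
#' @param sequences named character vector of uppercase DNA sequences
#'   (ACGT, N allowed).
#' @param pwms list of count PWMs (see [read_jaspar()]).
#' @param score_fraction hit threshold as a fraction of the motif
#'   maximum score (default 0.8).
#' @param pseudocount added to every PWM cell before normalisation.
#' @return data.frame with `seqname`, `motif`, `start` (1-based within
#'   the sequence), `strand` and `score`. A PWM longer than a sequence
#'   yields no hits for it.
#' @export
scan_motifs <- function(sequences, pwms, score_fraction = 0.8,
                        pseudocount = 0.01) {
  bases <- c("A", "C", "G", "T")
  hits <- list()
  lods <- lapply(pwms, pwm_logodds, pseudocount = pseudocount)
  for (sq in seq_along(sequences)) {
    seqname <- names(sequences)[sq] %||% as.character(sq)
    codes <- match(strsplit(sequences[[sq]], "")[[1]], bases)
    L <- length(codes)
    for (mi in seq_along(pwms)) {
      lod <- lods[[mi]]
      w <- ncol(lod)
      if (w > L) next
      maxscore <- sum(apply(lod, 2L, max))
      threshold <- score_fraction * maxscore
      ## reverse strand = reverse-complemented PWM on the forward codes
      lod_rc <- lod[4:1, w:1, drop = FALSE]
      nw <- L - w + 1L
      fwd <- numeric(nw); rev_ <- numeric(nw)
      for (k in seq_len(w)) {
        idx <- codes[k:(k + nw - 1L)]
        fwd <- fwd + lod[, k][idx]
        rev_ <- rev_ + lod_rc[, k][idx]
      }
      for (strand in c("+", "-")) {
        sc <- if (strand == "+") fwd else rev_
        at <- which(!is.na(sc) & sc >= threshold)
        if (length(at))
          hits[[length(hits) + 1L]] <-
            data.frame(seqname = seqname, motif = pwms[[mi]]$id,
                       start = at, strand = strand, score = sc[at],
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(seqname = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Build the candidate base GRN from peak assignments and motif hits
#'
#' A (TF, gene) candidate pair is included exactly when some peak
#' assigned to the gene carries a motif hit for a motif mapped to that
#' TF. Motif-to-TF mapping may be many-to-many. Expression-based
#' filtering of TFs is deferred to the network fitting stage.
#'
#' @param peak2gene data.frame (`peak`, `gene`) from
#'   [assign_peaks_to_genes()]; unassigned peaks (NA gene) are ignored.
#' @param motif_hits data.frame from [scan_motifs()] with peak names in
#'   `seqname`.
#' @param tf2motif data.frame (`tf`, `motif`); every motif appearing in
#'   `motif_hits` must map to at least one TF.
#' @return Object of class `base_grn`: list with `pairs` (data.frame
#'   `tf`, `gene`), `provenance` (per supporting hit: tf, gene, peak,
#'   motif, start, strand, score), `tfs` and `genes`.
#' @export
build_base_grn <- function(peak2gene, motif_hits, tf2motif) {
  unmapped <- setdiff(unique(motif_hits$motif), tf2motif$motif)
  if (length(unmapped))
    stopf("motif(s) without TF mapping: %s",
          paste(utils::head(unmapped, 3), collapse = ", "))
  p2g <- peak2gene[!is.na(peak2gene$gene), c("peak", "gene")]
  prov <- merge(motif_hits, tf2motif, by = "motif")
  prov <- merge(prov, p2g, by.x = "seqname", by.y = "peak")
  if (nrow(prov)) {
    prov <- data.frame(tf = prov$tf, gene = prov$gene, peak = prov$seqname,
                       motif = prov$motif, start = prov$start,
                       strand = prov$strand, score = prov$score,
                       stringsAsFactors = FALSE)
    prov <- prov[order(prov$tf, prov$gene, prov$peak, prov$start), ]
    rownames(prov) <- NULL
    pairs <- unique(prov[c("tf", "gene")])
    pairs <- pairs[order(pairs$tf, pairs$gene), ]
    rownames(pairs) <- NULL
  } else {
    prov <- data.frame(tf = character(0), gene = character(0),
                       peak = character(0), motif = character(0),
                       start = integer(0), strand = character(0),
                       score = numeric(0))
    pairs <- prov[c("tf", "gene")]
  }
  structure(list(pairs = pairs, provenance = prov,
                 tfs = unique(pairs$tf),
                 genes = unique(p2g$gene)),
            class = "base_grn")
}

#' @export
print.base_grn <- function(x, ...) {
  cat(sprintf("base_grn: %d candidate pairs, %d TFs, %d genes\n",
              nrow(x$pairs), length(x$tfs), length(x$genes)))
  invisible(x)
}

## candidate TFs per gene as a named list
base_grn_candidates <- function(base) {
  split(base$pairs$tf, base$pairs$gene)
}
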