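## Shared fixtures, built once per test run. Small sizes keep each file
## fast; the acceptance tests use the full default configuration.

small_config <- trajectory_config(n_cells = 300, n_tfs = 8, n_targets = 40,
                                  edge_density = 0.15, seed = 11)
small_sim <- simulate_trajectory_dataset(small_config)
small_gen <- simulate_regulatory_genome(small_sim$truth, seed = 12,
                                        decoy_rate = 0.5)
small_p2g <- assign_peaks_to_genes(small_gen$peaks, small_gen$tss)
small_hits <- scan_motifs(small_gen$peak_sequences, small_gen$pwms)
small_base <- build_base_grn(small_p2g, small_hits, small_gen$tf2motif)

## a dataset with a hand-set normalised layer (bypasses the count layer)
make_norm_dataset <- function(norm, pseudotime = NULL, state = "S1",
                              emb_y = NULL) {
  n <- ncol(norm)
  if (is.null(colnames(norm))) colnames(norm) <- sprintf("c%03d", seq_len(n))
  pt <- pseudotime %||% seq(0, 1, length.out = n)
  cells <- data.frame(cell_id = colnames(norm),
                      state = rep_len(state, n), pseudotime = pt,
                      emb_x = pt,
                      emb_y = emb_y %||% rep(0, n),
                      stringsAsFactors = FALSE)
  cell_dataset(counts = matrix(0L, nrow(norm), n, dimnames = dimnames(norm)),
               cells = cells, norm = norm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## minimal base_grn granting `tfs` as candidates of every gene in `genes`
make_base <- function(tfs, genes) {
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$tf, pairs$gene), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 provenance = cbind(pairs, peak = NA, motif = NA,
                                    start = NA, strand = NA, score = NA),
                 tfs = unique(pairs$tf), genes = unique(pairs$gene)),
            class = "base_grn")
}

## bare network object for topology tests
make_grn <- function(edges, state = "test") {
  structure(list(state = state, edges = edges, genes = NULL,
                 n_cells = NA, params = list()), class = "state_grn")
}

random_edges <- function(n_edges, genes, seed) {
  set.seed(seed)
  e <- data.frame(regulator = sample(genes, n_edges, replace = TRUE),
                  target = sample(genes, n_edges, replace = TRUE),
                  stringsAsFactors = FALSE)
  e <- e[e$regulator != e$target, ]
  e <- e[!duplicated(e[c("regulator", "target")]), ]
  e$coefficient <- round(stats::rnorm(nrow(e)), 3)
  e$stability <- 1
  e$pvalue <- 0
  e
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 20000,
                         width_range = c(50, 500), seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width - 1L,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

## independent interval merge (sort + coalesce), used as the oracle
merge_intervals_oracle <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cs <- sub$start[1]; ce <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= ce + 1L) {   # overlap or adjacency merges
        ce <- max(ce, sub$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
        cs <- sub$start[i]; ce <- sub$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cs, end = ce)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
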