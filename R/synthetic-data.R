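#' Configuration for the synthetic trajectory generator
#'
#' Describes a four-state (by default) single-cell trajectory in which a
#' set of transcription factors (TFs) follows logistic ramps of
#' pseudotime and target genes are linear combinations of TF levels with
#' a planted, signed coefficient matrix. The defaults emulate the scale
#' of an injury-response smooth-muscle dataset: 1,500 cells across the
#' Non-RSP -> LNK -> PrP -> CYC states, 25 TFs and 150 targets.
#'
#' @param n_cells number of cells.
#' @param n_tfs number of transcription factors.
#' @param n_targets number of target genes.
#' @param states ordered state names along the trajectory.
#' @param state_breaks increasing pseudotime quantile boundaries in
#'   (0,1) separating consecutive states; length `length(states) - 1`.
#' @param edge_density fraction of (TF, target) pairs with a nonzero
#'   planted coefficient, in (0, 1].
#' @param coeff_scale scale of planted coefficient magnitudes
#'   (|w| ~ Uniform(0.5, 1.5) * coeff_scale).
#' @param noise_sd standard deviation of Gaussian noise added to TF and
#'   target expression on the latent scale.
#' @param depth_mean mean per-cell library size (counts).
#' @param depth_sdlog log-normal sdlog of per-cell library size.
#' @param target_baseline baseline latent expression added to every
#'   target gene before flooring at zero.
#' @param positive_sign_prob probability that a planted coefficient is
#'   positive.
#' @param embedding_noise_sd standard deviation of the orthogonal
#'   (y) embedding axis; the x axis is pseudotime itself, so the
#'   analytic developmental flow is (1, 0) everywhere.
#' @param overdispersion optional negative-binomial size parameter for
#'   the count layer; `NULL` uses Poisson counts.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(n_cells = 1500, n_tfs = 25, n_targets = 150,
                              states = c("Non-RSP", "LNK", "PrP", "CYC"),
                              state_breaks = c(0.25, 0.5, 0.75),
                              edge_density = 0.1, coeff_scale = 1,
                              noise_sd = 0.3, depth_mean = 10000,
                              depth_sdlog = 0.3, target_baseline = 1,
                              positive_sign_prob = 0.8,
                              embedding_noise_sd = 0.15,
                              overdispersion = NULL, seed = 1L) {
  if (!is_count(n_cells) || !is_count(n_tfs) || !is_count(n_targets))
    stopf("n_cells, n_tfs and n_targets must be positive integers")
  if (length(states) < 2) stopf("need at least two states")
  if (length(state_breaks) != length(states) - 1L)
    stopf("state_breaks must have length(states) - 1 entries")
  if (any(diff(c(0, state_breaks, 1)) <= 0))
    stopf("state_breaks must be strictly increasing within (0, 1)")
  if (edge_density <= 0 || edge_density > 1)
    stopf("edge_density must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (coeff_scale <= 0 || depth_mean <= 0)
    stopf("coeff_scale and depth_mean must be positive")
  structure(list(n_cells = as.integer(n_cells), n_tfs = as.integer(n_tfs),
                 n_targets = as.integer(n_targets), states = states,
                 state_breaks = state_breaks, edge_density = edge_density,
                 coeff_scale = coeff_scale, noise_sd = noise_sd,
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 target_baseline = target_baseline,
                 positive_sign_prob = positive_sign_prob,
                 embedding_noise_sd = embedding_noise_sd,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "trajectory_config")
}

#' Simulate a trajectory-structured single-cell dataset with planted GRN
#'
#' Cells receive pseudotime ~ Uniform(0,1) and a state label from the
#' configured quantile boundaries. Odd-indexed TFs ramp up with
#' pseudotime (planted "stimulators" of trajectory progression),
#' even-indexed TFs ramp down ("repressors" that maintain the root
#' state); each ramp is a logistic with a per-TF random midpoint and
#' amplitude. Target latent expression is `baseline + W %*% tf + noise`
#' floored at zero, where `W` is the planted signed coefficient matrix.
#' A root marker gene (named `Myh11` by analogy with contractile
#' smooth-muscle datasets) is high in the first state. Counts are drawn
#' from a Poisson (optionally negative-binomial) layer with log-normal
#' per-cell depth; the embedding is `(pseudotime, noise)`, so the
#' analytic developmental flow is `(1, 0)` everywhere.
#'
#' The seeded RNG stream is consumed in a documented order so tests can
#' re-enumerate it: (1) planted edge indicators,
#' `runif(n_targets * n_tfs) < edge_density`, filled column-major into
#' the targets x TFs matrix; (2) coefficient magnitudes; (3) signs;
#' (4) TF ramp midpoints then amplitudes; (5) pseudotime; (6) embedding
#' y noise; (7) TF noise; (8) target noise; (9) root-marker noise;
#' (10) depths; (11) counts.
#'
#' @param config a [trajectory_config()].
#' @return list with `dataset` (a [cell_dataset()]) and `truth`, a
#'   `planted_truth` list carrying per-state coefficient matrices
#'   (identical across states), the planted edge table, TF ramp
#'   parameters, `stimulator_tfs`, `repressor_tfs`, `root_marker` and
#'   the noise-free latent matrix (genes x cells, before counts).
#' @export
simulate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  ns <- length(config$states)
  if (config$n_cells < 4L * ns)
    stopf("n_cells must be at least 4 x number of states (%d)", 4L * ns)
  res <- with_seed(config$seed, {
    n <- config$n_cells; ntf <- config$n_tfs; ntg <- config$n_targets
    tf_names <- sprintf("TF%02d", seq_len(ntf))
    tg_names <- sprintf("TG%03d", seq_len(ntg))

    ## (1-3) planted coefficient matrix (targets x TFs)
    mask <- matrix(stats::runif(ntg * ntf) < config$edge_density, ntg, ntf)
    mag <- matrix(stats::runif(ntg * ntf, 0.5, 1.5) * config$coeff_scale,
                  ntg, ntf)
    sgn <- matrix(ifelse(stats::runif(ntg * ntf) < config$positive_sign_prob,
                         1, -1), ntg, ntf)
    W <- mask * mag * sgn
    dimnames(W) <- list(tg_names, tf_names)

    ## (4) TF ramps: odd TFs up (stimulators), even TFs down (repressors)
    up <- seq_len(ntf) %% 2L == 1L
    midpoint <- stats::runif(ntf, 0.25, 0.75)
    amplitude <- stats::runif(ntf, 1.5, 3)
    slope <- 10

    ## (5-6) cells
    t_pseudo <- stats::runif(n)
    emb_y <- stats::rnorm(n, 0, config$embedding_noise_sd)
    state <- cut(t_pseudo, breaks = c(0, config$state_breaks, 1),
                 labels = config$states, include.lowest = TRUE)

    ## (7) TF latent expression
    ramp <- vapply(seq_len(ntf), function(j) {
      z <- stats::plogis(slope * (t_pseudo - midpoint[j]))
      0.2 + amplitude[j] * (if (up[j]) z else 1 - z)
    }, numeric(n))                              # cells x tfs
    tf_lat <- pmax(ramp + matrix(stats::rnorm(n * ntf, 0, config$noise_sd),
                                 n, ntf), 0)
    colnames(tf_lat) <- tf_names

    ## (8) target latent expression
    tg_lat <- config$target_baseline + tf_lat %*% t(W) +
      matrix(stats::rnorm(n * ntg, 0, config$noise_sd), n, ntg)
    tg_lat <- pmax(tg_lat, 0)
    colnames(tg_lat) <- tg_names

    ## (9) root marker: high at low pseudotime
    root <- pmax(3 * stats::plogis(-12 * (t_pseudo - 0.2)) +
                   stats::rnorm(n, 0, config$noise_sd), 0)

    latent <- t(cbind(tf_lat, tg_lat, Myh11 = root))  # genes x cells
    ## keep a positive floor so every cell has sampling mass
    rate <- latent + 0.02

    ## (10-11) counts
    depth <- stats::rlnorm(n, log(config$depth_mean) -
                             config$depth_sdlog^2 / 2, config$depth_sdlog)
    mu <- sweep(rate, 2L, depth / colSums(rate), `*`)
    counts <- if (is.null(config$overdispersion)) {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = config$overdispersion),
             nrow(mu), ncol(mu))
    }
    dimnames(counts) <- list(rownames(rate),
                             sprintf("cell%04d", seq_len(n)))

    cells <- data.frame(cell_id = colnames(counts),
                        state = as.character(state),
                        pseudotime = t_pseudo,
                        emb_x = t_pseudo, emb_y = emb_y,
                        stringsAsFactors = FALSE)
    ds <- cell_dataset(counts, cells)

    edges <- which(W != 0, arr.ind = TRUE)
    edge_tab <- data.frame(tf = tf_names[edges[, 2]],
                           target = tg_names[edges[, 1]],
                           coefficient = W[edges],
                           stringsAsFactors = FALSE)
    coeffs <- stats::setNames(rep(list(W), ns), config$states)
    truth <- structure(list(
      coefficients = coeffs,
      edges = edge_tab,
      tf_profiles = data.frame(tf = tf_names,
                               direction = ifelse(up, "up", "down"),
                               midpoint = midpoint, amplitude = amplitude,
                               stringsAsFactors = FALSE),
      stimulator_tfs = tf_names[up],
      repressor_tfs = tf_names[!up],
      root_marker = "Myh11",
      latent = latent), class = "planted_truth")
    list(dataset = ds, truth = truth)
  })
  res
}

#' Simulate a regulatory genome realising planted TF -> target edges
#'
#' Lays all genes on one synthetic chromosome with evenly spaced
#' transcription start sites, then realises every planted edge as an
#' accessible peak near the target's TSS whose sequence embeds the
#' regulator TF's consensus motif (random strand). Decoy peaks embed a
#' random TF's consensus near a gene that TF does not regulate, at
#' `decoy_rate` times the planted edge count. Consensus motifs are
#' distinct random 12-mers with sharply peaked count matrices
#' (97/1/1/1), so the default motif-scan threshold admits only exact
#' consensus matches and the base GRN recovered downstream equals the
#' planted incidence when `decoy_rate = 0`.
#'
#' Coordinates are 1-based inclusive in memory; [write_bed()] converts
#' to BED's 0-based half-open convention.
#'
#' @param truth `planted_truth` from [simulate_trajectory_dataset()].
#' @param seed integer seed.
#' @param peak_width nominal peak width in bp.
#' @param gene_spacing distance between consecutive TSS in bp.
#' @param decoy_rate decoy peaks per planted edge.
#' @param motif_length consensus length in bp.
#' @param flank maximal distance of a peak centre from its gene's TSS.
#' @return list with `peaks` (data.frame: chrom, start, end, name,
#'   score, strand plus provenance columns `gene`, `tf`, `is_decoy`),
#'   `tss` (gene, chrom, tss, strand), `gene_models` (gene, chrom,
#'   start, end), `pwms` (JASPAR-style count PWMs, one per TF),
#'   `tf2motif` (tf, motif), `genome` (named character, one
#'   chromosome) and `peak_sequences` (named character, one per peak).
#' @export
simulate_regulatory_genome <- function(truth, seed = 1L, peak_width = 500,
                                       gene_spacing = 10000,
                                       decoy_rate = 0.5, motif_length = 12,
                                       flank = 2000) {
  stopifnot(inherits(truth, "planted_truth"))
  if (nrow(truth$edges) < 1) stopf("truth must contain at least one planted edge")
  genes <- rownames(truth$latent)
  tfs <- sort(unique(truth$edges$tf))
  tfs <- union(truth$tf_profiles$tf, tfs)
  with_seed(seed, {
    n_genes <- length(genes)
    tss_pos <- 5000 + (seq_len(n_genes) - 1L) * gene_spacing
    if (anyDuplicated(tss_pos)) stopf("duplicate TSS positions")
    tss <- data.frame(gene = genes, chrom = "chrS", tss = tss_pos,
                      strand = "+", stringsAsFactors = FALSE)
    gene_models <- data.frame(gene = genes, chrom = "chrS",
                              start = tss_pos, end = tss_pos + 1500L,
                              stringsAsFactors = FALSE)
    chrom_len <- max(tss_pos) + gene_spacing

    ## distinct consensus motifs
    bases <- c("A", "C", "G", "T")
    repeat {
      consensus <- vapply(seq_along(tfs), function(i)
        paste(sample(bases, motif_length, replace = TRUE), collapse = ""),
        character(1))
      if (!anyDuplicated(consensus)) break
    }
    names(consensus) <- tfs
    pwms <- lapply(tfs, function(tf) {
      cs <- strsplit(consensus[[tf]], "")[[1]]
      counts <- matrix(1, 4, motif_length, dimnames = list(bases, NULL))
      counts[cbind(match(cs, bases), seq_len(motif_length))] <- 97
      list(id = paste0("M_", tf), name = tf, counts = counts)
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "id")
    tf2motif <- data.frame(tf = tfs, motif = paste0("M_", tfs),
                           stringsAsFactors = FALSE)

    genome <- sample(bases, chrom_len, replace = TRUE)

    ## realisations per gene: planted edges plus decoys
    realis <- truth$edges[c("tf", "target")]
    names(realis) <- c("tf", "gene")
    realis$is_decoy <- FALSE
    n_dec <- round(decoy_rate * nrow(truth$edges))
    if (n_dec > 0) {
      planted_key <- paste(realis$tf, realis$gene)
      dec <- data.frame(tf = character(0), gene = character(0))
      guard <- 0L
      while (nrow(dec) < n_dec && guard < 50L) {
        cand <- data.frame(tf = sample(tfs, n_dec, replace = TRUE),
                           gene = sample(genes, n_dec, replace = TRUE),
                           stringsAsFactors = FALSE)
        dec <- unique(rbind(dec, cand))
        dec <- dec[!(paste(dec$tf, dec$gene) %in% planted_key), , drop = FALSE]
        guard <- guard + 1L
      }
      dec <- utils::head(dec, n_dec)
      if (nrow(dec)) {
        dec$is_decoy <- TRUE
        realis <- rbind(realis, dec)
      }
    }

    ## place peaks gene by gene in non-overlapping slots around the TSS
    peak_rows <- vector("list", nrow(realis))
    seqs <- character(nrow(realis))
    k <- 0L
    for (g in unique(realis$gene)) {
      rows <- which(realis$gene == g)
      m <- length(rows)
      spacing <- if (m == 1) peak_width + 100 else
        min(peak_width + 100, floor(2 * flank / (m - 1)))
      width <- max(motif_length + 20, min(peak_width, spacing - 20))
      centre0 <- tss$tss[tss$gene == g]
      offsets <- (seq_len(m) - (m + 1) / 2) * spacing
      for (j in seq_len(m)) {
        k <- k + 1L
        centre <- round(centre0 + offsets[j])
        start <- max(1L, centre - width %/% 2)
        end <- min(chrom_len, start + width - 1L)
        tf <- realis$tf[rows[j]]
        cs <- strsplit(consensus[[tf]], "")[[1]]
        if (stats::runif(1) < 0.5)
          cs <- rev(c(A = "T", C = "G", G = "C", T = "A")[cs])
        pos <- start + sample.int(end - start + 1L - motif_length, 1L) - 1L
        genome[pos:(pos + motif_length - 1L)] <- cs
        peak_rows[[k]] <- data.frame(chrom = "chrS", start = start, end = end,
                                     name = "", score = 0, strand = ".",
                                     gene = g, tf = tf,
                                     is_decoy = realis$is_decoy[rows[j]],
                                     stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), ]
    peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    genome_str <- paste(genome, collapse = "")
    peak_seq <- substring(genome_str, peaks$start, peaks$end)
    names(peak_seq) <- peaks$name
    list(peaks = peaks, tss = tss, gene_models = gene_models, pwms = pwms,
         tf2motif = tf2motif, genome = c(chrS = genome_str),
         peak_sequences = peak_seq)
  })
}

#' Extract peak sequences from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @return Named character vector of peak sequences.
#' @export
peak_sequences <- function(genome, peaks) {
  out <- vapply(seq_len(nrow(peaks)), function(i)
    substring(genome[[peaks$chrom[i]]], peaks$start[i], peaks$end[i]),
    character(1))
  names(out) <- peaks$name %||% sprintf("peak_%04d", seq_len(nrow(peaks)))
  out
}

#' Simulate an ATAC read-density matrix with planted accessibility changes
#'
#' Per-peak log2 densities are Normal(peak mean, `noise_sd`); a fraction
#' of peaks carries an additional `log2(planted_fc)` offset (random
#' sign) in the second group. Intended for calibration and power checks
#' of the moderated differential-accessibility test.
#'
#' @param n_peaks number of peaks.
#' @param planted_fc linear fold change planted in differential peaks
#'   (1 = null simulation).
#' @param frac_da fraction of peaks that are differential.
#' @param replicates replicates per group (>= 2).
#' @param noise_sd standard deviation of log2 densities.
#' @param mean_log2 mean of the per-peak baseline log2 density.
#' @param groups two group names.
#' @param seed integer seed.
#' @return list with `density` (peaks x samples matrix of linear read
#'   densities), `groups` (factor per sample) and `labels` (data.frame:
#'   peak, is_da, direction, true_log2fc).
#' @export
simulate_atac_counts <- function(n_peaks = 10000, planted_fc = 4,
                                 frac_da = 0.05, replicates = 2,
                                 noise_sd = 0.25, mean_log2 = 8,
                                 groups = c("control", "treated"),
                                 seed = 1L) {
  if (replicates < 2) stopf("need at least 2 replicates per group")
  stopifnot(length(groups) == 2)
  with_seed(seed, {
    peak_mean <- stats::rnorm(n_peaks, mean_log2, 1.5)
    n_da <- round(frac_da * n_peaks)
    is_da <- rep(FALSE, n_peaks)
    direction <- rep(0L, n_peaks)
    if (planted_fc != 1 && n_da > 0) {
      idx <- sample.int(n_peaks, n_da)
      is_da[idx] <- TRUE
      direction[idx] <- ifelse(stats::runif(n_da) < 0.5, 1L, -1L)
    }
    offset <- direction * log2(planted_fc)
    grp <- factor(rep(groups, each = replicates), levels = groups)
    logd <- vapply(seq_along(grp), function(s) {
      mu <- peak_mean + if (grp[s] == groups[2]) offset else 0
      stats::rnorm(n_peaks, mu, noise_sd)
    }, numeric(n_peaks))
    density <- 2^logd
    dimnames(density) <- list(sprintf("peak_%05d", seq_len(n_peaks)),
                              paste(grp, rep(seq_len(replicates), 2), sep = "_"))
    list(density = density, groups = grp,
         labels = data.frame(peak = rownames(density), is_da = is_da,
                             direction = direction, true_log2fc = offset,
                             stringsAsFactors = FALSE))
  })
}
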