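## Ground-truth evaluation utilities: run the full synthetic pipeline at
## the default study conditions and measure how well each stage recovers
## what was planted. Used by the acceptance checks and reproducible from
## a single seed.

#' Run the default synthetic pipeline (simulate -> base GRN -> fits)
#'
#' Generates the default trajectory dataset (1,500 cells, 25 TFs, 150
#' targets, edge density 0.1, noise 0.3), realises its regulatory
#' genome, reconstructs the base GRN by motif scanning, and fits both a
#' trajectory-wide network and the four per-state networks.
#'
#' @param seed integer seed (dataset seed; the genome uses seed +
#'   10000).
#' @param states fit per-state networks (default TRUE).
#' @param config optional [trajectory_config()] overriding the default
#'   (its own seed wins).
#' @return list with `sim`, `gen`, `base`, `fit` (all-cell network) and
#'   `grns` (per state, when requested).
#' @export
default_synthetic_pipeline <- function(seed = 1L, states = TRUE,
                                       config = NULL) {
  cfg <- config %||% trajectory_config(seed = seed)
  sim <- simulate_trajectory_dataset(cfg)
  gen <- simulate_regulatory_genome(sim$truth, seed = cfg$seed + 10000L)
  p2g <- assign_peaks_to_genes(gen$peaks, gen$tss)
  hits <- scan_motifs(gen$peak_sequences, gen$pwms)
  base <- build_base_grn(p2g, hits, gen$tf2motif)
  fit <- fit_state_grn(sim$dataset, base, state = NULL, seed = cfg$seed)
  grns <- NULL
  if (states) {
    stn <- unique(sim$dataset$cells$state)
    grns <- lapply(stats::setNames(stn, stn), function(st)
      fit_state_grn(sim$dataset, base, state = st, seed = cfg$seed))
  }
  list(sim = sim, gen = gen, base = base, fit = fit, grns = grns)
}

#' Planted-edge recovery metrics for a fitted network
#'
#' AUPRC of the per-candidate |z| ranking against the planted edge
#' labels (candidates never fitted score 0), and the coefficient sign
#' agreement over recovered planted edges.
#'
#' @param fit a `state_grn`.
#' @param base the `base_grn` defining the candidate universe.
#' @param truth the `planted_truth` of the dataset.
#' @return list with `auprc`, `sign_agreement`, `n_candidates`,
#'   `n_recovered`, `n_recovered_planted`.
#' @export
edge_recovery_metrics <- function(fit, base, truth) {
  keys_cand <- paste(base$pairs$tf, base$pairs$gene)
  keys_truth <- paste(truth$edges$tf, truth$edges$target)
  score <- stats::setNames(rep(0, length(keys_cand)), keys_cand)
  kc <- paste(fit$candidates$regulator, fit$candidates$target)
  score[kc[kc %in% keys_cand]] <-
    abs(fit$candidates$zstat[kc %in% keys_cand])
  label <- keys_cand %in% keys_truth
  kf <- paste(fit$edges$regulator, fit$edges$target)
  common <- intersect(kf, keys_truth)
  agree <- sign(fit$edges$coefficient[match(common, kf)]) ==
    sign(truth$edges$coefficient[match(common, keys_truth)])
  list(auprc = auprc(score, label),
       sign_agreement = mean(agree),
       n_candidates = length(keys_cand),
       n_recovered = nrow(fit$edges),
       n_recovered_planted = length(common))
}

#' Edge count under a label-shuffled null
#'
#' Permutes the cell labels of all non-TF rows of the normalised layer
#' (decoupling every candidate TF -> target pair) and refits the
#' network with identical settings; reports the surviving edge count as
#' a percentage of the planted-data edge count.
#'
#' @param dataset a [cell_dataset()].
#' @param base the `base_grn`.
#' @param fit the planted-data fit to compare against.
#' @param seed permutation seed.
#' @return list with `n_null`, `n_data` and `pct`.
#' @export
shuffled_null_edge_fraction <- function(dataset, base, fit, seed = 1L) {
  ds <- dataset
  rows <- setdiff(ds$genes, base$tfs)
  ds$norm[rows, ] <- with_seed(seed,
    ds$norm[rows, sample(ncol(ds$norm)), drop = FALSE])
  fit0 <- fit_state_grn(ds, base, state = NULL,
                        seed = fit$params$seed,
                        n_bags = fit$params$n_bags,
                        bag_fraction = fit$params$bag_fraction,
                        stability_min = fit$params$stability_min,
                        coef_p_max = fit$params$coef_p_max)
  n_null <- sum(fit0$edges$target %in% rows)
  n_data <- sum(fit$edges$target %in% rows)
  list(n_null = n_null, n_data = n_data, pct = 100 * n_null / n_data)
}

#' Mean angular error of the developmental flow on synthetic data
#'
#' On the synthetic embedding the analytic flow is (1, 0) everywhere;
#' reports the mean absolute angle (degrees) between the estimated flow
#' and that direction over valid grid points.
#'
#' @param dataset a synthetic [cell_dataset()].
#' @param ... passed to [developmental_flow()].
#' @return list with `mean_error_deg`, `n_valid` and
#'   `mass_fraction_retained`.
#' @export
flow_angular_error <- function(dataset, ...) {
  fl <- developmental_flow(dataset, ...)
  ang <- atan2(fl$vy[fl$mask], fl$vx[fl$mask]) * 180 / pi
  list(mean_error_deg = mean(abs(ang)), n_valid = sum(fl$mask),
       mass_fraction_retained = sum(fl$mass[fl$mask]) / sum(fl$mass))
}

#' Planted-regulator recovery of a perturbation screen
#'
#' Measures the KO/OE net-score mirror (R^2 of the across-TF
#' regression), the fraction of planted stimulators classified
#' "stimulator" and repressors "blocker" at the knockout-score
#' thresholds, and the threshold-free separation (AUC of the negative
#' KO score ranking stimulators above repressors).
#'
#' @param screen a [perturbation_analysis()] result.
#' @param truth the `planted_truth`.
#' @return list with `ko_oe_r2` (NA without OE rows),
#'   `stimulator_recovery`, `blocker_recovery`, `separation_auc`,
#'   `n_tfs`.
#' @export
screen_metrics <- function(screen, truth) {
  sc <- screen$scores
  ko <- sc[sc$mode == "KO", ]
  oe <- sc[sc$mode == "OE", ]
  r2 <- if (nrow(oe)) {
    net_ko <- ko$sum_pos + ko$sum_neg
    net_oe <- (oe$sum_pos + oe$sum_neg)[match(ko$tf, oe$tf)]
    summary(stats::lm(net_ko ~ net_oe))$r.squared
  } else NA_real_
  cls <- screen$classification
  stim <- intersect(truth$stimulator_tfs, cls$tf)
  repr <- intersect(truth$repressor_tfs, cls$tf)
  neg <- stats::setNames(cls$ko_sum_neg, cls$tf)
  ## stimulators should rank below (more negative than) repressors
  sep <- NA_real_
  if (length(stim) && length(repr)) {
    r <- rank(neg[c(stim, repr)])
    u <- sum(r[seq_along(stim)]) - length(stim) * (length(stim) + 1) / 2
    sep <- 1 - u / (length(stim) * length(repr))
  }
  list(ko_oe_r2 = r2,
       stimulator_recovery = mean(cls$class[cls$tf %in% stim] ==
                                    "stimulator"),
       blocker_recovery = mean(cls$class[cls$tf %in% repr] == "blocker"),
       separation_auc = sep,
       n_tfs = nrow(ko))
}
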