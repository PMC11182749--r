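## State-specific weighted GRN fitting: for every target gene, a bagged
## ridge regression of its log-normalised expression on the expression
## of its base-GRN candidate TFs, restricted to the cells of one state.

#' Select genes for network modelling
#'
#' Highly variable genes by variance-to-mean dispersion on the
#' normalised layer, supplemented with explicitly requested genes
#' (e.g. TFs with pseudotime-dependent expression).
#'
#' @param dataset a [cell_dataset()].
#' @param n_hvg number of highly variable genes (capped at the gene
#'   count).
#' @param extra_genes genes to add regardless of dispersion rank;
#'   unknown names are dropped with a warning.
#' @return Character vector: HVGs in decreasing dispersion order
#'   (ties by gene name), followed by the extra genes not already
#'   selected, sorted.
#' @export
select_genes <- function(dataset, n_hvg = 4000, extra_genes = character()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  n_hvg <- min(n_hvg, length(dataset$genes))
  m <- rowMeans(dataset$norm)
  v <- apply(dataset$norm, 1L, stats::var)
  disp <- ifelse(m > 0, v / m, 0)
  ord <- order(-disp, dataset$genes)
  hvg <- dataset$genes[utils::head(ord, n_hvg)]
  extra <- unique(as.character(extra_genes))
  unknown <- setdiff(extra, dataset$genes)
  if (length(unknown)) {
    warnf("dropping %d unknown extra gene(s)", length(unknown))
    extra <- setdiff(extra, unknown)
  }
  c(hvg, sort(setdiff(extra, hvg)))
}

## closed-form ridge on centred data; returns coefficients
ridge_coef <- function(X, y, lambda) {
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + lambda
  drop(solve(XtX, crossprod(X, y)))
}

## generalized cross-validation over a lambda grid (SVD path)
ridge_gcv <- function(X, y, grid = 10^seq(-2, 3, length.out = 13)) {
  n <- nrow(X)
  sv <- svd(X, nu = min(n, ncol(X)))
  uy <- crossprod(sv$u, y)
  d2 <- sv$d^2
  yy <- sum(y^2)
  gcv <- vapply(grid, function(l) {
    shrink <- d2 / (d2 + l)
    rss <- yy - sum((2 * shrink - shrink^2) * uy^2)
    edf <- sum(shrink)
    n * rss / (n - edf)^2
  }, numeric(1))
  grid[which.min(gcv)]
}

#' Fit a state-specific gene regulatory network
#'
#' For each target gene in the modelling universe, fits a ridge
#' regression of its normalised expression on the expression of its
#' base-GRN candidate TFs over the cells of one state, repeated over
#' `n_bags` bootstrap bags. The edge coefficient ("connectivity
#' score") is the mean bag coefficient; its stability is the fraction
#' of bags whose coefficient sign matches that mean sign. Edges are
#' kept when stability is at least `stability_min` (default 0.9) and
#' the full-data coefficient is significant by a ridge sandwich z-test
#' (p <= `coef_p_max`), the package's stand-in for an external tool's
#' bagging p-value. Candidate TFs that are constant within the state,
#' and self-loops, are excluded.
#'
#' @param dataset a [cell_dataset()].
#' @param base a [build_base_grn()] object restricting candidate
#'   regulators per target.
#' @param state state label selecting cells, or `NULL` to use all
#'   cells.
#' @param genes optional modelling universe; defaults to the dataset
#'   genes that are base-GRN genes or candidate TFs (see
#'   [select_genes()] for variable-gene preselection).
#' @param n_bags number of bootstrap bags.
#' @param bag_fraction bag size as a fraction of the state's cells
#'   (sampled with replacement).
#' @param ridge_penalty fixed ridge penalty; `NULL` selects one per
#'   target by generalized cross-validation on a subsample of at most
#'   500 cells.
#' @param stability_min minimal sign-consistency across bags.
#' @param coef_p_max maximal coefficient p-value (ridge sandwich
#'   z-test).
#' @param detrend_df degrees of freedom of a natural-spline pseudotime
#'   trend that is projected out of both the TF expressions and the
#'   target before the regression (Frisch-Waugh residualisation).
#'   Genes co-varying along a trajectory are collinear through
#'   pseudotime, so without this adjustment a regulator's apparent
#'   effect leaks onto any TF with a similar temporal profile;
#'   adjusting for the shared trend identifies edges from cell-level
#'   covariation instead. Set 0 to disable (plain centring).
#' @param seed integer seed controlling the bootstrap bags.
#' @return Object of class `state_grn`: list with `state`, `edges`
#'   (data.frame `regulator`, `target`, `coefficient`, `stability`,
#'   `pvalue`, `zstat`), `candidates` (the same statistics for every
#'   candidate pair before filtering), `genes` (modelling universe),
#'   `tf_means` and `target_means` plus the fitted trend (used by
#'   [predict.state_grn()]), `n_cells` and `params`.
#' @examples
#' sim <- simulate_trajectory_dataset(trajectory_config(n_cells = 120,
#'   n_tfs = 4, n_targets = 12, seed = 2))
#' gen <- simulate_regulatory_genome(sim$truth, seed = 3, decoy_rate = 0)
#' p2g <- assign_peaks_to_genes(gen$peaks, gen$tss)
#' hits <- scan_motifs(gen$peak_sequences, gen$pwms)
#' base <- build_base_grn(p2g, hits, gen$tf2motif)
#' fit <- fit_state_grn(sim$dataset, base, state = NULL, seed = 1)
#' fit
#' @export
fit_state_grn <- function(dataset, base, state = NULL, genes = NULL,
                          n_bags = 20, bag_fraction = 0.8,
                          ridge_penalty = NULL, stability_min = 0.9,
                          coef_p_max = 1e-3, detrend_df = 8, seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"), inherits(base, "base_grn"))
  if (!is.null(state)) {
    if (!state %in% dataset$cells$state)
      stopf("state '%s' absent from cell labels", state)
    cells <- which(dataset$cells$state == state)
  } else cells <- seq_len(ncol(dataset$counts))
  if (length(cells) < 20)
    stopf("need at least 20 cells in state '%s' (have %d)",
          state %||% "all", length(cells))

  universe <- genes %||% intersect(dataset$genes,
                                   union(base$genes, base$tfs))
  cand <- base_grn_candidates(base)
  tfs_all <- intersect(base$tfs, dataset$genes)
  X_all <- t(dataset$norm[tfs_all, cells, drop = FALSE])  # cells x tfs
  tf_sd <- apply(X_all, 2L, stats::sd)
  usable_tfs <- tfs_all[tf_sd > 0]

  n <- length(cells)
  ## pseudotime-trend projection (Frisch-Waugh): residualise TFs and
  ## targets on [1, ns(pseudotime)] before the ridge fits
  pt <- dataset$cells$pseudotime[cells]
  detrend_df <- min(detrend_df, max(0L, floor(n / 20) - 1L))
  if (detrend_df > 0 && stats::sd(pt) > 0) {
    ns_basis <- splines::ns(pt, df = detrend_df)
    M <- cbind(1, ns_basis)
  } else {
    ns_basis <- NULL
    M <- matrix(1, n, 1L)
  }
  qrM <- qr(M)
  gamma_x <- qr.coef(qrM, X_all)
  gamma_x[is.na(gamma_x)] <- 0
  Xr_all <- X_all - M %*% gamma_x
  nb <- max(2L, round(bag_fraction * n))
  bags <- with_seed(seed,
    matrix(sample.int(n, nb * n_bags, replace = TRUE), nb, n_bags))

  targets <- intersect(universe, names(cand))
  cand_rows <- vector("list", length(targets))
  tgt_means <- numeric(0)
  gamma_y <- list()
  p_trend <- ncol(M)
  for (ti in seq_along(targets)) {
    g <- targets[[ti]]
    tfset <- intersect(setdiff(unique(cand[[g]]), g), usable_tfs)
    if (length(tfset) == 0) next
    X0 <- Xr_all[, tfset, drop = FALSE]
    y <- dataset$norm[g, cells]
    gy <- qr.coef(qrM, y); gy[is.na(gy)] <- 0
    y0 <- y - drop(M %*% gy)
    lambda <- ridge_penalty %||% {
      sub <- if (n > 500) seq(1L, n, length.out = 500) else seq_len(n)
      ridge_gcv(X0[sub, , drop = FALSE], y0[sub])
    }
    ## full-data fit and sandwich variance for the significance test
    XtX <- crossprod(X0)
    A <- solve(XtX + diag(lambda, ncol(X0)))
    beta_full <- drop(A %*% crossprod(X0, y0))
    H_tr <- sum(rowSums((X0 %*% A) * X0))
    rss <- sum((y0 - X0 %*% beta_full)^2)
    sigma2 <- rss / max(1, n - H_tr - p_trend)
    se <- sqrt(pmax(diag(A %*% XtX %*% A) * sigma2, .Machine$double.eps))
    zstat <- beta_full / se
    pval <- 2 * stats::pnorm(-abs(zstat))
    ## bagging on the residualised data
    bmat <- vapply(seq_len(n_bags), function(b) {
      idx <- bags[, b]
      Xb0 <- X0[idx, , drop = FALSE]
      Xb0 <- sweep(Xb0, 2L, colMeans(Xb0))
      yb0 <- y0[idx]; yb0 <- yb0 - mean(yb0)
      sdb <- apply(Xb0, 2L, stats::sd)
      out <- numeric(ncol(Xb0))
      ok <- sdb > 0
      if (any(ok))
        out[ok] <- ridge_coef(Xb0[, ok, drop = FALSE], yb0, lambda)
      out
    }, numeric(length(tfset)))
    bmat <- matrix(bmat, nrow = length(tfset))
    coefs <- rowMeans(bmat)
    stability <- vapply(seq_along(tfset), function(j) {
      if (coefs[j] == 0) return(0)
      mean(sign(bmat[j, ]) == sign(coefs[j]))
    }, numeric(1))
    cand_rows[[ti]] <- data.frame(regulator = tfset, target = g,
                                  coefficient = coefs,
                                  stability = stability,
                                  pvalue = pval, zstat = zstat,
                                  stringsAsFactors = FALSE)
    tgt_means[g] <- mean(y)
    gamma_y[[g]] <- gy
  }
  candidates <- do.call(rbind, cand_rows)
  if (is.null(candidates))
    candidates <- data.frame(regulator = character(0), target = character(0),
                             coefficient = numeric(0), stability = numeric(0),
                             pvalue = numeric(0), zstat = numeric(0))
  keep <- candidates$coefficient != 0 &
    candidates$stability >= stability_min &
    candidates$pvalue <= coef_p_max
  edges <- candidates[keep, , drop = FALSE]
  edges <- edges[order(-abs(edges$coefficient), edges$regulator,
                       edges$target), ]
  rownames(edges) <- NULL
  rownames(candidates) <- NULL
  structure(list(state = state %||% "all", edges = edges,
                 candidates = candidates, genes = universe,
                 tf_means = colMeans(X_all), target_means = tgt_means,
                 trend = list(basis = ns_basis, gamma_x = gamma_x,
                              gamma_y = gamma_y),
                 n_cells = n,
                 params = list(n_bags = n_bags, bag_fraction = bag_fraction,
                               ridge_penalty = ridge_penalty,
                               stability_min = stability_min,
                               coef_p_max = coef_p_max,
                               detrend_df = detrend_df, seed = seed)),
            class = "state_grn")
}

#' Keep the strongest k edges of a network
#'
#' Retains the `k` edges with largest absolute coefficient (the
#' top-2,000 convention for topology, top-10,000 for simulation), with
#' deterministic ties by (|coefficient| desc, regulator, target). With
#' fewer than `k` edges the network is returned unchanged.
#'
#' @param grn a `state_grn`.
#' @param k number of edges to keep (>= 1).
#' @return The pruned `state_grn`.
#' @export
prune_top_k <- function(grn, k) {
  stopifnot(inherits(grn, "state_grn"), is_count(k))
  e <- grn$edges
  ord <- order(-abs(e$coefficient), e$regulator, e$target)
  grn$edges <- e[utils::head(ord, k), , drop = FALSE]
  rownames(grn$edges) <- NULL
  grn$params$pruned_k <- k
  grn
}

#' Signed weighted adjacency matrix of a state GRN
#'
#' @param grn a `state_grn`.
#' @param genes gene universe for rows/columns; defaults to the genes
#'   incident to kept edges.
#' @return Square matrix, regulator rows x target columns.
#' @export
grn_adjacency <- function(grn, genes = NULL) {
  e <- grn$edges
  genes <- genes %||% sort(unique(c(e$regulator, e$target)))
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  keep <- e$regulator %in% genes & e$target %in% genes
  e <- e[keep, , drop = FALSE]
  W[cbind(e$regulator, e$target)] <- e$coefficient
  W
}

#' @export
print.state_grn <- function(x, ...) {
  cat(sprintf("state_grn ('%s'): %d edges, %d regulators, %d targets, %d cells\n",
              x$state, nrow(x$edges), length(unique(x$edges$regulator)),
              length(unique(x$edges$target)), x$n_cells))
  if (nrow(x$edges)) {
    cat("strongest edges:\n")
    print(utils::head(x$edges, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.state_grn <- function(object, ...) {
  e <- object$edges
  out <- list(state = object$state, n_edges = nrow(e),
              n_regulators = length(unique(e$regulator)),
              n_targets = length(unique(e$target)),
              coefficient_quartiles = stats::quantile(e$coefficient,
                                                      na.rm = TRUE),
              positive_fraction = mean(e$coefficient > 0),
              top_regulators = utils::head(
                sort(table(e$regulator), decreasing = TRUE), 10))
  class(out) <- "summary.state_grn"
  out
}

#' @export
print.summary.state_grn <- function(x, ...) {
  cat(sprintf("state '%s': %d edges (%d regulators -> %d targets)\n",
              x$state, x$n_edges, x$n_regulators, x$n_targets))
  cat(sprintf("positive-coefficient fraction: %.2f\n", x$positive_fraction))
  cat("coefficient quartiles:\n"); print(x$coefficient_quartiles)
  cat("highest out-degree regulators:\n"); print(x$top_regulators)
  invisible(x)
}

#' @export
coef.state_grn <- function(object, matrix = FALSE, ...) {
  if (matrix) return(grn_adjacency(object))
  object$edges
}

#' Predict target expression from TF expression
#'
#' Linear prediction `mean(target) + sum coef * (tf - mean(tf))` per
#' target with kept incoming edges, using the fitting-state centres.
#'
#' @param object a `state_grn`.
#' @param dataset a [cell_dataset()] (defaults are the state's cells if
#'   it carries the fitting states).
#' @param cells optional cell selector (see [cell_dataset()] helpers).
#' @param ... unused.
#' @return targets x cells matrix of predicted normalised expression.
#' @export
predict.state_grn <- function(object, dataset, cells = NULL, ...) {
  stopifnot(inherits(dataset, "cell_dataset"))
  idx <- resolve_cells(dataset, cells)
  tgts <- unique(object$edges$target)
  out <- matrix(NA_real_, length(tgts), length(idx),
                dimnames = list(tgts, dataset$cells$cell_id[idx]))
  basis <- object$trend$basis
  Mn <- if (is.null(basis)) matrix(1, length(idx), 1L) else
    cbind(1, stats::predict(basis, dataset$cells$pseudotime[idx]))
  for (g in tgts) {
    e <- object$edges[object$edges$target == g, ]
    x <- dataset$norm[e$regulator, idx, drop = FALSE]
    x0 <- t(x) - Mn %*% object$trend$gamma_x[, e$regulator, drop = FALSE]
    out[g, ] <- drop(Mn %*% object$trend$gamma_y[[g]]) +
      drop(x0 %*% e$coefficient)
  }
  out
}

#' @export
residuals.state_grn <- function(object, dataset, cells = NULL, ...) {
  pred <- predict(object, dataset, cells = cells)
  idx <- resolve_cells(dataset, cells)
  dataset$norm[rownames(pred), idx, drop = FALSE] - pred
}

#' Diagnostic plot of a fitted state GRN
#'
#' Left: histogram of edge coefficients. Right: out-degree versus
#' summed absolute coefficient per regulator.
#'
#' @param x a `state_grn`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.state_grn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$edges$coefficient, main = paste("state", x$state),
                 xlab = "edge coefficient", col = "grey80", ...)
  deg <- table(x$edges$regulator)
  wsum <- tapply(abs(x$edges$coefficient), x$edges$regulator, sum)
  graphics::plot(as.numeric(deg), as.numeric(wsum[names(deg)]),
                 xlab = "out-degree", ylab = "sum |coefficient|",
                 main = "regulators", pch = 19, col = "steelblue")
  invisible(x)
}
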