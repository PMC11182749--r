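## In-silico TF knockout / overexpression: iterative signal propagation
## through the fitted network, projection of the simulated expression
## shift onto the 2-D embedding as a vector field, the developmental
## flow (pseudotime gradient), and perturbation scores per grid point.

#' Propagate a TF perturbation through a state network
#'
#' Sets the perturbed TF to zero (knockout) or 1.5 times its maximal
#' normalised expression (overexpression) and propagates the resulting
#' expression shift through the network coefficient matrix for
#' `n_steps` regulatory hops. After every hop the TF's own shift is
#' re-clamped to its fixed delta and implied expression is clipped at
#' zero (expression cannot be negative). With no clipping the result
#' is linear in the initial delta.
#'
#' @param grn a `state_grn` (typically pruned to its top 10,000
#'   edges).
#' @param dataset a [cell_dataset()].
#' @param tf perturbed transcription factor (must be a network gene).
#' @param mode `"KO"` or `"OE"`.
#' @param n_steps number of propagation hops (default 3).
#' @param cells cell selector (default: all cells).
#' @param oe_value override for the overexpression target value;
#'   default `1.5 * max` over the selected cells.
#' @param quiet suppress the zero-out-degree warning.
#' @return genes x cells matrix of expression shifts (delta), over the
#'   union of network genes and the perturbed TF.
#' @export
propagate_perturbation <- function(grn, dataset, tf, mode = c("KO", "OE"),
                                   n_steps = 3, cells = NULL,
                                   oe_value = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(grn, "state_grn"), inherits(dataset, "cell_dataset"))
  genes <- sort(unique(c(grn$edges$regulator, grn$edges$target, tf)))
  genes <- intersect(union(genes, tf), dataset$genes)
  if (!tf %in% dataset$genes) {
    near <- utils::head(dataset$genes[
      order(utils::adist(tf, dataset$genes))], 3)
    stopf("TF '%s' not found; nearest gene names: %s", tf,
          paste(near, collapse = ", "))
  }
  idx <- resolve_cells(dataset, cells)
  X <- dataset$norm[genes, idx, drop = FALSE]
  if (!tf %in% grn$edges$regulator && !quiet)
    warnf("TF '%s' has no outgoing edges in state '%s'; delta is confined to itself",
          tf, grn$state)
  ## W[target, regulator]
  W <- t(grn_adjacency(grn, genes))
  target_value <- if (mode == "KO") 0 else
    (oe_value %||% (1.5 * max(X[tf, ])))
  d_tf <- target_value - X[tf, ]
  delta <- matrix(0, length(genes), length(idx),
                  dimnames = dimnames(X))
  delta[tf, ] <- d_tf
  for (s in seq_len(n_steps)) {
    delta <- W %*% delta
    delta[tf, ] <- d_tf
    delta <- pmax(X + delta, 0) - X
  }
  delta
}

#' Precompute the geometry shared by all perturbation fields
#'
#' K-nearest-neighbour structure on the embedding, per-cell neighbour
#' expression differences, and the Gaussian grid kernel. Build it once
#' and reuse it across TFs and modes.
#'
#' @param dataset a [cell_dataset()].
#' @param cells cell selector (default all).
#' @param genes genes over which shift/expression similarity is
#'   computed (typically the network gene universe).
#' @param k_neighbors neighbours per cell (default `min(200, n - 1)`,
#'   ties broken by cell index).
#' @param grid_size grid resolution per axis (default 40).
#' @param kernel_sigma Gaussian kernel bandwidth for grid smoothing;
#'   default = the grid spacing.
#' @param min_mass_frac grid points with kernel mass below this
#'   fraction of the maximal grid mass are masked (default 0.05).
#' @return list of class `field_context`.
#' @export
field_context <- function(dataset, cells = NULL, genes = NULL,
                          k_neighbors = NULL, grid_size = 40,
                          kernel_sigma = NULL, min_mass_frac = 0.05) {
  stopifnot(inherits(dataset, "cell_dataset"))
  idx <- resolve_cells(dataset, cells)
  n <- length(idx)
  genes <- genes %||% dataset$genes
  genes <- intersect(genes, dataset$genes)
  k <- min(k_neighbors %||% 200, n - 1L)
  emb <- cbind(dataset$cells$emb_x[idx], dataset$cells$emb_y[idx])
  D2 <- as.matrix(stats::dist(emb))^2
  diag(D2) <- Inf
  ord <- apply(D2, 1L, function(r) order(r)[seq_len(k)])
  nbrs <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)

  gx <- seq(min(emb[, 1]), max(emb[, 1]), length.out = grid_size)
  gy <- seq(min(emb[, 2]), max(emb[, 2]), length.out = grid_size)
  spacing <- mean(c(diff(gx)[1], diff(gy)[1]))
  sigma <- kernel_sigma %||% spacing
  gpts <- as.matrix(expand.grid(gx = gx, gy = gy))
  d2g <- outer(gpts[, 1], emb[, 1], `-`)^2 +
    outer(gpts[, 2], emb[, 2], `-`)^2
  Kw <- exp(-d2g / (2 * sigma^2))              # grid x cells
  mass <- rowSums(Kw)
  mask <- mass >= min_mass_frac * max(mass)

  X <- dataset$norm[genes, idx, drop = FALSE]
  structure(list(cells = idx, genes = genes, n = n, k = k, emb = emb,
                 nbrs = nbrs, X = X, gx = gx, gy = gy, gpts = gpts,
                 Kw = Kw, mass = mass, mask = mask, sigma = sigma,
                 grid_size = grid_size, spacing = spacing),
            class = "field_context")
}

## grid-smooth per-cell vectors into a grid_field
grid_smooth <- function(ctx, vcell) {
  vx <- drop(ctx$Kw %*% vcell[, 1]) / ctx$mass
  vy <- drop(ctx$Kw %*% vcell[, 2]) / ctx$mass
  structure(list(gx = ctx$gx, gy = ctx$gy, gpts = ctx$gpts,
                 vx = vx, vy = vy, mass = ctx$mass, mask = ctx$mask,
                 grid_size = ctx$grid_size, vcell = vcell),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field: %d x %d grid, %d valid points (%.0f%% of mass)\n",
              x$grid_size, x$grid_size, sum(x$mask),
              100 * sum(x$mass[x$mask]) / sum(x$mass)))
  invisible(x)
}

#' Project a simulated expression shift onto the embedding
#'
#' For every cell, the similarity between its shift vector delta and
#' the expression difference towards each of its k nearest embedding
#' neighbours is a Pearson correlation over the network genes;
#' transition probabilities are the softmax of similarity /
#' `temperature`; the cell vector is the probability-weighted mean
#' neighbour displacement minus the unweighted mean (density
#' correction), and cell vectors are Gaussian-kernel averaged onto the
#' grid. Cells with a zero or constant delta receive uniform
#' transition probabilities, hence (with the correction) a null
#' vector.
#'
#' @param delta genes x cells shift matrix from
#'   [propagate_perturbation()]; its columns must correspond to the
#'   context cells.
#' @param ctx a [field_context()] (or a [cell_dataset()], from which a
#'   default context is built).
#' @param temperature softmax temperature (default 0.05).
#' @param density_correction subtract the unweighted mean neighbour
#'   displacement (default TRUE).
#' @param ... passed to [field_context()] when `ctx` is a dataset.
#' @return A `grid_field` (list with grid axes, `vx`, `vy`, `mass`,
#'   `mask`).
#' @export
simulation_vector_field <- function(delta, ctx, temperature = 0.05,
                                    density_correction = TRUE, ...) {
  if (inherits(ctx, "cell_dataset"))
    ctx <- field_context(ctx, genes = rownames(delta), ...)
  stopifnot(inherits(ctx, "field_context"))
  genes <- intersect(ctx$genes, rownames(delta))
  n <- ctx$n; k <- ctx$k
  if (ncol(delta) != n)
    stopf("delta has %d columns but the context has %d cells",
          ncol(delta), n)
  Xg <- ctx$X[genes, , drop = FALSE]
  Dg <- delta[genes, , drop = FALSE]
  vcell <- matrix(0, n, 2L)
  for (c0 in seq_len(n)) {
    nb <- ctx$nbrs[c0, ]
    E <- ctx$emb[nb, , drop = FALSE]
    disp <- cbind(E[, 1] - ctx$emb[c0, 1], E[, 2] - ctx$emb[c0, 2])
    dc <- Dg[, c0]
    dc0 <- dc - mean(dc)
    ssd <- sum(dc0^2)
    if (ssd == 0) {
      P <- rep(1 / k, k)
    } else {
      M <- Xg[, nb, drop = FALSE] - Xg[, c0]
      M0 <- M - matrix(colMeans(M), nrow(M), k, byrow = TRUE)
      denom <- sqrt(colSums(M0^2) * ssd)
      sim <- drop(crossprod(M0, dc0))
      sim <- ifelse(denom > 0, sim / denom, 0)
      z <- sim / temperature
      z <- z - max(z)
      P <- exp(z); P <- P / sum(P)
    }
    v <- drop(crossprod(disp, P))
    if (density_correction) v <- v - colMeans(disp)
    vcell[c0, ] <- v
  }
  grid_smooth(ctx, vcell)
}

#' Developmental flow: gradient of grid-smoothed pseudotime
#'
#' Pseudotime is smoothed onto the grid as the mean over the
#' `k_regression` nearest cells of each grid point, regularised by a
#' Gaussian blur of `grid_smooth_sigma` grid cells (finite-sample
#' jitter in the k-NN means is otherwise amplified by differencing),
#' and the flow is its central-difference gradient (one-sided at the
#' borders), masked like the simulation field.
#'
#' @param dataset a [cell_dataset()] with per-cell pseudotime, or a
#'   [field_context()] built from one.
#' @param cells cell selector (ignored when a context is supplied).
#' @param pseudotime per-cell pseudotime overriding the dataset column.
#' @param grid_size,kernel_sigma,min_mass_frac grid parameters (see
#'   [field_context()]).
#' @param k_regression neighbours for the grid pseudotime regression
#'   (default 30).
#' @param grid_smooth_sigma Gaussian blur bandwidth on the pseudotime
#'   grid, in grid cells (0 disables).
#' @return A `grid_field`.
#' @export
developmental_flow <- function(dataset, cells = NULL, pseudotime = NULL,
                               grid_size = 40, kernel_sigma = NULL,
                               min_mass_frac = 0.05, k_regression = 30,
                               grid_smooth_sigma = 2) {
  if (inherits(dataset, "field_context")) {
    ctx <- dataset
    pt <- pseudotime %||% attr(ctx, "pseudotime")
    if (is.null(pt)) stopf("supply pseudotime with a field_context")
  } else {
    ctx <- field_context(dataset, cells = cells, grid_size = grid_size,
                         kernel_sigma = kernel_sigma,
                         min_mass_frac = min_mass_frac)
    pt <- pseudotime %||% dataset$cells$pseudotime[ctx$cells]
  }
  kr <- min(k_regression, ctx$n)
  d2 <- outer(ctx$gpts[, 1], ctx$emb[, 1], `-`)^2 +
    outer(ctx$gpts[, 2], ctx$emb[, 2], `-`)^2
  gp <- apply(d2, 1L, function(r) mean(pt[order(r)[seq_len(kr)]]))
  g <- ctx$grid_size
  Z <- matrix(gp, g, g)                       # [ix, iy]
  if (grid_smooth_sigma > 0) {
    ix <- seq_len(g)
    Ksm <- exp(-outer(ix, ix, `-`)^2 / (2 * grid_smooth_sigma^2))
    Ksm <- Ksm / rowSums(Ksm)
    Z <- Ksm %*% Z %*% t(Ksm)
  }
  hx <- diff(ctx$gx)[1]; hy <- diff(ctx$gy)[1]
  ddx <- Z; ddy <- Z
  ddx[2:(g - 1), ] <- (Z[3:g, ] - Z[1:(g - 2), ]) / (2 * hx)
  ddx[1, ] <- (Z[2, ] - Z[1, ]) / hx
  ddx[g, ] <- (Z[g, ] - Z[g - 1, ]) / hx
  ddy[, 2:(g - 1)] <- (Z[, 3:g] - Z[, 1:(g - 2)]) / (2 * hy)
  ddy[, 1] <- (Z[, 2] - Z[, 1]) / hy
  ddy[, g] <- (Z[, g] - Z[, g - 1]) / hy
  structure(list(gx = ctx$gx, gy = ctx$gy, gpts = ctx$gpts,
                 vx = as.vector(ddx), vy = as.vector(ddy),
                 mass = ctx$mass, mask = ctx$mask,
                 grid_size = ctx$grid_size, grid_pseudotime = as.vector(Z)),
            class = "grid_field")
}

#' Infer pseudotime from a root cell by graph distance
#'
#' Helper mirroring root-based pseudotime: the root cell is the cell
#' with maximal root-marker expression within the designated root
#' state; pseudotime is the shortest-path distance from it on a
#' k-nearest-neighbour embedding graph, rescaled to [0, 1].
#'
#' @param dataset a [cell_dataset()].
#' @param root_state state in which the root cell is sought.
#' @param root_marker gene whose maximal expression picks the root
#'   cell (e.g. a contractile marker such as Myh11).
#' @param k neighbours of the embedding graph (default 15).
#' @return Numeric pseudotime per cell in [0, 1].
#' @export
infer_pseudotime <- function(dataset, root_state, root_marker, k = 15) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (!root_marker %in% dataset$genes) stopf("unknown root marker gene")
  in_root <- dataset$cells$state == root_state
  if (!any(in_root)) stopf("no cells in root state '%s'", root_state)
  root <- which(in_root)[which.max(dataset$norm[root_marker, in_root])]
  emb <- cbind(dataset$cells$emb_x, dataset$cells$emb_y)
  n <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  diag(D) <- Inf
  k <- min(k, n - 1L)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    cbind(i, nb, D[i, nb])
  }))
  g <- igraph::graph_from_edgelist(edges[, 1:2], directed = FALSE)
  igraph::E(g)$weight <- edges[, 3]
  d <- igraph::distances(g, v = root)[1, ]
  if (any(!is.finite(d))) {
    warnf("embedding graph is disconnected; unreachable cells set to max")
    d[!is.finite(d)] <- max(d[is.finite(d)])
  }
  d / max(d)
}

#' Perturbation scores of a simulation field against the flow
#'
#' At every grid point valid in both fields, the perturbation score
#' (PS) is the inner product of the L2-normalised simulation and flow
#' vectors (zero vectors score 0), so PS lies in [-1, 1]: positive PS
#' pushes cells along the trajectory, negative PS against it. The
#' summary scores are the sums of positive and of negative PS over
#' valid grid points.
#'
#' @param sim,flow `grid_field`s on the same grid.
#' @return list with `ps` (per-grid PS, NA outside the joint mask),
#'   `sum_pos`, `sum_neg` and `n_valid`.
#' @export
perturbation_scores <- function(sim, flow) {
  stopifnot(inherits(sim, "grid_field"), inherits(flow, "grid_field"))
  if (!identical(sim$grid_size, flow$grid_size) ||
      !isTRUE(all.equal(sim$gx, flow$gx)) ||
      !isTRUE(all.equal(sim$gy, flow$gy)))
    stopf("simulation and flow fields are on different grids")
  mask <- sim$mask & flow$mask
  norm_s <- sqrt(sim$vx^2 + sim$vy^2)
  norm_f <- sqrt(flow$vx^2 + flow$vy^2)
  ps <- (sim$vx * flow$vx + sim$vy * flow$vy) /
    ifelse(norm_s * norm_f > 0, norm_s * norm_f, Inf)
  ps[!mask] <- NA_real_
  list(ps = ps, sum_pos = sum(pmax(ps[mask], 0)),
       sum_neg = sum(pmin(ps[mask], 0)), n_valid = sum(mask))
}

#' Classify TFs from knockout perturbation-score sums
#'
#' Applies the knockout-score thresholds: a TF is a trajectory
#' `stimulator` when its negative KO score is below `stim_neg_threshold`
#' (default -1) and its positive KO score below `stim_pos_threshold`
#' (default 0.75); a `blocker` when its positive KO score exceeds
#' `block_pos_threshold` (default 1); `context-specific` when both
#' sums are large (negative below the stimulator threshold and
#' positive above the blocker threshold); otherwise `none`.
#'
#' @param scores data.frame with columns `tf`, `mode`, `sum_pos`,
#'   `sum_neg`; KO rows must be present for every TF.
#' @param stim_neg_threshold,stim_pos_threshold,block_pos_threshold
#'   classification thresholds on the KO score sums.
#' @return data.frame ranked by ascending KO `sum_neg`: `tf`,
#'   `ko_sum_pos`, `ko_sum_neg`, (`oe_sum_pos`, `oe_sum_neg` when OE
#'   rows exist), `class`.
#' @export
rank_tfs <- function(scores, stim_neg_threshold = -1,
                     stim_pos_threshold = 0.75, block_pos_threshold = 1) {
  ko <- scores[scores$mode == "KO", ]
  if (nrow(ko) == 0) stopf("KO rows are required for classification")
  out <- data.frame(tf = ko$tf, ko_sum_pos = ko$sum_pos,
                    ko_sum_neg = ko$sum_neg, stringsAsFactors = FALSE)
  oe <- scores[scores$mode == "OE", ]
  if (nrow(oe)) {
    out$oe_sum_pos <- oe$sum_pos[match(out$tf, oe$tf)]
    out$oe_sum_neg <- oe$sum_neg[match(out$tf, oe$tf)]
  }
  stim <- out$ko_sum_neg < stim_neg_threshold
  blk <- out$ko_sum_pos > block_pos_threshold
  out$class <- ifelse(stim & blk, "context-specific",
                      ifelse(stim & out$ko_sum_pos < stim_pos_threshold,
                             "stimulator",
                             ifelse(blk, "blocker", "none")))
  out <- out[order(out$ko_sum_neg, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Systematic knockout/overexpression screen over state networks
#'
#' Runs the full perturbation stage: prunes each state network to its
#' top `k_simulation` edges, propagates every requested TF perturbation
#' per state over that state's cells, assembles the per-cell shifts
#' across the trajectory states, projects them onto the embedding,
#' scores them against the developmental flow, and classifies TFs from
#' the KO score sums.
#'
#' @param dataset a [cell_dataset()].
#' @param grns named list of `state_grn` objects (names = states along
#'   the trajectory); cells of states without a network are excluded.
#' @param tfs TFs to perturb; default: every regulator appearing in
#'   any network.
#' @param modes subset of `c("KO", "OE")`.
#' @param k_simulation edge budget per network (default 10000).
#' @param n_steps propagation hops (default 3).
#' @param k_neighbors,grid_size,kernel_sigma,min_mass_frac,temperature
#'   field parameters (see [field_context()] and
#'   [simulation_vector_field()]).
#' @param k_regression neighbours for the flow's grid pseudotime.
#' @return list of class `perturbation_screen`: `scores` (per TF and
#'   mode), `classification` (from [rank_tfs()]), `flow`, `context`.
#' @export
perturbation_analysis <- function(dataset, grns, tfs = NULL,
                                  modes = c("KO", "OE"),
                                  k_simulation = 10000, n_steps = 3,
                                  k_neighbors = NULL, grid_size = 40,
                                  kernel_sigma = NULL,
                                  min_mass_frac = 0.05,
                                  temperature = 0.05, k_regression = 30) {
  stopifnot(inherits(dataset, "cell_dataset"), is.list(grns))
  states <- names(grns)
  if (is.null(states)) stopf("grns must be a named list (state -> network)")
  grns <- lapply(grns, prune_top_k, k = k_simulation)
  cells <- which(dataset$cells$state %in% states)
  genes <- sort(unique(c(unlist(lapply(grns, function(g)
    c(g$edges$regulator, g$edges$target))))))
  genes <- intersect(genes, dataset$genes)
  tfs <- tfs %||% sort(unique(unlist(lapply(grns, function(g)
    g$edges$regulator))))
  ctx <- field_context(dataset, cells = cells, genes = genes,
                       k_neighbors = k_neighbors, grid_size = grid_size,
                       kernel_sigma = kernel_sigma,
                       min_mass_frac = min_mass_frac)
  flow <- developmental_flow(ctx,
                             pseudotime = dataset$cells$pseudotime[cells],
                             k_regression = k_regression)
  state_of <- dataset$cells$state[cells]
  rows <- list()
  for (tf in tfs) {
    oe_val <- 1.5 * max(dataset$norm[tf, cells])
    for (mode in modes) {
      delta <- matrix(0, length(genes), length(cells),
                      dimnames = list(genes, dataset$cells$cell_id[cells]))
      for (st in states) {
        sc <- which(state_of == st)
        if (length(sc) == 0) next
        d_st <- propagate_perturbation(grns[[st]], dataset, tf, mode = mode,
                                       n_steps = n_steps,
                                       cells = cells[sc],
                                       oe_value = if (mode == "OE") oe_val,
                                       quiet = TRUE)
        common <- intersect(rownames(d_st), genes)
        delta[common, sc] <- d_st[common, , drop = FALSE]
      }
      sim <- simulation_vector_field(delta, ctx, temperature = temperature)
      ps <- perturbation_scores(sim, flow)
      rows[[length(rows) + 1L]] <-
        data.frame(tf = tf, mode = mode, sum_pos = ps$sum_pos,
                   sum_neg = ps$sum_neg, n_valid = ps$n_valid,
                   stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  classification <- if ("KO" %in% modes) rank_tfs(scores) else NULL
  structure(list(scores = scores, classification = classification,
                 flow = flow, context = ctx),
            class = "perturbation_screen")
}

#' @export
print.perturbation_screen <- function(x, ...) {
  cat(sprintf("perturbation_screen: %d TFs x %d mode(s), %d valid grid points\n",
              length(unique(x$scores$tf)), length(unique(x$scores$mode)),
              x$scores$n_valid[1]))
  if (!is.null(x$classification)) {
    cat("classes:\n")
    print(table(x$classification$class))
  }
  invisible(x)
}
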