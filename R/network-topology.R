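## Topology statistics, cross-state overlap, and the per-node rewiring
## score between two state networks.

#' Degree centrality of a state GRN
#'
#' Unweighted and weighted (sum of absolute coefficients) in-, out- and
#' total degrees per node, with dense ranks (largest = rank 1, ties
#' share a rank).
#'
#' @param grn a `state_grn` (typically pruned to its top edges).
#' @return data.frame, one row per node: `gene`, `out_degree`,
#'   `in_degree`, `total_degree`, `w_out`, `w_in`, `w_total`,
#'   `rank_total`, `rank_weighted`.
#' @export
degree_centrality <- function(grn) {
  stopifnot(inherits(grn, "state_grn"))
  e <- grn$edges
  nodes <- sort(unique(c(e$regulator, e$target)))
  z <- stats::setNames(numeric(length(nodes)), nodes)
  out_d <- z; in_d <- z; w_out <- z; w_in <- z
  if (nrow(e)) {
    t1 <- table(e$regulator); out_d[names(t1)] <- t1
    t2 <- table(e$target); in_d[names(t2)] <- t2
    s1 <- tapply(abs(e$coefficient), e$regulator, sum)
    w_out[names(s1)] <- s1
    s2 <- tapply(abs(e$coefficient), e$target, sum)
    w_in[names(s2)] <- s2
  }
  tot <- out_d + in_d; w_tot <- w_out + w_in
  data.frame(gene = nodes, out_degree = as.numeric(out_d),
             in_degree = as.numeric(in_d), total_degree = as.numeric(tot),
             w_out = as.numeric(w_out), w_in = as.numeric(w_in),
             w_total = as.numeric(w_tot),
             rank_total = dense_rank_desc(as.numeric(tot)),
             rank_weighted = dense_rank_desc(as.numeric(w_tot)),
             stringsAsFactors = FALSE)
}

#' Overlap report across state networks
#'
#' Nodes are genes incident to a kept edge; TFs are nodes with at least
#' one outgoing edge in at least one network; edges are (regulator,
#' target) pairs ignoring weight. "Shared" means present in every
#' network.
#'
#' @param grns named list of two or more `state_grn` objects.
#' @return list of class `grn_overlap` with union/shared/unique counts
#'   for nodes, TFs and edges, plus the underlying gene sets.
#' @export
network_overlap <- function(grns) {
  stopifnot(is.list(grns), length(grns) >= 2)
  nm <- names(grns) %||% paste0("grn", seq_along(grns))
  node_sets <- lapply(grns, function(g)
    unique(c(g$edges$regulator, g$edges$target)))
  tf_union <- unique(unlist(lapply(grns, function(g) g$edges$regulator)))
  edge_sets <- lapply(grns, function(g)
    unique(paste(g$edges$regulator, g$edges$target, sep = "\r")))
  shared_nodes <- Reduce(intersect, node_sets)
  union_nodes <- Reduce(union, node_sets)
  tf_sets <- lapply(node_sets, intersect, x = tf_union)
  shared_tfs <- Reduce(intersect, tf_sets)
  union_tfs <- Reduce(union, tf_sets)
  shared_edges <- Reduce(intersect, edge_sets)
  union_edges <- Reduce(union, edge_sets)
  uniq <- function(sets) vapply(seq_along(sets), function(i)
    length(setdiff(sets[[i]], Reduce(union, sets[-i]))), numeric(1))
  structure(list(
    networks = nm,
    n_nodes = stats::setNames(lengths(node_sets), nm),
    n_union_nodes = length(union_nodes),
    n_shared_nodes = length(shared_nodes),
    unique_nodes = stats::setNames(uniq(node_sets), nm),
    n_union_tfs = length(union_tfs),
    n_shared_tfs = length(shared_tfs),
    unique_tfs = stats::setNames(uniq(tf_sets), nm),
    n_union_edges = length(union_edges),
    n_shared_edges = length(shared_edges),
    shared_nodes = sort(shared_nodes),
    shared_tfs = sort(shared_tfs)), class = "grn_overlap")
}

#' @export
print.grn_overlap <- function(x, ...) {
  cat(sprintf("overlap of %d networks (%s)\n", length(x$networks),
              paste(x$networks, collapse = ", ")))
  cat(sprintf("nodes: %d/%d shared (%.0f%%)\n", x$n_shared_nodes,
              x$n_union_nodes, 100 * x$n_shared_nodes / x$n_union_nodes))
  cat(sprintf("TFs:   %d/%d shared (%.0f%%)\n", x$n_shared_tfs,
              x$n_union_tfs, 100 * x$n_shared_tfs / max(1, x$n_union_tfs)))
  cat(sprintf("edges: %d/%d shared\n", x$n_shared_edges, x$n_union_edges))
  invisible(x)
}

#' Per-node rewiring score between two state networks
#'
#' The rewiring score of a node is the sum of absolute changes in the
#' connectivity score (signed edge coefficient) over all its incident
#' edges between the two networks, with absent edges counting as
#' weight zero: with signed weighted adjacency matrices `W_A`, `W_B`
#' (regulator row -> target column) over the union gene space,
#' `score(i) = sum_j |W_A[i,j] - W_B[i,j]| + sum_j |W_A[j,i] - W_B[j,i]|`,
#' self-loops counted once. The score is symmetric in its arguments
#' and zero exactly when the node's incident weights agree.
#'
#' @param grnA,grnB `state_grn` objects (e.g. PrP vs Non-RSP).
#' @param absolute compare absolute instead of signed coefficients.
#' @return data.frame sorted by decreasing score: `gene`, `score`,
#'   `rank` (dense, ties by name retain alphabetical order).
#' @export
rewiring_score <- function(grnA, grnB, absolute = FALSE) {
  stopifnot(inherits(grnA, "state_grn"), inherits(grnB, "state_grn"))
  a <- grnA$edges[c("regulator", "target", "coefficient")]
  b <- grnB$edges[c("regulator", "target", "coefficient")]
  if (absolute) {
    a$coefficient <- abs(a$coefficient)
    b$coefficient <- abs(b$coefficient)
  }
  m <- merge(a, b, by = c("regulator", "target"), all = TRUE,
             suffixes = c("_a", "_b"))
  m$coefficient_a[is.na(m$coefficient_a)] <- 0
  m$coefficient_b[is.na(m$coefficient_b)] <- 0
  m$d <- abs(m$coefficient_a - m$coefficient_b)
  nodes <- sort(unique(c(m$regulator, m$target)))
  score <- stats::setNames(numeric(length(nodes)), nodes)
  s_out <- tapply(m$d, m$regulator, sum)
  score[names(s_out)] <- score[names(s_out)] + s_out
  s_in <- tapply(m$d, m$target, sum)
  score[names(s_in)] <- score[names(s_in)] + s_in
  self <- m$regulator == m$target
  if (any(self)) {
    s_self <- tapply(m$d[self], m$regulator[self], sum)
    score[names(s_self)] <- score[names(s_self)] - s_self
  }
  out <- data.frame(gene = nodes, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  out$rank <- dense_rank_desc(out$score)
  rownames(out) <- NULL
  out
}

#' Top rewired genes between two networks
#'
#' Convenience wrapper returning the `n` genes with highest rewiring
#' score (dense ranking, deterministic ties by name).
#'
#' @param grnA,grnB `state_grn` objects.
#' @param n number of genes (default 50).
#' @param ... passed to [rewiring_score()].
#' @return Head of the rewiring table.
#' @export
top_rewired_genes <- function(grnA, grnB, n = 50, ...) {
  utils::head(rewiring_score(grnA, grnB, ...), n)
}
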