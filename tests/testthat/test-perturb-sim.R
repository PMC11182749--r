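## hand-built two-gene chain A -> B with coefficient w
chain_fixture <- function(w = 0.6, n = 30, base_a = 2, base_b = 5) {
  norm <- rbind(A = rep(base_a, n), B = rep(base_b, n))
  ds <- make_norm_dataset(norm)
  grn <- make_grn(data.frame(regulator = "A", target = "B",
                             coefficient = w, stability = 1, pvalue = 0))
  list(ds = ds, grn = grn)
}

test_that("knockout of a silent TF produces no shift", {
  fx <- chain_fixture(base_a = 0)
  delta <- propagate_perturbation(fx$grn, fx$ds, "A", "KO")
  expect_equal(max(abs(delta)), 0)
})

test_that("a single regulatory chain propagates delta_B = w * delta_A", {
  fx <- chain_fixture(w = 0.6)
  for (steps in c(1, 3, 5)) {
    delta <- propagate_perturbation(fx$grn, fx$ds, "A", "KO",
                                    n_steps = steps)
    expect_equal(unname(delta["A", ]), rep(-2, 30))
    expect_equal(unname(delta["B", ]), rep(0.6 * -2, 30), tolerance = 1e-12)
  }
})

test_that("overexpression clamps the TF to 1.5 x its maximum", {
  set.seed(161)
  norm <- rbind(A = runif(40, 0, 4), B = rep(8, 40))
  ds <- make_norm_dataset(norm)
  grn <- make_grn(data.frame(regulator = "A", target = "B",
                             coefficient = 0.2, stability = 1, pvalue = 0))
  delta <- propagate_perturbation(grn, ds, "A", "OE")
  expect_equal(unname(delta["A", ]), 1.5 * max(norm["A", ]) - norm["A", ])
})

test_that("propagation is linear in the initial delta when nothing clips", {
  fx <- chain_fixture(w = 0.5, base_a = 2, base_b = 50)
  d1 <- propagate_perturbation(fx$grn, fx$ds, "A", "OE", oe_value = 3)
  d2 <- propagate_perturbation(fx$grn, fx$ds, "A", "OE", oe_value = 4)
  expect_equal(unname(d2["B", ]), unname(2 * d1["B", ]), tolerance = 1e-12)
})

test_that("negative implied expression is clipped at zero", {
  fx <- chain_fixture(w = 2, base_a = 3, base_b = 1)  # KO drive -6 on B
  delta <- propagate_perturbation(fx$grn, fx$ds, "A", "KO")
  expect_equal(unname(delta["B", ]), rep(-1, 30))     # floor at expression 0
})

test_that("unknown TFs are rejected with suggestions, isolated TFs warn", {
  fx <- chain_fixture()
  expect_error(propagate_perturbation(fx$grn, fx$ds, "Z", "KO"), "nearest")
  grn_b <- make_grn(data.frame(regulator = "B", target = "A",
                               coefficient = 0, stability = 1, pvalue = 0))
  grn_b$edges <- grn_b$edges[0, ]
  expect_warning(propagate_perturbation(fx$grn, fx$ds, "B", "KO"),
                 "no outgoing")
})

test_that("a zero shift produces a null simulation field", {
  ds <- small_sim$dataset
  ctx <- field_context(ds, genes = ds$genes[1:10], grid_size = 15)
  delta <- matrix(0, 10, ncol(ds$norm),
                  dimnames = list(ds$genes[1:10], ds$cells$cell_id))
  fld <- simulation_vector_field(delta, ctx)
  expect_equal(max(abs(fld$vx)), 0)
  expect_equal(max(abs(fld$vy)), 0)
})

test_that("two-cell geometry gives the closed-form transition vector", {
  norm <- cbind(c1 = c(g1 = 1, g2 = 2, g3 = 3), c2 = c(2, 4, 3.5))
  ds <- make_norm_dataset(norm, pseudotime = c(0, 1), emb_y = c(0, 0.1))
  ctx <- field_context(ds, grid_size = 5, min_mass_frac = 0)
  delta <- cbind(c1 = norm[, 2] - norm[, 1], c2 = c(0, 0, 0))
  rownames(delta) <- rownames(norm)
  fld <- simulation_vector_field(delta, ctx, density_correction = FALSE)
  disp <- c(ds$cells$emb_x[2] - ds$cells$emb_x[1],
            ds$cells$emb_y[2] - ds$cells$emb_y[1])
  expect_equal(fld$vcell[1, ], disp, tolerance = 1e-12)
  ## with the density correction the single-neighbour vector cancels
  fld2 <- simulation_vector_field(delta, ctx)
  expect_equal(fld2$vcell[1, ], c(0, 0), tolerance = 1e-12)
})

test_that("developmental flow recovers a linear pseudotime gradient", {
  set.seed(171)
  n <- 400
  pt <- runif(n)
  ds <- make_norm_dataset(matrix(rnorm(5 * n), 5, n,
                                 dimnames = list(paste0("g", 1:5), NULL)),
                          pseudotime = pt, emb_y = runif(n, 0, 0.5))
  fl <- developmental_flow(ds, grid_size = 20)
  ang <- atan2(fl$vy[fl$mask], fl$vx[fl$mask]) * 180 / pi
  expect_lt(mean(abs(ang)), 10)
  expect_gt(mean(fl$vx[fl$mask]), 0.5)
  ## constant pseudotime: zero flow
  ds2 <- ds; ds2$cells$pseudotime <- rep(0.5, n)
  fl2 <- developmental_flow(ds2, grid_size = 20)
  expect_equal(max(abs(c(fl2$vx, fl2$vy))), 0, tolerance = 1e-10)
})

test_that("perturbation scores match a per-point loop oracle", {
  set.seed(181)
  mkfield <- function(vx, vy, mask) {
    structure(list(gx = 1:4, gy = 1:4,
                   gpts = as.matrix(expand.grid(gx = 1:4, gy = 1:4)),
                   vx = vx, vy = vy, mass = rep(1, 16), mask = mask,
                   grid_size = 4L), class = "grid_field")
  }
  mask <- rep(TRUE, 16)
  flow <- mkfield(rnorm(16), rnorm(16), mask)
  sim <- mkfield(rnorm(16), rnorm(16), mask)
  ps <- perturbation_scores(sim, flow)
  oracle_pos <- 0; oracle_neg <- 0
  for (i in 1:16) {
    ns <- sqrt(sim$vx[i]^2 + sim$vy[i]^2)
    nf <- sqrt(flow$vx[i]^2 + flow$vy[i]^2)
    v <- if (ns * nf > 0)
      (sim$vx[i] * flow$vx[i] + sim$vy[i] * flow$vy[i]) / (ns * nf) else 0
    if (v > 0) oracle_pos <- oracle_pos + v else oracle_neg <- oracle_neg + v
  }
  expect_equal(ps$sum_pos, oracle_pos, tolerance = 1e-12)
  expect_equal(ps$sum_neg, oracle_neg, tolerance = 1e-12)
  ## aligned and anti-aligned fields saturate at +/-1 per point
  same <- perturbation_scores(flow, flow)
  expect_equal(same$ps[mask], rep(1, 16))
  expect_equal(same$sum_neg, 0)
  anti <- perturbation_scores(mkfield(-flow$vx, -flow$vy, mask), flow)
  expect_equal(anti$ps[mask], rep(-1, 16))
  expect_equal(anti$sum_pos, 0)
})

test_that("TF classification applies the knockout-score thresholds", {
  sc <- data.frame(tf = c("s", "b", "c", "n"), mode = "KO",
                   sum_pos = c(0.3, 1.5, 2.0, 0.5),
                   sum_neg = c(-2.0, 0.0, -3.0, -0.5))
  cls <- rank_tfs(sc)
  expect_equal(cls$class[cls$tf == "s"], "stimulator")
  expect_equal(cls$class[cls$tf == "b"], "blocker")
  expect_equal(cls$class[cls$tf == "c"], "context-specific")
  expect_equal(cls$class[cls$tf == "n"], "none")
  expect_equal(cls$tf[1], "c")   # ranked by ascending negative KO score
  expect_error(rank_tfs(sc[sc$mode == "OE", ]), "KO rows")
})

test_that("screen fields are deterministic and conserve grid mass", {
  ds <- small_sim$dataset
  states <- unique(ds$cells$state)
  grns <- lapply(stats::setNames(states, states), function(st)
    fit_state_grn(ds, small_base, state = st, seed = 1))
  scr1 <- perturbation_analysis(ds, grns, tfs = "TF01", modes = "KO")
  scr2 <- perturbation_analysis(ds, grns, tfs = "TF01", modes = "KO")
  expect_identical(scr1$scores, scr2$scores)
  fl <- scr1$flow
  expect_gte(sum(fl$mass[fl$mask]) / sum(fl$mass), 0.95)
})

test_that("knockout and overexpression fields mirror each other", {
  ds <- small_sim$dataset
  states <- unique(ds$cells$state)
  grns <- lapply(stats::setNames(states, states), function(st)
    fit_state_grn(ds, small_base, state = st, seed = 1))
  grns <- lapply(grns, prune_top_k, k = 10000)
  genes <- sort(unique(unlist(lapply(grns, function(g)
    c(g$edges$regulator, g$edges$target)))))
  ctx <- field_context(ds, genes = genes)
  tf <- small_sim$truth$stimulator_tfs[1]
  fields <- lapply(c("KO", "OE"), function(mode) {
    delta <- matrix(0, length(genes), ncol(ds$norm),
                    dimnames = list(genes, ds$cells$cell_id))
    for (st in states) {
      sc <- which(ds$cells$state == st)
      d <- propagate_perturbation(grns[[st]], ds, tf, mode, cells = sc,
                                  quiet = TRUE)
      cm <- intersect(rownames(d), genes)
      delta[cm, sc] <- d[cm, ]
    }
    simulation_vector_field(delta, ctx)
  })
  flow <- developmental_flow(ds)
  ps_ko <- perturbation_scores(fields[[1]], flow)
  ps_oe <- perturbation_scores(fields[[2]], flow)
  ## net scores point in opposite directions ...
  expect_lt((ps_ko$sum_pos + ps_ko$sum_neg) *
              (ps_oe$sum_pos + ps_oe$sum_neg), 0)
  ## ... and the vector fields themselves are anticorrelated
  m <- fields[[1]]$mask
  r <- stats::cor(c(fields[[1]]$vx[m], fields[[1]]$vy[m]),
                  c(fields[[2]]$vx[m], fields[[2]]$vy[m]))
  expect_lt(r, -0.3)
})

test_that("graph-distance pseudotime increases from the root cell", {
  ds <- small_sim$dataset
  pt <- infer_pseudotime(ds, root_state = "Non-RSP", root_marker = "Myh11")
  expect_true(all(pt >= 0 & pt <= 1))
  expect_gt(stats::cor(pt, ds$cells$pseudotime), 0.9)
})
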