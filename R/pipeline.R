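## End-to-end orchestration from a single declarative configuration:
## simulate -> atac -> basegrn -> fit -> topology -> perturb ->
## signatures, with a JSON manifest recording seeds, parameters and
## per-file checksums for reproducibility.

#' Default pipeline configuration
#'
#' Nested list mirroring each stage's defaults; the `simulate` block
#' generates all inputs, so the pipeline runs with no external data.
#' Stage seeds are derived from the global seed by a fixed counter
#' (seed + stage index), giving reproducibility with stage-level
#' independence.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @param ... named overrides merged into the defaults (top-level
#'   blocks `simulate`, `atac`, `basegrn`, `fit`, `topology`,
#'   `perturb`, `signatures`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "grnrewire_out", ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(n_cells = 1500, n_tfs = 25, n_targets = 150,
                    edge_density = 0.1, noise_sd = 0.3, decoy_rate = 0.5),
    atac = list(min_overlap = 0.5, fc_threshold = 2, padj_threshold = 0.01,
                n_da_peaks = 2000, planted_fc = 4, frac_da = 0.05,
                replicates = 2, da_noise_sd = 0.25),
    basegrn = list(score_fraction = 0.8, max_distance = 1e5),
    fit = list(n_bags = 20, bag_fraction = 0.8, stability_min = 0.9,
               coef_p_max = 1e-3),
    topology = list(k_topology = 2000, top_rewired = 50),
    perturb = list(k_simulation = 10000, n_steps = 3, oe_multiplier = 1.5,
                   temperature = 0.05, grid_size = 40,
                   stim_neg_threshold = -1, stim_pos_threshold = 0.75,
                   block_pos_threshold = 1),
    signatures = list(logfc_min = 0.5, padj_max = 0.05, top_n = 10,
                      connectivity_min = 0.1))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && nm %in% names(cfg))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges and cross-stage constraints; each violation
#' is reported with the named constraint.
#'
#' @param config a `pipeline_config` (or plain list).
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_pipeline_config <- function(config) {
  chk <- function(ok, constraint) if (!ok) stopf("invalid config: %s", constraint)
  chk(is.numeric(config$seed), "seed must be numeric")
  chk(config$perturb$k_simulation >= config$topology$k_topology,
      "k_simulation >= k_topology (the simulation network must contain the topology network)")
  chk(config$atac$min_overlap > 0 && config$atac$min_overlap <= 1,
      "min_overlap in (0, 1]")
  chk(config$simulate$edge_density > 0 && config$simulate$edge_density <= 1,
      "edge_density in (0, 1]")
  chk(config$perturb$oe_multiplier >= 1, "oe_multiplier >= 1")
  chk(config$atac$replicates >= 2, "replicates >= 2")
  invisible(config)
}

#' Read / write pipeline configurations as YAML
#'
#' The configuration round-trips losslessly through disk.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(seed = raw$seed %||% 1L,
                 outdir = raw$outdir %||% "grnrewire_out"),
            raw[setdiff(names(raw), c("seed", "outdir"))]))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> atac -> basegrn -> fit (per state) ->
#' topology/rewiring -> perturbation screen -> signatures, writing
#' every stage's outputs as plain-text files under the configured
#' output directory plus a JSON manifest with per-file MD5 checksums.
#' Re-running with an unchanged configuration reproduces identical
#' checksums. A failing stage aborts with the stage named; partial
#' outputs are kept next to a `FAILED` marker file.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param outdir overrides the configured output directory.
#' @return list with `manifest` (also written as JSON) and the main
#'   in-memory results (`dataset`, `truth`, `base`, `grns`,
#'   `rewiring`, `screen`, `signatures`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out <- outdir %||% config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  manifest <- list(tool = "grnrewire",
                   version = as.character(utils::packageVersion("grnrewire")),
                   seed = config$seed, stages = list())
  results <- list()
  files <- character(0)
  stage_seed <- function(i) config$seed + i

  run_stage <- function(name, fun) {
    message(sprintf("[grnrewire] stage=%s seed=%d", name, config$seed))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "complete")
  }
  emit <- function(df, name, row_names = FALSE) {
    path <- file.path(out, name)
    write_tsv(df, path, row_names = row_names)
    files <<- c(files, path)
  }

  run_stage("simulate", function() {
    cfgs <- config$simulate
    tc <- trajectory_config(n_cells = cfgs$n_cells, n_tfs = cfgs$n_tfs,
                            n_targets = cfgs$n_targets,
                            edge_density = cfgs$edge_density,
                            noise_sd = cfgs$noise_sd, seed = stage_seed(1))
    sim <- simulate_trajectory_dataset(tc)
    gen <- simulate_regulatory_genome(sim$truth, seed = stage_seed(2),
                                      decoy_rate = cfgs$decoy_rate)
    results$sim <<- sim; results$gen <<- gen
    emit(sim$dataset$cells, "cell_metadata.tsv")
    emit(as.data.frame(sim$dataset$counts), "counts.tsv", row_names = TRUE)
    emit(sim$truth$edges, "planted_edges.tsv")
    p <- file.path(out, "peaks.bed"); write_bed(gen$peaks, p)
    files <<- c(files, p)
    emit(gen$tss, "tss.tsv")
    p <- file.path(out, "motifs.jaspar"); write_jaspar(gen$pwms, p)
    files <<- c(files, p)
    p <- file.path(out, "genome.fa"); write_fasta(gen$genome, p)
    files <<- c(files, p)
    emit(gen$tf2motif, "tf2motif.tsv")
  })

  run_stage("atac", function() {
    cfga <- config$atac
    gen <- results$gen
    ## jittered second replicate exercises reproducibility filtering
    jit <- with_seed(stage_seed(3),
                     sample(-50:50, nrow(gen$peaks), replace = TRUE))
    repB <- gen$peaks
    repB$start <- pmax(1L, repB$start + jit); repB$end <- repB$end + jit
    ordB <- order(repB$chrom, repB$start, repB$end)
    repro <- reproducible_peaks(gen$peaks[c("chrom", "start", "end")],
                                repB[ordB, c("chrom", "start", "end")],
                                min_overlap = cfga$min_overlap)
    pan <- union_peaks(list(repro))
    results$pan <<- pan
    ann <- annotate_peaks(pan, gen$tss, gen$gene_models)
    sim_atac <- simulate_atac_counts(n_peaks = cfga$n_da_peaks,
                                     planted_fc = cfga$planted_fc,
                                     frac_da = cfga$frac_da,
                                     replicates = cfga$replicates,
                                     noise_sd = cfga$da_noise_sd,
                                     seed = stage_seed(4))
    da <- moderated_differential_accessibility(
      sim_atac$density, sim_atac$groups,
      fc_threshold = cfga$fc_threshold,
      padj_threshold = cfga$padj_threshold)
    results$da <<- da
    p <- file.path(out, "pan_peaks.bed"); write_bed(pan, p)
    files <<- c(files, p)
    emit(data.frame(category = names(ann$proportions),
                    proportion = as.numeric(ann$proportions)),
         "peak_annotation.tsv")
    emit(da, "differential_accessibility.tsv")
  })

  run_stage("basegrn", function() {
    gen <- results$gen
    p2g <- assign_peaks_to_genes(gen$peaks, gen$tss,
                                 max_distance = config$basegrn$max_distance)
    hits <- scan_motifs(gen$peak_sequences, gen$pwms,
                        score_fraction = config$basegrn$score_fraction)
    base <- build_base_grn(p2g, hits, gen$tf2motif)
    results$base <<- base
    emit(base$pairs, "base_grn_pairs.tsv")
    emit(base$provenance, "base_grn_provenance.tsv")
  })

  run_stage("fit", function() {
    cfgf <- config$fit
    sim <- results$sim
    states <- unique(sim$dataset$cells$state)
    grns <- lapply(stats::setNames(states, states), function(st)
      fit_state_grn(sim$dataset, results$base, state = st,
                    n_bags = cfgf$n_bags, bag_fraction = cfgf$bag_fraction,
                    stability_min = cfgf$stability_min,
                    coef_p_max = cfgf$coef_p_max, seed = stage_seed(5)))
    results$grns <<- grns
    all_edges <- do.call(rbind, lapply(states, function(st)
      cbind(state = st, grns[[st]]$edges)))
    emit(all_edges, "state_grn_edges.tsv")
  })

  run_stage("topology", function() {
    k <- config$topology$k_topology
    grns_t <- lapply(results$grns, prune_top_k, k = k)
    topo <- do.call(rbind, lapply(names(grns_t), function(st)
      cbind(state = st, degree_centrality(grns_t[[st]]))))
    emit(topo, "topology.tsv")
    ov <- network_overlap(grns_t)
    jsonlite::write_json(unclass(ov)[c("networks", "n_union_nodes",
                                       "n_shared_nodes", "n_union_tfs",
                                       "n_shared_tfs", "n_union_edges",
                                       "n_shared_edges")],
                         file.path(out, "overlap.json"), auto_unbox = TRUE)
    files <<- c(files, file.path(out, "overlap.json"))
    states <- names(grns_t)
    a <- if ("PrP" %in% states) "PrP" else states[min(3, length(states))]
    b <- if ("Non-RSP" %in% states) "Non-RSP" else states[1]
    rw <- rewiring_score(grns_t[[a]], grns_t[[b]])
    results$rewiring <<- rw
    emit(utils::head(rw, config$topology$top_rewired), "top_rewired.tsv")
  })

  run_stage("perturb", function() {
    cfgp <- config$perturb
    screen <- perturbation_analysis(results$sim$dataset, results$grns,
                                    k_simulation = cfgp$k_simulation,
                                    n_steps = cfgp$n_steps,
                                    temperature = cfgp$temperature,
                                    grid_size = cfgp$grid_size)
    results$screen <<- screen
    emit(screen$scores, "perturbation_scores.tsv")
    emit(screen$classification, "tf_classification.tsv")
    fl <- screen$flow
    emit(data.frame(gx = fl$gpts[, 1], gy = fl$gpts[, 2],
                    vx = fl$vx, vy = fl$vy, mask = fl$mask),
         "developmental_flow.tsv")
  })

  run_stage("signatures", function() {
    cfgs <- config$signatures
    sim <- results$sim
    states <- unique(sim$dataset$cells$state)
    a <- if ("PrP" %in% states) "PrP" else states[min(3, length(states))]
    b <- if ("Non-RSP" %in% states) "Non-RSP" else states[1]
    de <- wilcoxon_de(sim$dataset, a, b)
    emit(de, "differential_expression.tsv")
    sig <- define_signature_from_de(de, logfc_min = cfgs$logfc_min,
                                    padj_max = cfgs$padj_max,
                                    name = paste0(a, "_signature"))
    reg <- regulator_signature(results$screen$scores,
                               results$grns[[a]], top_n = cfgs$top_n,
                               connectivity_min = cfgs$connectivity_min)
    emit(data.frame(signature = c(rep(sig$name, length(sig$genes)),
                                  rep(reg$name, length(reg$genes))),
                    gene = c(sig$genes, reg$genes)),
         "signatures.tsv")
    sc <- rank_signature_score(sim$dataset, sig)
    emit(data.frame(cell_id = names(sc), score = as.numeric(sc)),
         "signature_scores.tsv")
    results$signatures <<- list(state = sig, regulators = reg)
  })

  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  manifest$parameters_md5 <- {
    tmp <- file.path(out, "config.yaml")
    write_pipeline_config(config, tmp)
    files <- c(files, tmp)
    unname(tools::md5sum(tmp))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("[grnrewire] complete: %d stages, %d files",
                  length(manifest$stages), length(manifest$files)))
  invisible(list(manifest = manifest, dataset = results$sim$dataset,
                 truth = results$sim$truth, base = results$base,
                 grns = results$grns, rewiring = results$rewiring,
                 screen = results$screen, da = results$da,
                 signatures = results$signatures, outdir = out))
}
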