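# Per-enzyme orchestration: configuration, the full analysis (load ->
# superpose -> PCA + deformation vector -> ANM -> overlap statistics ->
# random-mode baseline), and report serialization.

#' Read and validate an enzyme analysis configuration
#'
#' Plain YAML, one file per enzyme. Required keys: `name`; `structures` (list
#' of entries with `id`, `path` or `accession`, and `role` among
#' open/closed/other); `representative_open` / `representative_closed` (ids);
#' `loop` (`chain`, `start`, `end`). Optional: `chains` (chain filter), `anm`
#' (`cutoff` = 15, `gamma` = 1, `n_soft_modes` = 10, `structure` =
#' `"representative_open"` default or `"ensemble_mean"` for ensembles
#' generated symmetrically about a reference), `random` (`n_sets` = 100,
#' `seed` = 1), `weighting` (default `amplitude_inv_eig`), `ligand_strip`
#' (default TRUE; C-alpha extraction always drops ligands, the flag is kept to
#' make the choice explicit in run logs), `cache_dir` for accession fetches.
#'
#' @param path path to a YAML configuration file.
#' @return Object of class `enzyme_config`.
#' @export
read_enzyme_config <- function(path) {
  if (!file.exists(path)) stop_lm(sprintf("config '%s' not found", path), "usage_error")
  cfg <- yaml::read_yaml(path)
  validate_enzyme_config(cfg)
}

#' @rdname read_enzyme_config
#' @param cfg a configuration list (as parsed from YAML).
#' @export
validate_enzyme_config <- function(cfg) {
  need <- c("name", "structures", "representative_open",
            "representative_closed", "loop")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop_lm(paste("config lacks required key(s):", paste(missing, collapse = ", ")),
            "validation_error")
  ids <- vapply(cfg$structures, function(s) as.character(s$id), "")
  if (anyDuplicated(ids)) stop_lm("duplicate structure ids", "validation_error")
  for (rep_id in c(cfg$representative_open, cfg$representative_closed))
    if (!rep_id %in% ids)
      stop_lm(sprintf("representative '%s' not among structure sources", rep_id),
              "validation_error")
  if (!all(c("chain", "start", "end") %in% names(cfg$loop)))
    stop_lm("loop must give chain, start, end", "validation_error")
  defaults <- list(chains = NULL,
                   anm = list(), random = list(), weighting = "amplitude_inv_eig",
                   ligand_strip = TRUE, cache_dir = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  anm_def <- list(cutoff = 15, gamma = 1, n_soft_modes = 10L,
                  structure = "representative_open")
  for (k in names(anm_def)) if (is.null(cfg$anm[[k]])) cfg$anm[[k]] <- anm_def[[k]]
  rnd_def <- list(n_sets = 100L, seed = 1L)
  for (k in names(rnd_def)) if (is.null(cfg$random[[k]])) cfg$random[[k]] <- rnd_def[[k]]
  structure(cfg, class = "enzyme_config")
}

config_loop <- function(cfg)
  segment_selection(cfg$loop$chain, cfg$loop$start, cfg$loop$end)

load_config_structures <- function(cfg) {
  models <- list()
  for (s in cfg$structures) {
    path <- s$path
    if (is.null(path)) {
      if (is.null(s$accession))
        stop_lm(sprintf("structure '%s' has neither path nor accession", s$id),
                "validation_error")
      path <- if (is.null(cfg$cache_dir)) fetch_structures(s$accession)
              else fetch_structures(s$accession, cfg$cache_dir)
    }
    models[[as.character(s$id)]] <-
      load_structure(path, chain_filter = cfg$chains, id = as.character(s$id))
  }
  models
}

# restrict a coarse model to a set of residue keys (order of `keys`)
subset_model <- function(model, keys) {
  pos <- match(keys, model_keys(model))
  coarse_model(id = model$id, chain = model$chain[pos], resno = model$resno[pos],
               insert = model$insert[pos], xyz = model$xyz[pos, , drop = FALSE],
               bfactor = model$bfactor[pos])
}

#' Run the full per-enzyme analysis
#'
#' Executes the complete pipeline for one enzyme: load structures, superpose
#' the ensemble iteratively, PCA of the ensemble and the open-to-closed
#' deformation vector, ANM of the representative open structure (restricted to
#' the residues commonly resolved across the ensemble, so every statistic is
#' computed on one fixed correspondence), per-mode and cumulative overlaps,
#' loop overlaps and the Table-style summary, weighted-average overlap
#' profiles over mode and sequence windows, the random-mode baseline and
#' enhancement factor, soft-mode collectivities and the B-factor comparison.
#'
#' @param config an [read_enzyme_config()] result (or a list accepted by
#'   [validate_enzyme_config()]).
#' @param out_dir optional directory; when given, all report tables, mode sets
#'   and a run log are written there.
#' @return Object of class `enzyme_report` (see Details), a list with the
#'   deviation metrics (`table1`), PCA fractions, overlap profiles, the loop
#'   overlap summary (`table2`), window profiles, the enhancement analysis,
#'   collectivities and the B-factor correlation.
#' @export
run_enzyme_analysis <- function(config, out_dir = NULL) {
  config <- validate_enzyme_config(unclass(config))
  stage <- "load"
  result <- tryCatch({
    models <- load_config_structures(config)
    open <- models[[config$representative_open]]
    closed <- models[[config$representative_closed]]
    loop <- config_loop(config)

    stage <- "superpose"
    ens <- iterative_superpose_ensemble(models)
    keys <- ens$keys
    key_str <- residue_keys(keys$chain, keys$resno, keys$insert)

    chains <- unique(keys$chain)
    loop_len <- config$loop$end - config$loop$start + 1L
    per_chain_loops <- lapply(chains, function(ch) {
      seg <- segment_selection(ch, config$loop$start, config$loop$end)
      n_in <- sum(keys$chain == ch & keys$resno >= seg$start_residue &
                    keys$resno <= seg$end_residue)
      if (n_in >= 2L) seg else NULL
    })
    per_chain_loops <- Filter(Negate(is.null), per_chain_loops)

    stage <- "deviation_metrics"
    table1 <- do.call(rbind, lapply(per_chain_loops, function(seg) {
      data.frame(enzyme = config$name, chain = seg$chain,
                 loop = sprintf("%d-%d", seg$start_residue, seg$end_residue),
                 rmsd_overall = rmsd_selection(open, closed, "all", "all"),
                 rmsd_loop = rmsd_selection(open, closed, seg, "all"),
                 rmsd_isolated_loop = rmsd_selection(open, closed, seg, "selection"),
                 tip_motion = as.numeric(tip_displacement(open, closed, seg)))
    }))

    stage <- "pca"
    pca <- ensemble_pca(ens)
    pc1 <- pca$vectors[, 1]

    stage <- "deformation"
    open_c <- subset_model(open, key_str)
    closed_c <- subset_model(closed, key_str)
    defvec <- deformation_vector(open_c, closed_c)

    stage <- "anm"
    anm_input <- switch(config$anm$structure,
      representative_open = open_c,
      ensemble_mean = coarse_model(id = "ensemble_mean", chain = keys$chain,
                                   resno = keys$resno, insert = keys$insert,
                                   xyz = ens$mean_xyz,
                                   bfactor = open_c$bfactor),
      stop_lm(sprintf("unknown anm structure '%s'", config$anm$structure),
              "validation_error"))
    hm <- build_hessian(anm_input, r_cut = config$anm$cutoff,
                        gamma = config$anm$gamma)
    anm <- anm_modes(hm)
    p <- min(config$anm$n_soft_modes, anm$k)

    stage <- "overlap"
    prof_def <- overlap_profile(defvec, anm, "deformation")
    prof_pc1 <- overlap_profile(pc1, anm, "PC1")
    loop_main <- per_chain_loops[[
      which(vapply(per_chain_loops, function(s) s$chain, "") == config$loop$chain)[1]]]
    loop_ov <- vapply(seq_len(p), function(j)
      segment_overlap(defvec, anm, loop_main, keys = keys, j = j), numeric(1))
    loop_ov_pc1 <- vapply(seq_len(p), function(j)
      segment_overlap(pc1, anm, loop_main, keys = keys, j = j), numeric(1))
    loop_overlaps <- data.frame(mode = seq_len(p), deformation = loop_ov,
                                pc1 = loop_ov_pc1)

    hi <- which.max(loop_ov)
    ge5 <- which(loop_ov >= 0.5)

    stage <- "mode_window"
    mw <- mode_window_profile(defvec, anm, loop_main, p = p,
                              weighting = config$weighting, keys = keys)

    stage <- "random_baseline"
    enh <- enhancement_analysis(defvec, anm, loop_main, p = p,
                                n_random = config$random$n_sets,
                                seed = config$random$seed,
                                weighting = config$weighting, keys = keys)

    table2 <- data.frame(enzyme = config$name,
                         highest_loop_overlap = loop_ov[hi],
                         highest_loop_overlap_mode = hi,
                         slowest_mode_ge_0.5 = if (length(ge5)) min(ge5) else NA_integer_,
                         slowest_mode_ge_0.5_overlap = if (length(ge5)) loop_ov[min(ge5)] else NA_real_,
                         modes_ge_0.5 = paste(ge5, collapse = ","),
                         enhancement_factor = enh$enhancement_factor)

    stage <- "collectivity"
    coll <- data.frame(mode = seq_len(p),
                       collectivity = vapply(seq_len(p), function(j)
                         collectivity(anm, j), numeric(1)))

    stage <- "bfactors"
    theo <- mode_square_fluctuations(anm, subset = 1L)
    bexp <- open_c$bfactor
    bcor <- if (stats::sd(bexp) > 0) bfactor_correlation(theo, bexp) else NA_real_

    structure(list(name = config$name, m = ens$m, n_common = nrow(keys),
                   table1 = table1,
                   pca_fractions = data.frame(mode = seq_along(pca$fractions),
                                              fraction = pca$fractions),
                   overlap_profile = rbind(prof_def, prof_pc1),
                   loop_overlaps = loop_overlaps,
                   table2 = table2,
                   mode_window_profile = mw,
                   enhancement = enh,
                   collectivity = coll,
                   bfactor_correlation = bcor,
                   theoretical_bfactors = theo,
                   experimental_bfactors = bexp,
                   anm = anm, pca = pca, deformation = defvec,
                   ensemble = ens, config = config),
              class = "enzyme_report")
  }, loopmodes_error = function(e) {
    stop_lm(sprintf("[%s] stage '%s' failed: %s", config$name, stage,
                    conditionMessage(e)), "pipeline_error")
  })
  if (!is.null(out_dir)) write_enzyme_report(result, out_dir)
  result
}

#' @export
print.enzyme_report <- function(x, ...) {
  cat(sprintf("enzyme_report '%s': %d structures, %d common residues\n",
              x$name, x$m, x$n_common))
  cat(sprintf("  overall RMSD %.2f A | loop RMSD %.2f A | isolated loop %.2f A | tip %.2f A\n",
              x$table1$rmsd_overall[1], x$table1$rmsd_loop[1],
              x$table1$rmsd_isolated_loop[1], x$table1$tip_motion[1]))
  cat(sprintf("  PC1 variance fraction %.2f; highest loop overlap %.2f (mode %d)\n",
              x$pca_fractions$fraction[1], x$table2$highest_loop_overlap,
              x$table2$highest_loop_overlap_mode))
  cat(sprintf("  enhancement factor %.2f; B-factor correlation %s\n",
              x$table2$enhancement_factor,
              ifelse(is.na(x$bfactor_correlation), "NA",
                     sprintf("%.2f", x$bfactor_correlation))))
  invisible(x)
}

#' Write an enzyme report to CSV tables, mode sets and a run log
#'
#' Emits `table1.csv`, `table2.csv`, `pca_fractions.csv`,
#' `overlap_profile.csv`, `loop_overlaps.csv`, `window_profiles.csv`,
#' `collectivity.csv`, `bfactors.csv`, mode-set text files (`anm_modes.txt`,
#' `pca_modes.txt`) and `run_log.txt` recording every parameter and seed.
#'
#' @param report an [run_enzyme_analysis()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_enzyme_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(report$table1, "table1.csv")
  wcsv(report$table2, "table2.csv")
  wcsv(report$pca_fractions, "pca_fractions.csv")
  wcsv(report$overlap_profile, "overlap_profile.csv")
  wcsv(report$loop_overlaps, "loop_overlaps.csv")
  mw <- report$mode_window_profile
  mw$enzyme <- report$name
  seqp <- report$enhancement$profile
  seqp$axis <- "sequence-window"
  wp <- rbind(data.frame(enzyme = report$name, axis = mw$axis, chain = NA,
                         window_start = mw$window_start, value = mw$value,
                         baseline = NA, difference = NA),
              data.frame(enzyme = report$name, axis = seqp$axis,
                         chain = seqp$chain, window_start = seqp$window_start,
                         value = seqp$anm, baseline = seqp$random,
                         difference = seqp$difference))
  wcsv(wp, "window_profiles.csv")
  wcsv(report$collectivity, "collectivity.csv")
  wcsv(data.frame(chain = report$anm$keys$chain, resno = report$anm$keys$resno,
                  theoretical = report$theoretical_bfactors,
                  experimental = report$experimental_bfactors), "bfactors.csv")
  write_mode_set(report$anm, file.path(dir, "anm_modes.txt"))
  write_mode_set(report$pca, file.path(dir, "pca_modes.txt"))
  cfg <- report$config
  writeLines(c(sprintf("enzyme: %s", report$name),
               sprintf("structures: %d", report$m),
               sprintf("common residues: %d", report$n_common),
               sprintf("loop: %s %d-%d", cfg$loop$chain, cfg$loop$start, cfg$loop$end),
               sprintf("anm cutoff: %g A", cfg$anm$cutoff),
               sprintf("anm gamma: %g", cfg$anm$gamma),
               sprintf("soft modes: %d", cfg$anm$n_soft_modes),
               sprintf("weighting: %s", cfg$weighting),
               sprintf("random sets: %d", cfg$random$n_sets),
               sprintf("random seed: %d", cfg$random$seed),
               sprintf("ligand_strip: %s", cfg$ligand_strip)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
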