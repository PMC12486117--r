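# End-to-end orchestration: simulate -> preprocess -> split -> QAOA select ->
# quantum encode -> train -> evaluate (patient-level and site-held-out), with
# every reproducibility artifact written to the run directory, plus the
# one-factor-at-a-time ablation harness over circuit depth L, qubit count Q
# and QAOA layer count p.

#' Default pipeline configuration
#'
#' Nested configuration mirroring the workflow stages. Model hyperparameter
#' defaults are the ablation optima `L = 6`, `Q = 10`, `p = 3`; cohort and
#' optimiser settings are desk-scale.
#'
#' @param seed global seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    synthetic = list(n_patients = 400L, n_img_features = 16L,
                     n_gen_features = 24L, n_informative_img = 3L,
                     n_informative_gen = 3L, n_redundant = 4L,
                     effect_size = 1.5, site_count = 3L, site_shift_sd = 0.3,
                     missing_rate = 0.05, class_balance = 0.5),
    qfs = list(p = 3L, restarts = 3L, maxit = 300L, mode = "exact",
               alpha = 0.25, beta = NULL, n_candidates = 12L),
    qenc = list(Q = 10L, L = 6L, entangler = "ring"),
    fusion = list(h_img = 16L, d_img = 8L, token_size = 8L, d_model = 16L,
                  n_heads = 2L, n_layers = 1L, d_gen = 8L, h_head = 16L),
    train = list(lambda = 0.1, ece_bins = 10L, lr = 0.01, batch_size = 32L,
                 max_epochs = 8L, patience = 4L, early_stop_w = 1),
    evalsplit = list(fractions = c(0.7, 0.15, 0.15), val_fraction = 0.2,
                     held_site = "site1", threshold = 0.5),
    ablation = list(L = c(2L, 6L), Q = c(4L, 10L), p = c(1L, 3L),
                    seeds = 1:5)
  )
}

# deep-merge override entries into a config list
.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML with overrides
#'
#' @param path optional YAML file; absent entries fall back to
#'   [defaultRunConfig()].
#' @param seed global seed (overrides the file).
#' @param overrides named list merged last (use dotted names resolved by the
#'   command-line wrapper).
#' @return resolved configuration list.
#' @export
loadRunConfig <- function(path = NULL, seed = NULL, overrides = list()) {
  cfg <- defaultRunConfig(if (is.null(seed)) 1L else seed)
  if (!is.null(path)) cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  .mergeConfig(cfg, overrides)
}

.logLine <- function(logPath, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
      file = logPath, append = TRUE)
}

.writeMetricsJson <- function(report, path, extra = list()) {
  m <- as.list(metricValues(report))
  obj <- c(m, list(threshold = report@threshold,
                   confusion = as.list(confusionCounts(report)),
                   degenerate = report@degenerate),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the full hybrid radiogenomic pipeline
#'
#' Executes every stage on a synthetic cohort and writes the complete
#' artifact set to `outdir`: the resolved configuration (with content hash)
#' and all seeds, the cohort tables and truth, split indices for both
#' protocols, the QAOA-selected features, the trained checkpoints, per-epoch
#' history, quantum features, metrics JSON and ROC/reliability CSV for both
#' evaluation protocols, example preprocessed patches, and a structured log.
#' Stages whose artifacts already exist for the same configuration hash are
#' skipped, so reruns are idempotent and any stage can be redone by deleting
#' its files.
#'
#' @param config configuration from [loadRunConfig()] / [defaultRunConfig()].
#' @param outdir run directory (created).
#' @return invisibly, a list with the run directory, metrics for both
#'   protocols, and the artifact paths.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = tempfile("run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  logPath <- fp("log.txt")

  cfgPath <- fp("resolved_config.yaml")
  yaml::write_yaml(config, cfgPath)
  hash <- unname(tools::md5sum(cfgPath))
  oldHash <- if (file.exists(fp("config_hash.txt")))
    readLines(fp("config_hash.txt"))[1] else ""
  if (!identical(hash, oldHash)) {
    # stale artifacts from a different configuration must not be reused
    stale <- setdiff(list.files(outdir), c("resolved_config.yaml", "log.txt"))
    unlink(fp(stale), recursive = TRUE)
    writeLines(hash, fp("config_hash.txt"))
  }
  .logLine(logPath, "run start; config hash", hash, "seed", config$seed)
  jsonlite::write_json(
    list(global = config$seed, cohort = config$seed,
         split = config$seed + 1L, qaoa = config$seed + 2L,
         train = config$seed + 3L),
    fp("seeds.json"), auto_unbox = TRUE)

  # stage: simulate ---------------------------------------------------------
  synCfg <- do.call(syntheticConfig, c(config$synthetic,
                                       list(seed = config$seed)))
  cohort <- generateCohort(synCfg)
  if (!file.exists(fp("imaging_features.csv"))) {
    writeCohort(cohort, outdir)
    .logLine(logPath, "simulate: cohort written,", nPatients(cohort),
             "patients")
  } else .logLine(logPath, "simulate: cached")

  # stage: preprocess (example imaging fixtures through the full chain) ----
  if (!file.exists(fp("radiomics_examples.csv"))) {
    rad <- list()
    for (lb in c(0, 1)) {
      gp <- generateImagePatch(lb, size = 32L, bias = TRUE,
                               seed = config$seed + lb)
      corrected <- correctBiasField(imagePatch(gp$patch), order = 2L)
      roi <- extractRoi(corrected, gp$mask, margin = 2L)
      writePatchPng(roi$patch$pixels / max(roi$patch$pixels), roi$mask,
                    outdir, prefix = sprintf("patch_label%d", lb))
      rad[[length(rad) + 1L]] <- c(label = lb,
                                   radiomicDescriptors(roi$patch, roi$mask))
    }
    utils::write.csv(do.call(rbind, rad), fp("radiomics_examples.csv"),
                     row.names = FALSE)
    .logLine(logPath, "preprocess: example patches + radiomics written")
  } else .logLine(logPath, "preprocess: cached")

  # stage: split ------------------------------------------------------------
  spPat <- patientSplit(cohort, config$evalsplit$fractions,
                        seed = config$seed + 1L)
  held <- config$evalsplit$held_site
  if (!held %in% siteIds(cohort)) held <- siteIds(cohort)[1]
  spSite <- siteHoldoutSplit(cohort, held, config$evalsplit$val_fraction,
                             seed = config$seed + 1L)
  jsonlite::write_json(spPat, fp("split_patient.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  jsonlite::write_json(spSite, fp("split_site.json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  .logLine(logPath, "split: patient-level", length(spPat$train), "/",
           length(spPat$val), "/", length(spPat$test),
           "; site-held-out test site", held)

  arch <- fusionArch(
    d_in_img = ncol(imgFeatures(cohort)), n_gen = ncol(genFeatures(cohort)),
    h_img = config$fusion$h_img, d_img = config$fusion$d_img,
    gen = genomicEncoderConfig(token_size = config$fusion$token_size,
                               d_model = config$fusion$d_model,
                               n_heads = config$fusion$n_heads,
                               n_layers = config$fusion$n_layers,
                               d_gen = config$fusion$d_gen,
                               seed = config$seed + 4L),
    vqc = vqcConfig(Q = config$qenc$Q, L = config$qenc$L,
                    entangler = config$qenc$entangler,
                    seed = config$seed + 5L),
    h_head = config$fusion$h_head, seed = config$seed + 6L)
  qcfg <- qaoaConfig(p = config$qfs$p, restarts = config$qfs$restarts,
                     maxit = config$qfs$maxit, seed = config$seed + 2L,
                     mode = config$qfs$mode)
  tcfg <- do.call(trainConfig, c(config$train, list(seed = config$seed + 3L)))

  y <- cohortLabels(cohort)
  names(y) <- patientIds(cohort)
  results <- list()
  for (proto in c("patient", "site")) {
    sp <- if (proto == "patient") spPat else spSite
    ckPath <- fp(sprintf("checkpoint_%s.json", proto))
    metPath <- fp(sprintf("metrics_%s.json", proto))
    if (file.exists(metPath) && file.exists(ckPath)) {
      .logLine(logPath, proto, ": cached")
      results[[proto]] <- jsonlite::read_json(metPath, simplifyVector = TRUE)
      next
    }
    fit <- trainFusion(cohort, sp, arch = arch, train = tcfg, qaoa = qcfg,
                       alpha = config$qfs$alpha, beta = config$qfs$beta,
                       n_candidates = config$qfs$n_candidates)
    # stage: select (artifact)
    jsonlite::write_json(
      list(indices = fit$model@fitted$selIdx, cost = fit$selection$cost,
           provenance = fit$selection$provenance, seed = qcfg$seed,
           config = qcfg, candidates = fit$selection$candidates),
      fp(sprintf("selected_features_%s.json", proto)),
      auto_unbox = TRUE, digits = NA, null = "null")
    # stage: encode (artifact: quantum features under the trained circuit)
    pAll <- predictFusion(fit, cohort)
    ft <- fit$model@fitted
    XgI <- genFeatures(cohort)
    XiS <- sweep(sweep(imgFeatures(cohort), 2L, ft$imgStats$mean, "-"),
                 2L, ft$imgStats$sd, "/")
    XgS <- sweep(sweep(XgI, 2L, ft$genStats$mean, "-"), 2L, ft$genStats$sd,
                 "/")
    XgS[is.na(XgS)] <- 0
    A <- scaleToAngles(cbind(XiS, XgS)[, ft$selIdx, drop = FALSE], ft$scaler)
    Zq <- quantumEmbedBatch(A, fit$model@params[["vqc.theta"]], arch$vqc)
    utils::write.csv(data.frame(patient_id = patientIds(cohort), Zq),
                     fp(sprintf("quantum_features_%s.csv", proto)),
                     row.names = FALSE)
    # stage: train (artifacts)
    saveCheckpoint(fit$model, ckPath)
    utils::write.csv(fit$history,
                     fp(sprintf("history_%s.csv", proto)), row.names = FALSE)
    # stage: evaluate
    pt <- pAll[sp$test]
    rep <- computeMetrics(pt, y[sp$test],
                          threshold = config$evalsplit$threshold,
                          M = tcfg$ece_bins)
    utils::write.csv(rocCurve(pt, y[sp$test]),
                     fp(sprintf("roc_%s.csv", proto)), row.names = FALSE)
    utils::write.csv(reliabilityCurve(pt, y[sp$test], M = tcfg$ece_bins),
                     fp(sprintf("reliability_%s.csv", proto)),
                     row.names = FALSE)
    .writeMetricsJson(rep, metPath,
                      extra = list(split = sp$kind, n_test = length(sp$test),
                                   best_epoch = fit$bestEpoch))
    .logLine(logPath, proto, ": AUC",
             format(metricValues(rep)["AUC"], digits = 4),
             "ECE", format(metricValues(rep)["ECE"], digits = 4))
    results[[proto]] <- jsonlite::read_json(metPath, simplifyVector = TRUE)
  }
  .logLine(logPath, "run complete")
  invisible(list(outdir = outdir, metrics = results,
                 artifacts = list.files(outdir)))
}

#' One-factor-at-a-time ablation harness
#'
#' Sweeps circuit depth `L`, qubit count `Q`, and QAOA layer count `p` one
#' factor at a time (the others held at the configured defaults), repeating
#' each setting over the configured seeds, and writes a summary CSV keyed by
#' `(factor, value, seed)` with accuracy, AUC and ECE on the patient-level
#' test split.
#'
#' @param config configuration list (see [defaultRunConfig()]); the grids and
#'   seeds come from `config$ablation`.
#' @param outdir output directory for `ablation.csv`.
#' @return the summary data.frame, invisibly written to
#'   `outdir/ablation.csv`.
#' @export
runAblation <- function(config = defaultRunConfig(), outdir = tempfile("abl")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- config$ablation
  rows <- list()
  evalOne <- function(L, Q, p, seed) {
    synCfg <- do.call(syntheticConfig, c(config$synthetic, list(seed = seed)))
    cohort <- generateCohort(synCfg)
    sp <- patientSplit(cohort, config$evalsplit$fractions, seed = seed)
    arch <- fusionArch(
      d_in_img = ncol(imgFeatures(cohort)),
      n_gen = ncol(genFeatures(cohort)),
      h_img = config$fusion$h_img, d_img = config$fusion$d_img,
      gen = genomicEncoderConfig(token_size = config$fusion$token_size,
                                 d_model = config$fusion$d_model,
                                 n_heads = config$fusion$n_heads,
                                 n_layers = config$fusion$n_layers,
                                 d_gen = config$fusion$d_gen,
                                 seed = seed + 4L),
      vqc = vqcConfig(Q = Q, L = L, entangler = config$qenc$entangler,
                      seed = seed + 5L),
      h_head = config$fusion$h_head, seed = seed + 6L)
    qcfg <- qaoaConfig(p = p, restarts = config$qfs$restarts,
                       maxit = config$qfs$maxit, seed = seed + 2L,
                       mode = config$qfs$mode)
    tcfg <- do.call(trainConfig, c(config$train, list(seed = seed + 3L)))
    fit <- trainFusion(cohort, sp, arch = arch, train = tcfg, qaoa = qcfg,
                       alpha = config$qfs$alpha, beta = config$qfs$beta,
                       n_candidates = config$qfs$n_candidates)
    y <- cohortLabels(cohort); names(y) <- patientIds(cohort)
    pt <- predictFusion(fit, cohort, sp$test)
    m <- metricValues(computeMetrics(pt, y[sp$test], M = tcfg$ece_bins))
    c(acc = unname(m["ACC"]), auc = unname(m["AUC"]), ece = unname(m["ECE"]))
  }
  defaults <- list(L = config$qenc$L, Q = config$qenc$Q, p = config$qfs$p)
  for (factor in intersect(c("L", "Q", "p"), names(grid))) {
    for (value in grid[[factor]]) {
      for (seed in grid$seeds) {
        setting <- defaults
        setting[[factor]] <- value
        m <- evalOne(setting$L, setting$Q, setting$p, as.integer(seed))
        rows[[length(rows) + 1L]] <- data.frame(
          factor = factor, value = value, seed = seed,
          acc = m["acc"], auc = m["auc"], ece = m["ece"])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(outdir, "ablation.csv"), row.names = FALSE)
  invisible(out)
}
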