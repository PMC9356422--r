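## Desk-scale orchestration of the full experiment: simulate cohort ->
## extract patches -> train 3 seeds -> classify slides -> heatmaps ->
## reliability report.

#' Experiment configuration
#'
#' All knobs of the end-to-end experiment, serializable to a single YAML
#' file; the configuration hash is recorded in every output. The desk
#' profile is sized so the whole experiment (cohort simulation, three
#' training seeds, whole-slide classification and the statistics report)
#' runs in minutes on one CPU: 1200 px slides (a 4 x 4 test grid), 600 px
#' training slides, 25 px pooled CNN inputs and a two-stage residual net.
#' The full profile mirrors the clinical geometry (3600 px slides, 300 px
#' inputs, bottleneck stages) and is provided for completeness, not for
#' desk-scale runs.
#'
#' @param n_patients,specimens_per_patient,class_mix,difficulty,slide_px
#'   cohort parameters (see [generateCohort()]).
#' @param cohort_seed,train_seed seeds for the evaluation cohort and the
#'   training set.
#' @param train_slides_per_class,train_slide_px training-set size and slide
#'   side.
#' @param window_px,train_step_px,test_step_px patch geometry (300/100/300).
#' @param train_fraction slide-level training fraction of the train/val
#'   split (default 0.9).
#' @param input_px,stage_widths,blocks_per_stage,block_type,max_epochs,lr,batch_size
#'   model and optimizer settings (see [modelConfig()]).
#' @param seeds integer(3) distinct training seeds for the ensemble.
#' @param ci_level confidence level for interval estimates (default 0.99).
#' @param heatmap_samples number of cohort slides to render heatmap overlays
#'   for when an output directory is set.
#' @param overlay_alpha heatmap overlay transparency.
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @param profile `"desk"` or `"full"` (label only; the numeric fields
#'   govern).
#' @return A validated `srh_experiment_config` list.
#' @export
experimentConfig <- function(n_patients = 20L, specimens_per_patient = 1L,
                             class_mix = c(0.78, 0.19, 0.03),
                             difficulty = "easy", slide_px = 1200L,
                             cohort_seed = 2025L, train_seed = 4001L,
                             train_slides_per_class = 6L,
                             train_slide_px = 600L,
                             window_px = 300L, train_step_px = 100L,
                             test_step_px = 300L,
                             input_px = 25L, stage_widths = c(8L, 16L),
                             blocks_per_stage = 1L, block_type = "basic",
                             train_fraction = 0.9,
                             max_epochs = 40L, lr = 1e-3, batch_size = 64L,
                             seeds = c(11L, 12L, 13L), ci_level = 0.99,
                             heatmap_samples = 2L, overlay_alpha = 0.5,
                             out_dir = NULL, profile = "desk") {
  if (length(seeds) != 3L || anyDuplicated(seeds))
    stop("'seeds' must be 3 distinct integers", call. = FALSE)
  cfg <- list(n_patients = as.integer(n_patients),
              specimens_per_patient = as.integer(specimens_per_patient),
              class_mix = class_mix, difficulty = difficulty,
              slide_px = as.integer(slide_px),
              cohort_seed = as.integer(cohort_seed),
              train_seed = as.integer(train_seed),
              train_slides_per_class = as.integer(train_slides_per_class),
              train_slide_px = as.integer(train_slide_px),
              window_px = as.integer(window_px),
              train_step_px = as.integer(train_step_px),
              test_step_px = as.integer(test_step_px),
              input_px = as.integer(input_px),
              stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              block_type = block_type,
              train_fraction = train_fraction,
              max_epochs = as.integer(max_epochs), lr = lr,
              batch_size = as.integer(batch_size),
              seeds = as.integer(seeds), ci_level = ci_level,
              heatmap_samples = as.integer(heatmap_samples),
              overlay_alpha = overlay_alpha, out_dir = out_dir,
              profile = profile)
  ## validate the embedded model configuration early
  invisible(modelConfig(stage_widths = cfg$stage_widths,
                        blocks_per_stage = cfg$blocks_per_stage,
                        block_type = cfg$block_type,
                        input_px = cfg$input_px, lr = cfg$lr,
                        batch_size = cfg$batch_size))
  class(cfg) <- c("srh_experiment_config", "list")
  cfg
}

#' @rdname experimentConfig
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))], path)
  invisible(path)
}

#' @rdname experimentConfig
#' @export
readExperimentConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experimentConfig, x)
}

#' @rdname experimentConfig
#' @export
configHash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  objectHash(x)
}

## Build the labeled training patch set: a class-balanced set of synthetic
## slides, each cut into overlapping training windows pooled to the model
## input size.
makeTrainingSet <- function(config) {
  classes <- srhClasses()
  n_per <- config$train_slides_per_class
  labels <- rep(classes, each = n_per)
  drawn <- withSeed(config$train_seed, {
    list(params = lapply(labels, drawTextureParams,
                         difficulty = config$difficulty),
         seeds = sample.int(.Machine$integer.max - 1L, length(labels)))
  })
  grid <- patchGrid(config$train_slide_px, config$train_slide_px,
                    step_px = config$train_step_px,
                    window_px = config$window_px)
  per_slide <- nPatches(grid)
  n_slides <- length(labels)
  x <- array(0, c(config$input_px, config$input_px, 3L,
                  per_slide * n_slides))
  y <- character(per_slide * n_slides)
  slide_id <- character(per_slide * n_slides)
  for (i in seq_len(n_slides)) {
    sl <- generateSlide(labels[i], params = drawn$params[[i]],
                        width_px = config$train_slide_px,
                        height_px = config$train_slide_px,
                        seed = drawn$seeds[i])
    img <- buildSRH(sl)
    idx <- (i - 1L) * per_slide + seq_len(per_slide)
    x[, , , idx] <- patchTensor(img, grid, out_px = config$input_px)
    y[idx] <- labels[i]
    slide_id[idx] <- sprintf("T%03d", i)
  }
  list(x = x, y = y, slide_id = slide_id,
       slide_labels = stats::setNames(labels, sprintf("T%03d",
                                                      seq_len(n_slides))))
}

subsetPatches <- function(set, ids) {
  keep <- set$slide_id %in% ids
  list(x = set$x[, , , keep, drop = FALSE], y = set$y[keep])
}

#' Run the full desk-scale experiment
#'
#' Produces, in order: the evaluation cohort, the training patch set with
#' inverse-frequency class weights and a slide-level stratified split, three
#' models trained from distinct seeds under the validation stopping rule,
#' whole-slide predictions for every cohort slide and model, heatmap overlay
#' PNGs for a sample of slides (when `out_dir` is set), and the complete
#' reliability report: per-class ICC across the three models, Cohen's kappa
#' and percent agreement per model against ground truth, per-class ROC-AUC,
#' Cronbach's alpha across the three areas of each specimen, and Kendall's
#' W. Every artifact is reproducible from the configuration; outputs carry
#' the configuration hash.
#'
#' @param config an `srh_experiment_config` from [experimentConfig()].
#' @param verbose print stage progress.
#' @return A list of class `srh_experiment`; see the elements `cohort`,
#'   `models`, `slide_probs`, `stats`, `agreement`, `config_hash`.
#' @export
runExperiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "srh_experiment_config"))
  hash <- configHash(config)
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("stage 1/5: simulating cohort (%d patients, %s mode)",
      config$n_patients, config$difficulty)
  cohort <- generateCohort(config$n_patients, config$specimens_per_patient,
                           config$class_mix, config$difficulty,
                           seed = config$cohort_seed,
                           slide_px = config$slide_px)
  manifest <- cohortManifest(cohort)
  if (!is.null(out_dir))
    utils::write.csv(cbind(manifest, config_hash = hash),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)

  say("stage 2/5: building training patches (%d slides/class)",
      config$train_slides_per_class)
  tset <- makeTrainingSet(config)
  weights <- classWeights(base::table(tset$y)[srhClasses()])
  split <- splitTrainVal(tset$slide_labels, fraction = config$train_fraction,
                         seed = config$train_seed)
  data <- list(train = subsetPatches(tset, split$train),
               val = subsetPatches(tset, split$val),
               weights = weights)

  say("stage 3/5: training ensemble (seeds %s)",
      paste(config$seeds, collapse = ", "))
  mcfg <- modelConfig(stage_widths = config$stage_widths,
                      blocks_per_stage = config$blocks_per_stage,
                      block_type = config$block_type,
                      input_px = config$input_px, lr = config$lr,
                      batch_size = config$batch_size)
  ens <- retrainEnsemble(mcfg, data, seeds = config$seeds,
                         max_epochs = config$max_epochs)
  models <- ens$models
  train_reports <- lapply(models, function(m) m@trainState)
  if (!is.null(out_dir))
    jsonlite::write_json(
      list(config_hash = hash,
           members = lapply(train_reports, function(ts)
             list(stopped = ts$stopped, epochs = nrow(ts$history),
                  val_accuracy = ts$val_accuracy, val_loss = ts$val_loss))),
      file.path(out_dir, "training_report.json"), auto_unbox = TRUE,
      digits = NA)

  say("stage 4/5: classifying %d cohort slides x %d models",
      nrow(manifest), length(models))
  n_slides <- nrow(manifest)
  grid <- patchGrid(config$slide_px, config$slide_px,
                    step_px = config$test_step_px,
                    window_px = config$window_px)
  slide_probs <- lapply(models, function(m)
    matrix(0, n_slides, 3L, dimnames = list(NULL, srhClasses())))
  final_class <- lapply(models, function(m) character(n_slides))
  n_excluded <- matrix(0L, n_slides, length(models))
  for (i in seq_len(n_slides)) {
    img <- buildSRH(cohortSlide(cohort, i))
    x <- patchTensor(img, grid, out_px = config$input_px)
    for (mi in seq_along(models)) {
      probs <- predictPatches(models[[mi]], x)
      agg <- aggregateSlide(patchPredictions(probs, grid))
      slide_probs[[mi]][i, ] <- agg@P
      final_class[[mi]][i] <- agg@finalClass
      n_excluded[i, mi] <- agg@nExcluded
    }
    if (!is.null(out_dir) && i <= config$heatmap_samples) {
      pp <- patchPredictions(predictPatches(models[[1]], x), grid)
      hm <- probabilityHeatmap(pp, dim(img@rgb)[1:2], grid)
      ov <- overlayHeatmap(img, hm, alpha = config$overlay_alpha)
      writeSlide(ov, file.path(out_dir, sprintf(
        "heatmap_%s_%s.png", manifest$specimen_id[i], manifest$area[i])))
    }
  }

  say("stage 5/5: reliability statistics")
  truth <- manifest$label
  classes <- srhClasses()
  icc <- lapply(stats::setNames(1:3, classes), function(ci)
    iccSingleAbsolute(sapply(slide_probs, function(P) P[, ci]),
                      ci_level = config$ci_level))
  kendall <- lapply(stats::setNames(1:3, classes), function(ci)
    kendallsW(sapply(slide_probs, function(P) P[, ci])))
  model_names <- paste0("cnn", seq_along(models))
  kappa <- vapply(seq_along(models), function(mi)
    cohensKappa(truth, final_class[[mi]])$kappa, numeric(1))
  accuracy <- vapply(seq_along(models), function(mi)
    mean(final_class[[mi]] == truth), numeric(1))
  auc <- lapply(stats::setNames(seq_along(models), model_names),
                function(mi) {
    lapply(stats::setNames(1:3, classes), function(ci) {
      if (length(unique(truth == classes[ci])) < 2L) return(NULL)
      rocAuc(slide_probs[[mi]][, ci], truth == classes[ci],
             ci_level = config$ci_level)
    })
  })
  best <- which.max(kappa)
  spec_ids <- unique(manifest$specimen_id)
  area_tab <- t(vapply(spec_ids, function(s) {
    rows <- which(manifest$specimen_id == s)[order(
      manifest$area[manifest$specimen_id == s])]
    slide_probs[[best]][rows, "tumor"]
  }, numeric(3)))
  alpha <- cronbachAlpha(area_tab)
  area_agree <- mean(vapply(spec_ids, function(s) {
    rows <- manifest$specimen_id == s
    length(unique(final_class[[best]][rows])) == 1L
  }, logical(1)))
  agreement <- agreementReport(stats::setNames(final_class, model_names),
                               truth)

  stats_out <- list(
    icc = icc, kendall = kendall,
    kappa = stats::setNames(kappa, model_names),
    accuracy = stats::setNames(accuracy, model_names),
    auc = auc,
    cronbach_alpha = alpha,
    area_agreement = area_agree,
    best_model = model_names[best],
    all_stopped = !ens$flagged)
  if (!is.null(out_dir)) {
    for (mi in seq_along(models))
      utils::write.csv(
        data.frame(manifest[, c("specimen_id", "area", "label")],
                   slide_probs[[mi]], final = final_class[[mi]]),
        file.path(out_dir, sprintf("predictions_%s.csv", model_names[mi])),
        row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash,
           icc = lapply(icc, function(z) z[c("icc", "lower", "upper")]),
           kappa = as.list(stats_out$kappa),
           accuracy = as.list(stats_out$accuracy),
           cronbach_alpha = alpha$alpha, area_agreement = area_agree),
      file.path(out_dir, "statistics.json"), auto_unbox = TRUE, digits = NA)
    writeExperimentConfig(config, file.path(out_dir, "config.yaml"))
  }
  structure(list(config = config, config_hash = hash, cohort = cohort,
                 weights = weights, split = split, models = models,
                 train_reports = train_reports,
                 slide_probs = slide_probs, final_class = final_class,
                 n_excluded = n_excluded, grid = grid, stats = stats_out,
                 agreement = agreement),
            class = "srh_experiment")
}

#' @export
print.srh_experiment <- function(x, ...) {
  s <- x$stats
  cat("SRH desk-scale experiment (config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  cat(sprintf("  models stopped by criterion: %s\n", s$all_stopped))
  cat(sprintf("  slide accuracy: %s\n",
              paste(sprintf("%.3f", s$accuracy), collapse = " / ")))
  cat(sprintf("  ICC (tumor / non-tumor / low quality): %.3f / %.3f / %.3f\n",
              s$icc$tumor$icc, s$icc$non_tumor$icc, s$icc$low_quality$icc))
  cat(sprintf("  Cronbach alpha across areas (%s): %.3f\n", s$best_model,
              s$cronbach_alpha$alpha))
  invisible(x)
}

#' Recompute the published clinical agreement arithmetic
#'
#' The clinical validation compared three retrained CNNs against a blinded
#' neuropathologist on 402 SRH images (326 tumor, 67 non-tumor, 9 low
#' quality). This helper recomputes the per-class and overall agreement
#' percentages from the published correct-prediction counts and compares
#' them with the published percentages at their printed one-decimal
#' precision. One published cell (model 3, tumor, printed 95.0 percent for
#' 305/326 = 93.6 percent) is inconsistent with its own counts and is flagged
#' rather than reproduced.
#'
#' @return data.frame with columns `model`, `scope`, `correct`, `n`,
#'   `computed_percent`, `published_percent`, `consistent`, `flagged`.
#' @export
#' @examples
#' publishedAgreementCheck()
publishedAgreementCheck <- function() {
  totals <- c(tumor = 326L, non_tumor = 67L, low_quality = 9L)
  correct <- list(cnn1 = c(297L, 46L, 5L),
                  cnn2 = c(298L, 48L, 5L),
                  cnn3 = c(305L, 49L, 6L))
  published_class <- list(cnn1 = c(91.1, 68.7, 55.6),
                          cnn2 = c(91.4, 71.6, 55.6),
                          cnn3 = c(95.0, 73.1, 66.7))
  published_overall <- c(cnn1 = 86.5, cnn2 = 87.3, cnn3 = 89.6)
  flagged_cells <- data.frame(model = "cnn3", scope = "tumor")
  out <- NULL
  for (nm in names(correct)) {
    cc <- correct[[nm]]
    for (ci in 1:3) {
      pct <- 100 * cc[ci] / totals[ci]
      scope <- names(totals)[ci]
      fl <- any(flagged_cells$model == nm & flagged_cells$scope == scope)
      out <- rbind(out, data.frame(
        model = nm, scope = scope, correct = cc[ci], n = totals[ci],
        computed_percent = pct,
        published_percent = published_class[[nm]][ci],
        consistent = abs(pct - published_class[[nm]][ci]) <= 0.1,
        flagged = fl))
    }
    pct <- 100 * sum(cc) / sum(totals)
    out <- rbind(out, data.frame(
      model = nm, scope = "overall", correct = sum(cc), n = sum(totals),
      computed_percent = pct, published_percent = published_overall[[nm]],
      consistent = abs(pct - published_overall[[nm]]) <= 0.1,
      flagged = FALSE))
  }
  rownames(out) <- NULL
  out
}
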