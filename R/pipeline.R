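#' Default run configuration for the end-to-end pipeline
#'
#' Nested blocks configure every stage; \code{\link{validateRunConfig}}
#' rejects unknown keys. The defaults describe a desk-scale run on
#' synthetic phantom cases (reduced 96 x 96 x 32 grids, a slim network)
#' so the whole chain executes on one CPU.
#'
#' @param seed global seed; every stage derives its own stream from it
#' @param out_root artifact root directory
#' @return a \code{runConfig} nested list
#' @export
defaultRunConfig <- function(seed = 1L, out_root = tempfile("glioma_run_")) {
  list(
    seed = as.integer(seed),
    out_root = out_root,
    data = list(n_cases = 5L, jitter = 3, noise_std = 0.04),
    preprocess = list(crop_size = c(96L, 96L), min_brain_fraction = 0.01),
    model = list(base_filters = 8L, encoder_levels = 4L, num_blocks = 1L,
                 num_heads = 4L, embed_dim = 64L, mlp_dim = 128L,
                 patch_size = 1L),
    train = list(lr = 0.07, momentum = 0.9, batch_size = 4L,
                 epochs = 20L, folds = 2L),
    augment = list(shift_fraction = 0.1, flip_prob = 0.5,
                   rotation_max_deg = 20, zoom_max_fraction = 0.2,
                   brightness_max_fraction = 0.2, noise_std = 0.01),
    staple = list(tol = 1e-7, max_iter = 100L),
    xai = list(layer = "OUT", pixels = "predicted"),
    eval = list(hd95_mode = "pooled"))
}

.allowedKeys <- list(
  root = c("seed", "out_root", "data", "preprocess", "model", "train",
          "augment", "staple", "xai", "eval"),
  data = c("n_cases", "jitter", "noise_std"),
  preprocess = c("crop_size", "min_brain_fraction"),
  model = c("base_filters", "encoder_levels", "num_blocks", "num_heads",
            "embed_dim", "mlp_dim", "patch_size"),
  train = c("lr", "momentum", "batch_size", "epochs", "folds"),
  augment = c("shift_fraction", "flip_prob", "rotation_max_deg",
              "zoom_max_fraction", "brightness_max_fraction", "noise_std"),
  staple = c("tol", "max_iter"),
  xai = c("layer", "pixels"),
  eval = c("hd95_mode"))

#' Validate a run configuration
#'
#' Schema check before any work: unknown keys are rejected with their
#' field path; structural invariants (e.g. folds >= 2) are enforced.
#'
#' @param config nested list (e.g. parsed from YAML)
#' @return the config, invisibly, or an error
#' @export
validateRunConfig <- function(config) {
  checkBlock <- function(block, path) {
    unknown <- setdiff(names(block), .allowedKeys[[path]])
    if (length(unknown))
      stop(sprintf("unknown config key(s) at '%s': %s",
                   if (path == "root") "<root>" else path,
                   paste(unknown, collapse = ", ")))
  }
  checkBlock(config, "root")
  for (blk in intersect(names(config), setdiff(names(.allowedKeys), "root")))
    checkBlock(config[[blk]], blk)
  if (!is.null(config$train$folds) && config$train$folds < 2)
    stop("config error at 'train.folds': must be >= 2")
  if (!is.null(config$data$n_cases) && config$data$n_cases < 1)
    stop("config error at 'data.n_cases': must be >= 1")
  invisible(config)
}

.logEvent <- function(out_root, event, ...) {
  line <- jsonlite::toJSON(c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                  event = event), list(...)),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_root, "log.jsonl"),
      append = TRUE)
}

.writeResolvedConfig <- function(config, dir) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.modelCfgFrom <- function(config) {
  m <- config$model
  modelConfig(base_filters = m$base_filters,
              encoder_levels = m$encoder_levels,
              input_size = config$preprocess$crop_size,
              num_blocks = m$num_blocks, num_heads = m$num_heads,
              embed_dim = m$embed_dim, mlp_dim = m$mlp_dim,
              patch_size = m$patch_size)
}

.loadPreproc <- function(out_root) {
  files <- sort(list.files(file.path(out_root, "preproc"),
                           pattern = "\\.rds$", full.names = TRUE))
  pp <- lapply(files, readRDS)
  names(pp) <- sub("\\.rds$", "", basename(files))
  pp
}

#' Run one pipeline step
#'
#' Subcommands: \code{simulate} (phantom cohort), \code{preprocess},
#' \code{train} (all folds), \code{predict} (per-fold validation-case
#' volumes), \code{ensemble} (STAPLE fusion), \code{evaluate} (metric
#' CSV), \code{explain} (saliency + modality ablation). Artifacts land
#' under \code{config$out_root} in deterministic paths, each stage
#' directory holding the resolved config that produced it.
#'
#' @param name subcommand name
#' @param config validated run configuration
#' @return invisible list of produced artifact paths
#' @export
runStep <- function(name, config) {
  validateRunConfig(config)
  out_root <- config$out_root
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  name <- match.arg(name, c("simulate", "preprocess", "train", "predict",
                            "ensemble", "evaluate", "explain"))
  .logEvent(out_root, paste0(name, ":start"), seed = config$seed)
  res <- switch(name,
    simulate = {
      dd <- file.path(out_root, "data")
      spec <- phantomSpec(noise_std = config$data$noise_std)
      dirs <- generatePhantomCohort(config$data$n_cases, dd,
                                    base_spec = spec,
                                    jitter = config$data$jitter,
                                    seed = deriveSeed(config$seed, 1L))
      .writeResolvedConfig(config, dd)
      dirs
    },
    preprocess = {
      pd <- file.path(out_root, "preproc")
      dir.create(pd, showWarnings = FALSE)
      case_dirs <- list.dirs(file.path(out_root, "data"),
                             recursive = FALSE)
      for (cd in case_dirs) {
        cs <- loadCase(cd)
        pp <- preprocessCase(cs,
                             crop_size = config$preprocess$crop_size,
                             min_brain_fraction =
                               config$preprocess$min_brain_fraction)
        saveRDS(pp, file.path(pd, paste0(basename(cd), ".rds")))
      }
      .writeResolvedConfig(config, pd)
      pd
    },
    train = {
      md <- file.path(out_root, "models")
      dir.create(md, showWarnings = FALSE)
      pp <- .loadPreproc(out_root)
      folds <- makeFolds(names(pp), config$train$folds,
                         seed = deriveSeed(config$seed, 2L))
      mcfg <- .modelCfgFrom(config)
      tcfg <- trainConfig(lr = config$train$lr,
                          momentum = config$train$momentum,
                          batch_size = config$train$batch_size,
                          epochs = config$train$epochs,
                          folds = config$train$folds,
                          seed = deriveSeed(config$seed, 3L),
                          augment = do.call(augmentConfig, config$augment),
                          min_brain_fraction =
                            config$preprocess$min_brain_fraction)
      saveRDS(folds, file.path(md, "folds.rds"))
      for (f in seq_along(folds)) {
        tr <- trainFold(f, folds[[f]], pp, mcfg, tcfg)
        saveCheckpoint(tr$model, file.path(md, sprintf("fold_%d.rds", f)))
        write.csv(tr$log, file.path(md, sprintf("fold_%d_log.csv", f)),
                  row.names = FALSE)
        .logEvent(out_root, "train:fold", fold = f,
                  best_val_dice = tr$best_val_dice)
      }
      .writeResolvedConfig(config, md)
      md
    },
    predict = {
      prd <- file.path(out_root, "pred")
      dir.create(prd, showWarnings = FALSE)
      pp <- .loadPreproc(out_root)
      md <- file.path(out_root, "models")
      folds <- readRDS(file.path(md, "folds.rds"))
      for (f in seq_along(folds)) {
        model <- loadCheckpoint(file.path(md, sprintf("fold_%d.rds", f)))
        fd <- file.path(prd, sprintf("fold_%d", f))
        dir.create(fd, showWarnings = FALSE)
        for (id in names(pp)) {
          pv <- predictVolume(model, pp[[id]])
          saveLabelVolume(pv$labels, pv$labels,
                          file.path(fd, paste0(id, ".nii.gz")))
        }
      }
      .writeResolvedConfig(config, prd)
      prd
    },
    ensemble = {
      fd <- file.path(out_root, "fused")
      dir.create(fd, showWarnings = FALSE)
      prd <- file.path(out_root, "pred")
      folds <- list.dirs(prd, recursive = FALSE)
      ids <- sub("\\.nii\\.gz$", "",
                 list.files(folds[1], pattern = "\\.nii\\.gz$"))
      for (id in ids) {
        stack <- lapply(folds, function(f) {
          img <- RNifti::readNifti(file.path(f, paste0(id, ".nii.gz")))
          array(as.integer(img), dim = dim(img))
        })
        fused <- stapleMultilabel(stack, tol = config$staple$tol,
                                  max_iter = config$staple$max_iter)
        lv <- LabelVolume(fused)
        saveLabelVolume(lv, lv, file.path(fd, paste0(id, ".nii.gz")))
      }
      .writeResolvedConfig(config, fd)
      fd
    },
    evaluate = {
      ed <- file.path(out_root, "eval")
      dir.create(ed, showWarnings = FALSE)
      rows <- list()
      data_dirs <- list.dirs(file.path(out_root, "data"),
                             recursive = FALSE)
      truths <- lapply(data_dirs, function(cd) loadCase(cd)$labels)
      names(truths) <- basename(data_dirs)
      sources <- c(list.dirs(file.path(out_root, "pred"),
                             recursive = FALSE),
                   file.path(out_root, "fused"))
      for (src in sources) {
        tag <- basename(src)
        if (tag == "fused") tag <- "ensemble"
        for (id in names(truths)) {
          f <- file.path(src, paste0(id, ".nii.gz"))
          if (!file.exists(f)) next
          img <- RNifti::readNifti(f)
          pred <- array(as.integer(img), dim = dim(img))
          ev <- evaluateRegions(pred, labelArray(truths[[id]]),
                                spacing = truths[[id]]@spacing,
                                hd95_mode = config$eval$hd95_mode)
          ev$case <- id; ev$model <- tag
          rows[[length(rows) + 1]] <- ev
        }
      }
      metrics <- do.call(rbind, rows)
      write.csv(metrics[, c("case", "model", "region", "dsc", "hd95")],
                file.path(ed, "metrics.csv"), row.names = FALSE)
      .writeResolvedConfig(config, ed)
      file.path(ed, "metrics.csv")
    },
    explain = {
      xd <- file.path(out_root, "xai")
      dir.create(xd, showWarnings = FALSE)
      pp <- .loadPreproc(out_root)
      md <- file.path(out_root, "models")
      model <- loadCheckpoint(file.path(md, "fold_1.rds"))
      id <- names(pp)[1]
      truth <- loadCase(list.dirs(file.path(out_root, "data"),
                                  recursive = FALSE)[1])$labels
      ab <- modalityAblation(model, pp[[id]], truth, with_saliency = TRUE)
      write.csv(ab$report, file.path(xd, "ablation.csv"),
                row.names = FALSE)
      for (cls in names(ab$saliency))
        saveSaliency(ab$saliency[[cls]],
                     file.path(xd, sprintf("%s_class%s_OUT.nii.gz", id,
                                           cls)))
      .writeResolvedConfig(config, xd)
      xd
    })
  .logEvent(out_root, paste0(name, ":done"))
  invisible(res)
}

#' Run the full pipeline chain
#'
#' simulate, preprocess, train, predict, ensemble, evaluate, explain —
#' in order. With identical seeds the chain is deterministic: the
#' evaluation CSV is reproduced exactly.
#'
#' @param config run configuration (default \code{\link{defaultRunConfig}})
#' @param steps subset of steps to run, in order
#' @return path of the evaluation CSV if produced, else the last artifact
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        steps = c("simulate", "preprocess", "train",
                                  "predict", "ensemble", "evaluate",
                                  "explain")) {
  res <- NULL
  for (s in steps) res <- runStep(s, config)
  invisible(res)
}
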