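# Shared fixtures. Heavy artifacts (phantom cohort, trained fold models)
# are built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

tinyModelConfig <- function() {
  modelConfig(base_filters = 8L, encoder_levels = 4L,
              input_size = c(96L, 96L), num_blocks = 1L, num_heads = 4L,
              embed_dim = 64L, mlp_dim = 128L)
}

# small cohort on disk, loadable by loadCase()
phantomCohortDir <- function() {
  if (is.null(.fixtures$cohort_dir)) {
    td <- file.path(tempdir(), "gliomaseg_cohort")
    unlink(td, recursive = TRUE)
    generatePhantomCohort(5, td, jitter = 3, seed = 101)
    .fixtures$cohort_dir <- td
  }
  .fixtures$cohort_dir
}

phantomCases <- function() {
  if (is.null(.fixtures$cases)) {
    dirs <- list.dirs(phantomCohortDir(), recursive = FALSE)
    cases <- list(); truths <- list()
    for (d in dirs) {
      cs <- loadCase(d)
      cases[[basename(d)]] <- preprocessCase(cs, crop_size = c(96L, 96L))
      truths[[basename(d)]] <- cs$labels
    }
    .fixtures$cases <- cases
    .fixtures$truths <- truths
  }
  list(cases = .fixtures$cases, truths = .fixtures$truths)
}

# two fold models trained on the phantom cohort (the expensive fixture;
# built once, reused by the learnability / fusion / attribution tests)
trainedFolds <- function() {
  if (is.null(.fixtures$trained)) {
    pc <- phantomCases()
    folds <- makeFolds(names(pc$cases), 2, seed = 1)
    tcfg <- trainConfig(lr = 0.07, epochs = 20, folds = 2, seed = 1,
                        batch_size = 4)
    fits <- lapply(1:2, function(f)
      trainFold(f, folds[[f]], pc$cases, tinyModelConfig(), tcfg))
    .fixtures$trained <- list(fits = fits, folds = folds)
  }
  .fixtures$trained
}
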