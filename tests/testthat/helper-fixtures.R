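# Shared fixtures. Heavy objects are built lazily and cached for the
# whole test session.

fixture_cache <- new.env(parent = emptyenv())

# small model: 6 training / 3 evaluation identities, reduced dictionary
small_model <- function() {
  if (is.null(fixture_cache$small)) {
    train <- lapply(1:6, function(i) sample_identity(8000 + i, "A"))
    ev <- lapply(1:3, function(i) sample_identity(8100 + i, "A"))
    cfg <- model_config(n_prototypes = 60)
    fixture_cache$small <- list(
      model = train_model(train, ev, cfg, seed = 7),
      train = train, eval = ev, config = cfg)
  }
  fixture_cache$small
}

# the full 10-run study battery (trained models + all experiment stats)
study_runs <- function() {
  if (is.null(fixture_cache$study))
    fixture_cache$study <- lapply(0:9, run_study)
  fixture_cache$study
}

# test features of the seed-0 study model on its 10 test identities
study_test_features <- function() {
  if (is.null(fixture_cache$feat0)) {
    r <- study_runs()[[1]]
    base <- (r$seed %% 1000L) * 1000000L
    ids <- lapply(1:10, function(i) sample_identity(base + 400000 + i, "A"))
    sw <- facepatches:::render_sweep(ids, size = r$model_A$config$size_px)
    fixture_cache$feat0 <- c(extract_features(r$model_A, sw$images),
                             list(provenance = sw$provenance))
  }
  fixture_cache$feat0
}

# one-sided rank-sum p-value (x > y)
rs_p <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                      exact = FALSE))$p.value
}
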