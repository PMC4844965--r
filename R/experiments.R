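#' Experiment configuration
#'
#' Configuration for the bundled experiment runners. The defaults are the
#' reduced desk-scale setting: 20 training, 10 evaluation and 20 test
#' identities, 200 prototypes, 64 px images, 10 independent runs
#' (seeds 0-9).
#'
#' @param experiment One of `"geometry"`, `"canonical"`, `"inversion"`,
#'   `"rotation"`, `"composite"`, `"ore"`.
#' @param seeds Integer vector, one entry per independent run.
#' @param n_train,n_eval,n_test Identity counts.
#' @param model Model configuration ([model_config()]).
#' @param out_dir Output directory (tables, figures, manifest).
#' @param population Training population for the single-population
#'   experiments.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, seeds = 0:9, n_train = 20,
                              n_eval = 10, n_test = 20,
                              model = model_config(), out_dir = NULL,
                              population = "A") {
  valid <- c("geometry", "canonical", "inversion", "rotation",
             "composite", "ore")
  if (!experiment %in% valid)
    stop("unknown experiment '", experiment, "'; valid names are: ",
         paste(valid, collapse = ", "))
  structure(list(experiment = experiment, seeds = seeds,
                 n_train = n_train, n_eval = n_eval, n_test = n_test,
                 model = model, out_dir = out_dir,
                 population = population),
            class = "experiment_config")
}

# identity sets for one run; sub-seeds keep train/eval/test disjoint
run_identities <- function(cfg, seed, population = cfg$population) {
  base <- (seed %% 1000L) * 1000000L
  list(train = lapply(seq_len(cfg$n_train), function(i)
         sample_identity(base + 1000 + i, population)),
       eval = lapply(seq_len(cfg$n_eval), function(i)
         sample_identity(base + 200000 + i, population)),
       test = lapply(seq_len(cfg$n_test), function(i)
         sample_identity(base + 400000 + i, population)))
}

# train (or reuse) the model for one run
run_model <- function(cfg, seed, population = cfg$population) {
  ids <- run_identities(cfg, seed, population)
  m <- train_model(ids$train, ids$eval, cfg$model, seed = seed + 1)
  list(model = m, ids = ids)
}

#' Build the composite-face stimulus set
#'
#' Ten top-half identities, each combined with five different bottom
#' halves, in aligned and misaligned conditions (frontal view): 50 images
#' per condition.
#'
#' @param tops List of at least 10 `face_identity` objects; the first 10
#'   provide top halves, bottoms are drawn cyclically from the same set.
#' @param size Image side in pixels.
#' @return A list with `aligned` and `misaligned` image lists and `top`
#'   (top-half identity index per image).
#' @export
composite_set <- function(tops, size = 64) {
  n_top <- min(10, length(tops))
  build <- function(aligned) {
    imgs <- list(); top_lab <- integer(0)
    for (i in seq_len(n_top)) {
      for (k in 1:5) {
        bot <- tops[[(i + k - 1) %% length(tops) + 1]]
        imgs <- c(imgs, list(make_composite(tops[[i]], bot,
                                            aligned = aligned,
                                            size = size)))
        top_lab <- c(top_lab, i)
      }
    }
    list(images = imgs, top = top_lab)
  }
  al <- build(TRUE); mis <- build(FALSE)
  list(aligned = al$images, misaligned = mis$images, top = al$top)
}

# similarity matrices + indices for the three last layers, one run
run_geometry <- function(cfg, seed) {
  rm <- run_model(cfg, seed)
  sw <- render_sweep(rm$ids$test, size = cfg$model$size_px)
  f <- extract_features(rm$model, sw$images)
  rows <- lapply(names(f), function(ly) {
    sm <- similarity_matrix(f[[ly]], block = cfg$n_test)
    data.frame(seed = seed, layer = ly, vsi = vsi(sm), visi = visi(sm))
  })
  list(table = do.call(rbind, rows), features = f,
       provenance = sw$provenance, model = rm$model)
}

run_canonical <- function(cfg, seed) {
  rm <- run_model(cfg, seed)
  sw <- render_sweep(rm$ids$test, size = cfg$model$size_px)
  f <- extract_features(rm$model, sw$images, layers = c("C2", "ISL"))
  ids <- sw$provenance$id_label; vs <- sw$provenance$yaw_deg
  d_isl <- doi(f$ISL, ids, vs)
  d_c2 <- doi(f$C2, ids, vs)
  cvm <- cross_view_matrix(f$ISL, ids, vs, cost = cfg$model$svm_cost)
  list(doi = data.frame(seed = seed, view = yaw_grid(),
                        doi_isl = d_isl$doi, doi_c2 = d_c2$doi),
       accuracy_matrix = cvm,
       tuning_isl = d_isl$tuning, tuning_c2 = d_c2$tuning)
}

run_inversion <- function(cfg, seed) {
  rm <- run_model(cfg, seed)
  up <- render_sweep(rm$ids$test, size = cfg$model$size_px)
  inv <- render_sweep(rm$ids$test, size = cfg$model$size_px,
                      inverted = TRUE)
  fu <- extract_features(rm$model, up$images, layers = c("C2", "ISL"))
  fi <- extract_features(rm$model, inv$images, layers = c("C2", "ISL"))
  ids <- up$provenance$id_label; vs <- up$provenance$yaw_deg
  list(isl = inversion_contrast(fu$ISL, fi$ISL, ids, vs),
       c2 = inversion_contrast(fu$C2, fi$C2, ids, vs))
}

run_rotation <- function(cfg, seed, rotations = seq(0, 180, by = 5)) {
  rm <- run_model(cfg, seed)
  by_rot <- lapply(rotations, function(a) {
    imgs <- lapply(rm$ids$test, function(id)
      render_face(id, yaw = 0, inplane = a, aperture = TRUE,
                  size = cfg$model$size_px))
    extract_features(rm$model, imgs, layers = c("C2", "ISL"))
  })
  names(by_rot) <- rotations
  list(ISL = lapply(by_rot, `[[`, "ISL"), C2 = lapply(by_rot, `[[`, "C2"))
}

run_composite <- function(cfg, seed) {
  rm <- run_model(cfg, seed)
  cs <- composite_set(rm$ids$test, size = cfg$model$size_px)
  fa <- extract_features(rm$model, cs$aligned, layers = c("C2", "ISL"))
  fm <- extract_features(rm$model, cs$misaligned, layers = c("C2", "ISL"))
  list(isl = composite_hit_rate(fa$ISL, fm$ISL, cs$top),
       c2 = composite_hit_rate(fa$C2, fm$C2, cs$top))
}

run_ore <- function(cfg, seed, views = c(-90, -60, -30, 0, 30, 60, 90)) {
  mA <- run_model(cfg, seed, population = "A")
  mB <- run_model(cfg, seed, population = "B")
  n_ore <- min(cfg$n_test, 10)
  base <- (seed %% 1000L) * 1000000L
  tsA <- render_sweep(lapply(seq_len(n_ore), function(i)
    sample_identity(base + 600000 + i, "A")),
    size = cfg$model$size_px, yaws = views)
  tsB <- render_sweep(lapply(seq_len(n_ore), function(i)
    sample_identity(base + 700000 + i, "B")),
    size = cfg$model$size_px, yaws = views)
  score <- function(m, ts) {
    f <- extract_features(m, ts$images, layers = "ISL")$ISL
    acc <- cross_view_identification(
      f, ts$provenance$id_label, ts$provenance$yaw_deg,
      train_views = c(-90, -30, 30, 90), test_views = c(-60, 0, 60),
      cost = cfg$model$svm_cost)
    dis <- mean(unlist(lapply(views, function(v)
      as.vector(stats::dist(f[ts$provenance$yaw_deg == v, ,
                              drop = FALSE])))))
    c(accuracy = acc, dissimilarity = dis)
  }
  rbind(data.frame(seed = seed, trained_on = "A", tested_on = "A",
                   t(score(mA$model, tsA))),
        data.frame(seed = seed, trained_on = "A", tested_on = "B",
                   t(score(mA$model, tsB))),
        data.frame(seed = seed, trained_on = "B", tested_on = "B",
                   t(score(mB$model, tsB))),
        data.frame(seed = seed, trained_on = "B", tested_on = "A",
                   t(score(mB$model, tsA))))
}

#' Run one of the bundled experiments
#'
#' Generates the stimuli, trains one model per seed, extracts features,
#' computes the experiment's statistics and (when `out_dir` is set)
#' writes result tables, a run manifest and simple figure files.
#' Re-running with an identical configuration reproduces identical
#' tables.
#'
#' @param config An [experiment_config()].
#' @return A list with per-seed results and a summary table; invisibly
#'   written to `config$out_dir` when given.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  runner <- switch(config$experiment,
                   geometry = run_geometry, canonical = run_canonical,
                   inversion = run_inversion, rotation = run_rotation,
                   composite = run_composite, ore = run_ore)
  runs <- lapply(config$seeds, function(s) runner(config, s))
  names(runs) <- paste0("seed", config$seeds)
  summary <- summarise_experiment(config, runs)
  out <- list(experiment = config$experiment, runs = runs,
              summary = summary, config = config)
  if (!is.null(config$out_dir)) write_experiment(out, config)
  out
}

summarise_experiment <- function(config, runs) {
  switch(config$experiment,
    geometry = {
      tab <- do.call(rbind, lapply(runs, `[[`, "table"))
      stats::aggregate(cbind(vsi, visi) ~ layer, tab, mean)
    },
    canonical = {
      tab <- do.call(rbind, lapply(runs, `[[`, "doi"))
      data.frame(mean_doi_isl = mean(tab$doi_isl),
                 mean_doi_c2 = mean(tab$doi_c2))
    },
    inversion = {
      do.call(rbind, lapply(names(runs), function(nm) {
        r <- runs[[nm]]
        data.frame(run = nm,
                   visi_isl_upright = r$isl$visi["upright"],
                   visi_isl_inverted = r$isl$visi["inverted"],
                   sig_views_isl = sum(r$isl$per_view$p < 0.05),
                   sig_views_c2 = sum(r$c2$per_view$p < 0.05))
      }))
    },
    rotation = {
      discriminability_score(lapply(runs, `[[`, "ISL"))
    },
    composite = {
      do.call(rbind, lapply(names(runs), function(nm) {
        cv <- runs[[nm]]$isl$curves
        data.frame(run = nm, threshold = cv$threshold,
                   isl_aligned = cv$aligned,
                   isl_misaligned = cv$misaligned,
                   c2_aligned = runs[[nm]]$c2$curves$aligned,
                   c2_misaligned = runs[[nm]]$c2$curves$misaligned)
      }))
    },
    ore = do.call(rbind, runs))
}

write_experiment <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$out_dir, config$experiment)
  utils::write.table(out$summary, paste0(base, "_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(experiment = config$experiment, seeds = config$seeds,
                   n_train = config$n_train, n_eval = config$n_eval,
                   n_test = config$n_test,
                   model = config$model[setdiff(names(config$model),
                                                "bank_config")],
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paste0(base, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (config$experiment == "geometry") {
    f1 <- out$runs[[1]]$features
    for (ly in names(f1)) {
      sm <- similarity_matrix(f1[[ly]], block = config$n_test)
      png::writePNG((unclass(sm) + 1) / 2,
                    paste0(base, "_similarity_", ly, ".png"))
    }
  }
  invisible(out)
}

#' Desk-scale study configuration for the full experiment battery
#'
#' @param n_train,n_eval Identities for training and for the
#'   evaluation-gated learning phase.
#' @param n_test Test identities for the geometry / canonical-view /
#'   inversion analyses (rendered at all 37 views).
#' @param n_ore Test identities per population for the other-race
#'   analysis (rendered at the 7-view grid).
#' @param model Model configuration.
#' @param parts Which experiment blocks to run.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_train = 20, n_eval = 10, n_test = 10,
                         n_ore = 20, model = model_config(),
                         parts = c("geometry", "canonical", "inversion",
                                   "composite", "ore")) {
  structure(list(n_train = n_train, n_eval = n_eval, n_test = n_test,
                 n_ore = n_ore, model = model, parts = parts),
            class = "study_config")
}

#' Run the full experiment battery for one seed
#'
#' Trains one model on population A (and, when the other-race block is
#' requested, a second on population B), then computes the
#' representational-geometry indices, degree of invariance, cross-view
#' identification matrix, inversion contrasts, composite-face hit-rate
#' curves and other-race statistics, sharing the trained models across
#' blocks.
#'
#' @param seed Integer seed for this run (controls identity sampling,
#'   prototype learning, schedules and view splits).
#' @param config A [study_config()].
#' @return A named list of per-block results plus the trained models and
#'   their growth ledgers.
#' @export
run_study <- function(seed, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  base <- (seed %% 1000L) * 1000000L
  mk_ids <- function(off, n, pop) lapply(seq_len(n), function(i)
    sample_identity(base + off + i, pop))
  ids_train <- mk_ids(1000, config$n_train, "A")
  ids_eval <- mk_ids(200000, config$n_eval, "A")
  ids_test <- mk_ids(400000, config$n_test, "A")
  modelA <- train_model(ids_train, ids_eval, config$model, seed = seed + 1)
  out <- list(seed = seed, model_A = modelA, ledger_A = modelA$ledger)
  px <- config$model$size_px

  need_test <- any(c("geometry", "canonical", "inversion") %in%
                     config$parts)
  if (need_test) {
    sw <- render_sweep(ids_test, size = px)
    f <- extract_features(modelA, sw$images)
    ids <- sw$provenance$id_label; vs <- sw$provenance$yaw_deg
    if ("geometry" %in% config$parts) {
      out$geometry <- do.call(rbind, lapply(names(f), function(ly) {
        sm <- similarity_matrix(f[[ly]], block = config$n_test)
        data.frame(seed = seed, layer = ly, vsi = vsi(sm),
                   visi = visi(sm))
      }))
    }
    if ("canonical" %in% config$parts) {
      d_isl <- doi(f$ISL, ids, vs)
      d_c2 <- doi(f$C2, ids, vs)
      out$canonical <- list(
        doi = data.frame(seed = seed, view = yaw_grid(),
                         isl = d_isl$doi, c2 = d_c2$doi),
        row_mean_accuracy = rowMeans(
          cross_view_matrix(f$ISL, ids, vs,
                            cost = config$model$svm_cost)))
    }
    if ("inversion" %in% config$parts) {
      inv <- render_sweep(ids_test, size = px, inverted = TRUE)
      fi <- extract_features(modelA, inv$images,
                             layers = c("C2", "ISL"))
      out$inversion <- list(
        isl = inversion_contrast(f$ISL, fi$ISL, ids, vs),
        c2 = inversion_contrast(f$C2, fi$C2, ids, vs))
    }
  }
  if ("composite" %in% config$parts) {
    cs <- composite_set(ids_test, size = px)
    fa <- extract_features(modelA, cs$aligned, layers = c("C2", "ISL"))
    fm <- extract_features(modelA, cs$misaligned,
                           layers = c("C2", "ISL"))
    out$composite <- list(
      isl = composite_hit_rate(fa$ISL, fm$ISL, cs$top),
      c2 = composite_hit_rate(fa$C2, fm$C2, cs$top))
  }
  if ("ore" %in% config$parts) {
    ids_train_B <- mk_ids(101000, config$n_train, "B")
    ids_eval_B <- mk_ids(300000, config$n_eval, "B")
    modelB <- train_model(ids_train_B, ids_eval_B, config$model,
                          seed = seed + 1)
    out$model_B <- modelB
    views <- c(-90, -60, -30, 0, 30, 60, 90)
    tsA <- render_sweep(mk_ids(600000, config$n_ore, "A"), size = px,
                        yaws = views)
    tsB <- render_sweep(mk_ids(700000, config$n_ore, "B"), size = px,
                        yaws = views)
    score <- function(m, ts) {
      fo <- extract_features(m, ts$images, layers = "ISL")$ISL
      acc <- cross_view_identification(
        fo, ts$provenance$id_label, ts$provenance$yaw_deg,
        train_views = c(-90, -30, 30, 90), test_views = c(-60, 0, 60),
        cost = config$model$svm_cost)
      dis <- mean(unlist(lapply(views, function(v)
        as.vector(stats::dist(fo[ts$provenance$yaw_deg == v, ,
                                 drop = FALSE])))))
      c(accuracy = acc, dissimilarity = dis)
    }
    out$ore <- rbind(
      data.frame(seed = seed, trained_on = "A", tested_on = "A",
                 t(score(modelA, tsA))),
      data.frame(seed = seed, trained_on = "A", tested_on = "B",
                 t(score(modelA, tsB))),
      data.frame(seed = seed, trained_on = "B", tested_on = "B",
                 t(score(modelB, tsB))),
      data.frame(seed = seed, trained_on = "B", tested_on = "A",
                 t(score(modelB, tsA))))
  }
  out
}
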