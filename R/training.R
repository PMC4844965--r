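#' Model configuration
#'
#' Collects the tunable parameters of the full hierarchy. Defaults are
#' the desk-scale experiment settings used throughout the package's test
#' experiments; `n_prototypes = 1000` reproduces the standard full-scale
#' S2 dictionary.
#'
#' @param size_px Image side in pixels.
#' @param n_prototypes Number of S2 prototypes.
#' @param proto_sizes Prototype side lengths on the C1 grid.
#' @param gamma S2 tuning sharpness.
#' @param sigma VSL Gaussian width.
#' @param alpha VSL trace coefficient.
#' @param rho Vigilance threshold.
#' @param max_coeff,trace_coeff ISL mixing coefficients.
#' @param accept_threshold Minimum VISI improvement on the evaluation set
#'   required to keep an identity's newly grown units (0 = keep iff VISI
#'   strictly increases).
#' @param gate_on_accuracy If `TRUE`, acceptance additionally requires
#'   that evaluation SVM accuracy does not decrease.
#' @param svm_cost Regularisation constant of the linear SVM used for all
#'   identification accuracies.
#' @param bank_config Gabor bank configuration.
#' @return A list of class `model_config`.
#' @export
model_config <- function(size_px = 64, n_prototypes = 200,
                         proto_sizes = c(4, 8, 12, 16), gamma = 1,
                         sigma = 0.5, alpha = 0.3, rho = 0.9,
                         max_coeff = 0.7, trace_coeff = 0.3,
                         accept_threshold = 0, gate_on_accuracy = FALSE,
                         svm_cost = 1,
                         bank_config = gabor_bank_config()) {
  structure(as.list(environment()), class = "model_config")
}

#' Build a sequential presentation schedule
#'
#' One block per identity: the first view is chosen uniformly at random,
#' the remaining 36 follow in 5-degree order with wrap-around at the
#' profile (after +90 comes -90), and a blank marker separates identities.
#'
#' @param identities List of `face_identity` objects (or a character
#'   vector of labels).
#' @param seed Integer seed for the random start views.
#' @param available Optional data frame with columns `id_label` and
#'   `yaw_deg` restricting the views on disk; every identity must have
#'   the full 37-view grid.
#' @return A tibble with columns `id_label`, `yaw_deg`, `blank`; blank
#'   separator rows have `blank = TRUE`.
#' @export
build_schedule <- function(identities, seed = 1, available = NULL) {
  labels <- unname(vapply(identities, function(x)
    if (is.character(x)) x else x$id_label, character(1)))
  yaws <- yaw_grid()
  if (!is.null(available)) {
    for (lb in labels) {
      have <- sort(unique(available$yaw_deg[available$id_label == lb]))
      if (!all(yaws %in% have))
        stop("identity ", lb, " is missing views: ",
             paste(setdiff(yaws, have), collapse = ", "))
    }
  }
  starts <- withr::with_seed(as.integer(seed),
                             sample.int(length(yaws), length(labels),
                                        replace = TRUE))
  rows <- list()
  for (i in seq_along(labels)) {
    idx <- ((starts[i] - 1 + 0:(length(yaws) - 1)) %% length(yaws)) + 1
    rows[[2 * i - 1]] <- data.frame(id_label = labels[i],
                                    yaw_deg = yaws[idx], blank = FALSE)
    rows[[2 * i]] <- data.frame(id_label = NA_character_,
                                yaw_deg = NA_real_, blank = TRUE)
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Normalise a training/evaluation input to (images, provenance).
# Accepts a list of face_identity objects (rendered on the fly at all 37
# views), or a ready image set: a list with `images` and a `provenance`
# data frame carrying id_label and yaw_deg (e.g. photographs loaded from
# a make_dataset()-style manifest via load_dataset()).
as_face_set <- function(x, size_px) {
  if (is.list(x) && !is.null(x$images) && !is.null(x$provenance)) {
    stopifnot(all(c("id_label", "yaw_deg") %in% names(x$provenance)),
              length(x$images) == nrow(x$provenance))
    return(x)
  }
  if (length(x) > 0 && inherits(x[[1]], "face_identity"))
    return(render_sweep(x, size = size_px))
  stop("expected a list of face_identity objects or an image set with ",
       "$images and $provenance")
}

face_set_labels <- function(x) {
  if (is.list(x) && !is.null(x$provenance))
    unique(x$provenance$id_label)
  else vapply(x, `[[`, character(1), "id_label")
}

#' Load a rendered dataset from its manifest
#'
#' Reads the images written by [make_dataset()] (or any directory of
#' grayscale PNGs with a compatible delimited manifest) back into the
#' image-set form accepted by [train_model()] and [evaluate_model()].
#'
#' @param manifest Path to the manifest file (tab-delimited, with at
#'   least `path`, `id_label`, `yaw_deg` columns).
#' @return A list with `images` and `provenance`.
#' @export
load_dataset <- function(manifest) {
  man <- utils::read.delim(manifest)
  dir <- dirname(manifest)
  imgs <- lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(dir, basename(p))
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  list(images = imgs, provenance = man)
}

#' Train the full model
#'
#' Runs the sequential learning protocol: S2 prototypes are sampled from
#' the training images, then the presentation schedule is played through
#' the stack with trace updates and vigilance-gated VSL growth. After
#' each identity that created a new ISL unit the model is scored on the
#' evaluation set (VISI and cross-view SVM accuracy); if VISI does not
#' improve by more than `accept_threshold` the identity's new units are
#' rolled back. Parameters are frozen when the schedule ends.
#'
#' @param train_ids,eval_ids Disjoint identity sets, each given either
#'   as a list of `face_identity` objects (rendered on the fly at all 37
#'   views) or as an image set (`$images` plus `$provenance` with
#'   id_label and yaw_deg, e.g. from [load_dataset()]); every identity
#'   must cover the full 37-view grid.
#' @param config A [model_config()].
#' @param seed Integer seed controlling prototype sampling, schedule
#'   start views and the evaluation train/test view split.
#' @return A list of class `face_model` with the trained populations, the
#'   prototype dictionary, the configuration and a growth ledger (tibble:
#'   one row per training identity with units added, evaluation VISI
#'   before/after, SVM accuracy and the acceptance decision).
#' @export
train_model <- function(train_ids, eval_ids, config = model_config(),
                        seed = 1) {
  if (length(train_ids) == 0) stop("training set is empty")
  train_sw <- as_face_set(train_ids, config$size_px)
  eval_sw <- as_face_set(eval_ids, config$size_px)
  tl <- unique(train_sw$provenance$id_label)
  el <- unique(eval_sw$provenance$id_label)
  if (length(intersect(tl, el)) > 0)
    stop("train and eval identity sets must be disjoint")
  bank <- gabor_bank(config$bank_config)

  dict <- learn_prototypes(train_sw$images, n = config$n_prototypes,
                           sizes = config$proto_sizes,
                           seed = seed * 100 + 1, bank = bank,
                           gamma = config$gamma)
  c2_train <- extract_c2(train_sw$images, dict, bank)
  key <- paste(train_sw$provenance$id_label, train_sw$provenance$yaw_deg)
  rownames(c2_train) <- key

  c2_eval <- extract_c2(eval_sw$images, dict, bank)
  eval_prov <- eval_sw$provenance

  vsl <- vsl_population(ncol(c2_train), sigma = config$sigma,
                        alpha = config$alpha, rho = config$rho)
  isl <- isl_population(config$max_coeff, config$trace_coeff)
  schedule <- build_schedule(tl, seed = seed * 100 + 2,
                             available = train_sw$provenance)

  score <- function(vsl, isl) {
    if (length(isl$incoming) < 2)
      return(list(visi = NA_real_, acc = NA_real_))
    lf <- layer_features(c2_eval, vsl, isl)
    sm <- similarity_matrix(lf$ISL, block = length(el))
    acc <- svm_view_split_accuracy(lf$ISL, eval_prov,
                                   seed = seed * 100 + 3,
                                   cost = config$svm_cost)
    list(visi = visi(sm), acc = acc)
  }

  ledger <- list()
  visi_ref <- -Inf   # best accepted VISI so far (baseline: empty model)
  acc_ref <- -Inf
  blocks <- split(seq_len(nrow(schedule)), cumsum(schedule$blank) -
                    schedule$blank)
  n_id <- 0
  for (bi in blocks) {
    rows <- schedule[bi, ]
    pres <- rows[!rows$blank, ]
    if (nrow(pres) == 0) next
    n_id <- n_id + 1
    snap_vsl <- vsl; snap_isl <- isl
    n_vsl0 <- nrow(vsl$centers); n_isl0 <- length(isl$incoming)
    for (r in seq_len(nrow(pres))) {
      c2 <- c2_train[paste(pres$id_label[r], pres$yaw_deg[r]), ]
      gr <- vsl_grow(vsl, c2)
      vsl <- gr$population
      if (!is.na(gr$new_unit)) {
        wr <- wire_to_winner(isl, gr$new_unit)
        isl <- wr$population
      }
      vr <- vsl_respond(vsl, c2, update_trace = TRUE)
      vsl <- vr$population
      ir <- isl_respond(isl, vr$activation, update_trace = TRUE)
      isl <- ir$population
    }
    rt <- reset_traces(vsl, isl)   # blank separator
    vsl <- rt$vsl; isl <- rt$isl
    new_isl <- length(isl$incoming) - n_isl0
    if (new_isl > 0) {
      sc <- score(vsl, isl)
      prev_ref <- visi_ref
      accept <- is.na(sc$visi) ||
        sc$visi > visi_ref + config$accept_threshold
      if (config$gate_on_accuracy && !is.na(sc$acc) && is.finite(acc_ref))
        accept <- accept && sc$acc >= acc_ref
      if (accept) {
        if (!is.na(sc$visi)) visi_ref <- sc$visi
        if (!is.na(sc$acc)) acc_ref <- sc$acc
      } else {
        vsl <- snap_vsl; isl <- snap_isl
      }
      ledger[[n_id]] <- data.frame(
        id_label = pres$id_label[1],
        n_vsl_added = nrow(vsl$centers) - n_vsl0,
        isl_index = if (accept) length(isl$incoming) else NA_integer_,
        visi_before = if (is.finite(prev_ref)) prev_ref else NA_real_,
        visi_after = sc$visi, svm_accuracy = sc$acc, accepted = accept)
    } else {
      ledger[[n_id]] <- data.frame(
        id_label = pres$id_label[1],
        n_vsl_added = nrow(vsl$centers) - n_vsl0,
        isl_index = NA_integer_, visi_before = NA_real_,
        visi_after = NA_real_, svm_accuracy = NA_real_, accepted = TRUE)
    }
  }
  ledger <- tibble::as_tibble(do.call(rbind, ledger))
  structure(list(bank = bank, dict = dict, vsl = vsl, isl = isl,
                 config = config, seed = seed, ledger = ledger,
                 train_labels = tl),
            class = "face_model")
}

#' @export
print.face_model <- function(x, ...) {
  cat("<face_model>", nrow(x$vsl$centers), "VSL units,",
      length(x$isl$incoming), "ISL units,",
      length(x$dict$prototypes), "prototypes\n")
  invisible(x)
}

#' Extract layer features for a set of images
#'
#' Feed-forward inference with traces held at zero (the frozen,
#' evaluation-phase regime).
#'
#' @param model A trained `face_model`.
#' @param images List of grayscale matrices.
#' @param layers Which layers to return.
#' @return Named list of feature matrices (one row per image).
#' @export
extract_features <- function(model, images,
                             layers = c("C2", "VSL", "ISL")) {
  c2 <- extract_c2(images, model$dict, model$bank)
  out <- list()
  if ("C2" %in% layers) out$C2 <- c2
  if (any(c("VSL", "ISL") %in% layers)) {
    lf <- layer_features(c2, model$vsl, model$isl)
    if ("VSL" %in% layers) out$VSL <- lf$VSL
    if ("ISL" %in% layers) out$ISL <- lf$ISL
  }
  out
}

# multiclass linear SVM accuracy with a random 18/19 view split
svm_view_split_accuracy <- function(features, provenance, seed = 1,
                                    cost = 1) {
  views <- sort(unique(provenance$yaw_deg))
  tr_views <- withr::with_seed(as.integer(seed),
                               sample(views, 18))
  tr <- provenance$yaw_deg %in% tr_views
  svm_accuracy(features[tr, , drop = FALSE], provenance$id_label[tr],
               features[!tr, , drop = FALSE], provenance$id_label[!tr],
               cost = cost)
}

# linear SVM train/test accuracy (the package's single classifier route)
svm_accuracy <- function(xtr, ytr, xte, yte, cost = 1) {
  keep <- apply(xtr, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) return(1 / length(unique(ytr)))
  fit <- e1071::svm(xtr[, keep, drop = FALSE], factor(ytr),
                    kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, xte[, keep, drop = FALSE])
  mean(as.character(pred) == yte)
}

#' Evaluate a trained model on an identity set
#'
#' Renders all 37 views of the evaluation identities, extracts ISL
#' features, and reports the view-invariant identity selectivity index
#' plus the accuracy of a linear SVM trained on a random 18-view split
#' and tested on the remaining 19 views.
#'
#' @param model A `face_model`.
#' @param eval_ids At least two identities, as `face_identity` objects
#'   or an image set covering all 37 views.
#' @param seed Seed for the view split.
#' @return A list with `visi` and `accuracy`.
#' @export
evaluate_model <- function(model, eval_ids, seed = 1) {
  sw <- as_face_set(eval_ids, model$config$size_px)
  n_id <- length(unique(sw$provenance$id_label))
  if (n_id < 2) stop("need at least 2 evaluation identities")
  if (!all(yaw_grid() %in% sw$provenance$yaw_deg))
    stop("evaluation set must cover all 37 views")
  f <- extract_features(model, sw$images, layers = "ISL")$ISL
  sm <- similarity_matrix(f, block = n_id)
  list(visi = visi(sm),
       accuracy = svm_view_split_accuracy(f, sw$provenance, seed = seed,
                                          cost = model$config$svm_cost))
}

#' Vigilance grid search
#'
#' Trains one model per candidate vigilance value and scores each on the
#' evaluation set; the value maximising evaluation VISI is reported.
#'
#' @param train_ids,eval_ids Disjoint identity lists.
#' @param grid Candidate `rho` values.
#' @param config Base model configuration.
#' @param seed Training seed.
#' @return A list with `best_rho` and a tibble `results` (rho, visi,
#'   accuracy, n_vsl, n_isl).
#' @export
tune_vigilance <- function(train_ids, eval_ids,
                           grid = seq(0.80, 0.98, by = 0.02),
                           config = model_config(), seed = 1) {
  rows <- lapply(grid, function(r) {
    cfg <- config; cfg$rho <- r
    m <- train_model(train_ids, eval_ids, cfg, seed = seed)
    ev <- evaluate_model(m, eval_ids, seed = seed)
    data.frame(rho = r, visi = ev$visi, accuracy = ev$accuracy,
               n_vsl = nrow(m$vsl$centers), n_isl = length(m$isl$incoming))
  })
  results <- tibble::as_tibble(do.call(rbind, rows))
  list(best_rho = results$rho[which.max(results$visi)], results = results)
}

# ---- checkpoint I/O: structured text, bit-exact round trip ----

# numeric payloads are stored as %.17g strings: exact round trip for
# doubles, which JSON number formatting does not guarantee
array_to_list <- function(a) list(dim = dim(a),
                                  data = sprintf("%.17g", as.vector(a)))
list_to_array <- function(l) array(as.numeric(l$data), dim = l$dim)

#' Save / load a model checkpoint
#'
#' JSON text with full-precision numbers; loading reproduces inference
#' bit-identically.
#'
#' @param model A `face_model`.
#' @param path File path.
#' @return `load_model` returns the restored `face_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config = model$config[setdiff(names(model$config), "bank_config")],
    bank_config = unclass(model$config$bank_config),
    seed = model$seed,
    train_labels = model$train_labels,
    prototypes = lapply(model$dict$prototypes, array_to_list),
    proto_provenance = model$dict$provenance,
    gamma = model$dict$gamma,
    proto_sizes = model$dict$sizes,
    vsl = list(centers = array_to_list(model$vsl$centers),
               sigma = model$vsl$sigma, alpha = model$vsl$alpha,
               rho = model$vsl$rho),
    isl = list(incoming = model$isl$incoming,
               max_coeff = model$isl$max_coeff,
               trace_coeff = model$isl$trace_coeff),
    ledger = model$ledger)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank_cfg <- do.call(gabor_bank_config, obj$bank_config[
    setdiff(names(obj$bank_config), character(0))])
  config <- do.call(model_config, c(obj$config, list(bank_config = bank_cfg)))
  protos <- if (is.data.frame(obj$prototypes)) {
    lapply(seq_len(nrow(obj$prototypes)), function(i)
      array(as.numeric(obj$prototypes$data[[i]]),
            dim = obj$prototypes$dim[[i]]))
  } else {
    lapply(obj$prototypes, function(p)
      array(as.numeric(p$data), dim = p$dim))
  }
  dict <- structure(list(prototypes = protos,
                         provenance = as.data.frame(obj$proto_provenance),
                         gamma = obj$gamma, sizes = obj$proto_sizes),
                    class = "prototype_dictionary")
  vsl <- vsl_population(obj$vsl$centers$dim[2], sigma = obj$vsl$sigma,
                        alpha = obj$vsl$alpha, rho = obj$vsl$rho)
  vsl$centers <- array(as.numeric(obj$vsl$centers$data),
                       dim = obj$vsl$centers$dim)
  vsl$trace <- numeric(nrow(vsl$centers))
  isl <- isl_population(obj$isl$max_coeff, obj$isl$trace_coeff)
  isl$incoming <- if (is.matrix(obj$isl$incoming)) {
    # equal-length incoming sets simplify to a matrix on read
    lapply(seq_len(nrow(obj$isl$incoming)), function(i)
      as.integer(obj$isl$incoming[i, ]))
  } else {
    lapply(obj$isl$incoming, as.integer)
  }
  isl$trace <- numeric(length(isl$incoming))
  structure(list(bank = gabor_bank(bank_cfg), dict = dict, vsl = vsl,
                 isl = isl, config = config, seed = obj$seed,
                 ledger = tibble::as_tibble(obj$ledger),
                 train_labels = obj$train_labels),
            class = "face_model")
}
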