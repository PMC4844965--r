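#' @useDynLib facepatches, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The standard yaw grid
#'
#' Yaw angles used for multi-view datasets: -90 (left profile) to +90
#' (right profile) in 5 degree steps, 37 views in total.
#'
#' @return Numeric vector of 37 yaw angles in degrees.
#' @export
yaw_grid <- function() seq(-90, 90, by = 5)

# Parameter table for the synthetic face populations. Means/sds are in
# normalised head coordinates ([-1, 1] canvas); angles are radians on the
# head sphere. `shift` marks the dimensions along which population B's mean
# is displaced from population A's (in units of the common sd).
face_param_table <- function() {
  data.frame(
    name = c("head_width", "head_height", "eye_sep", "eye_height",
             "eye_size", "nose_length", "nose_width", "mouth_width",
             "mouth_height", "brow_height", "feature_contrast"),
    mean = c(0.40, 0.50, 0.55, 0.24, 0.060, 0.26, 0.065, 0.36,
             0.045, 0.115, 0.42),
    sd   = c(0.020, 0.022, 0.050, 0.030, 0.008, 0.035, 0.012, 0.050,
             0.008, 0.020, 0.050),
    shift = c(0, 0, 1, -1, 0, 1, 0, -1, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the two synthetic face populations
#'
#' Two identity-parameter distributions stand in for two races: both are
#' multivariate normal with a shared diagonal covariance; population B's
#' mean is shifted by `shift_sd` within-population standard deviations
#' along a fixed subset of dimensions (eye separation, eye height, nose
#' length, mouth width, brow height).
#'
#' @param shift_sd Size of the between-population mean shift, in units of
#'   the within-population standard deviation. Default 1.5: large enough
#'   that an other-race effect is detectable with 20 identities, small
#'   enough that cross-population identification stays above chance.
#' @return A list with the parameter table and the shift size.
#' @export
face_population_config <- function(shift_sd = 1.5) {
  tab <- face_param_table()
  list(params = tab, shift_sd = shift_sd,
       populations = c("A", "B"))
}

#' Sample a synthetic face identity
#'
#' Draws one identity-parameter vector from the named population. The same
#' seed always yields the same identity; distinct seeds yield distinct
#' parameter vectors with probability one.
#'
#' @param seed Integer seed for the draw.
#' @param population Population label, `"A"` or `"B"`.
#' @param config Population configuration, see [face_population_config()].
#' @param id_label Optional identity label; defaults to
#'   `"<population><seed>"`.
#' @return An object of class `face_identity`: a list with `id_label`,
#'   `population` and the named parameter vector `params`.
#' @export
sample_identity <- function(seed, population = "A",
                            config = face_population_config(),
                            id_label = NULL) {
  if (!is.character(population) || length(population) != 1 ||
      !(population %in% config$populations)) {
    stop("unknown population label; valid labels are: ",
         paste(config$populations, collapse = ", "))
  }
  tab <- config$params
  mu <- tab$mean
  if (population == "B") mu <- mu + config$shift_sd * tab$shift * tab$sd
  params <- withr::with_seed(as.integer(seed), {
    stats::rnorm(nrow(tab), mean = mu, sd = tab$sd)
  })
  names(params) <- tab$name
  # keep geometry renderable: clamp to a broad plausible box
  lo <- tab$mean - 4 * tab$sd - abs(config$shift_sd * tab$shift * tab$sd)
  hi <- tab$mean + 4 * tab$sd + abs(config$shift_sd * tab$shift * tab$sd)
  params <- pmin(pmax(params, lo), hi)
  if (is.null(id_label)) id_label <- paste0(population, seed)
  structure(list(id_label = id_label, population = population,
                 params = params),
            class = "face_identity")
}

#' @export
print.face_identity <- function(x, ...) {
  cat("<face_identity>", x$id_label, "(population", x$population, ")\n")
  print(round(x$params, 3))
  invisible(x)
}

# smooth 0..1 step used for soft edges (keeps view-to-view change smooth)
soft_step <- function(x, scale) stats::plogis(x / scale)

# soft elliptical blob centred at (x0, y0) with half-axes (a, b);
# exponent p controls edge hardness
soft_blob <- function(xg, yg, x0, y0, a, b, p = 2) {
  q <- (abs(xg - x0) / a)^p + (abs(yg - y0) / b)^p
  exp(-q)
}

#' Render a synthetic face image
#'
#' Pure parametric rendering of one identity at one pose: features sit at
#' fixed azimuths on a head ellipsoid and are projected with yaw-dependent
#' horizontal displacement and foreshortening; features rotated beyond
#' about 70 degrees from the camera axis are occluded (with a soft edge so
#' appearance changes smoothly from view to view). Identical inputs always
#' give identical images.
#'
#' @param identity A `face_identity`.
#' @param yaw Yaw in degrees, within \[-90, 90\]; 0 is frontal, +90 the
#'   right profile.
#' @param inplane In-plane rotation in degrees, within \[0, 180\],
#'   counter-clockwise about the image centre.
#' @param inverted If `TRUE` the upright rendering is flipped vertically.
#' @param aperture If `TRUE`, pixels outside the inscribed circle are set
#'   to the background gray.
#' @param size Side of the square image in pixels.
#' @param noise_sd Standard deviation of the per-pose capture noise
#'   (each rendered pose is a separate photograph; the noise is seeded
#'   deterministically from identity and pose, keeping rendering pure).
#'   Set to 0 for a noiseless rendering.
#' @return A `size` x `size` numeric matrix with values in \[0, 1\];
#'   background gray is 0.5.
#' @export
render_face <- function(identity, yaw = 0, inplane = 0, inverted = FALSE,
                        aperture = FALSE, size = 64, noise_sd = 0.03) {
  stopifnot(inherits(identity, "face_identity"))
  if (!is.numeric(yaw) || length(yaw) != 1 || yaw < -90 || yaw > 90)
    stop("yaw must be a single value in [-90, 90]")
  if (!is.numeric(inplane) || length(inplane) != 1 ||
      inplane < 0 || inplane > 180)
    stop("inplane must be a single value in [0, 180]")
  if (!is.numeric(size) || length(size) != 1 || size < 8)
    stop("size must be a positive integer >= 8")
  p <- as.list(identity$params)
  th <- yaw * pi / 180

  # symmetric pixel grid on [-1, 1]; row 1 is the top of the image
  cs <- (seq_len(size) - (size + 1) / 2) / (size / 2)
  xg0 <- matrix(cs, size, size, byrow = TRUE)
  yg0 <- matrix(rev(cs), size, size, byrow = FALSE)
  if (inplane != 0) {
    a <- inplane * pi / 180
    xg <- cos(a) * xg0 + sin(a) * yg0
    yg <- -sin(a) * xg0 + cos(a) * yg0
  } else {
    xg <- xg0
    yg <- yg0
  }

  # head ellipse: horizontal radius shrinks slightly towards profile
  rx <- p$head_width * (0.72 + 0.28 * cos(th))
  ry <- p$head_height
  qh <- sqrt((xg / rx)^2 + (yg / ry)^2)
  head_w <- soft_step(1 - qh, 0.02)
  img <- 0.5 + head_w * (0.74 - 0.5)

  # lateral shading that tracks the yaw (the far side of the head is
  # darker): a smooth, monotone-in-yaw appearance cue
  img <- img - 0.30 * head_w * sin(th) * (xg / rx)

  # hair cap: darker band over the top of the head (stable identity-free cue)
  hair <- head_w * soft_step(yg / ry - 0.55, 0.03)
  img <- img - 0.22 * hair

  contrast <- p$feature_contrast

  # a feature at azimuth phi projects to x = rx * sin(phi + yaw);
  # horizontal extent scales with cos(phi + yaw); occlusion beyond ~70 deg
  proj <- function(phi) {
    ang <- phi + th
    list(x = rx * sin(ang),
         fs = pmax(cos(ang), 0.05),
         vis = ((cos(ang) + 1) / 2)^3)
  }
  add_blob <- function(img, pr, y0, a, b, amp, pexp = 2) {
    if (pr$vis < 1e-4) return(img)
    img - amp * pr$vis * contrast *
      soft_blob(xg, yg, pr$x, y0, pmax(a * pr$fs, 1e-3), b, pexp)
  }

  eye_y <- p$eye_height
  # eyes
  for (s in c(-1, 1)) {
    pr <- proj(s * p$eye_sep)
    img <- add_blob(img, pr, eye_y, p$eye_size * 1.6, p$eye_size, 1.0, 2)
  }
  # brows: elongated bars above the eyes
  for (s in c(-1, 1)) {
    pr <- proj(s * p$eye_sep)
    img <- add_blob(img, pr, eye_y + p$brow_height,
                    p$eye_size * 2.2, p$eye_size * 0.45, 0.8, 4)
  }
  # nose: vertical blob at azimuth 0, tip slightly below centre
  nose_y <- eye_y - 0.06 - p$nose_length / 2
  prn <- proj(0)
  img <- img - 0.55 * prn$vis * contrast *
    soft_blob(xg, yg, prn$x, nose_y, pmax(p$nose_width * prn$fs, 1e-3),
              p$nose_length / 2, 4)
  # mouth: horizontal bar below the nose
  mouth_y <- eye_y - 0.10 - p$nose_length - 0.10
  prm <- proj(0)
  img <- img - 0.85 * prm$vis * contrast *
    soft_blob(xg, yg, prm$x, mouth_y,
              pmax(p$mouth_width * prm$fs, 1e-3), p$mouth_height, 4)
  # ear: small blob near azimuth +/-100 deg, visible towards profile
  for (s in c(-1, 1)) {
    pre <- proj(s * 100 * pi / 180)
    pre$vis <- soft_step(cos(s * 100 * pi / 180 + th) -
                           cos(88 * pi / 180), 0.10) *
      soft_step(abs(th) / pi * 2 - 0.25, 0.12)
    img <- add_blob(img, pre, eye_y - 0.10,
                    p$eye_size * 1.4, p$eye_size * 2.0, 0.40, 2)
  }

  # capture noise: every rendered pose is a separate "photograph" with its
  # own sensor noise, seeded deterministically from (identity, pose) so
  # rendering stays a pure function of its inputs
  if (noise_sd > 0) {
    key <- (sum(round(identity$params * 1e6)) + round(yaw * 131) +
              round(inplane * 17) + size) %% 2147483647L
    nz <- withr::with_seed(as.integer(key),
                           stats::rnorm(length(img), 0, noise_sd))
    img <- img + nz
  }
  img <- pmin(pmax(img, 0), 1)
  if (aperture) {
    qa <- sqrt(xg0^2 + yg0^2)
    img[qa > 1] <- 0.5
  }
  if (inverted) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  img
}

#' Build a composite-face stimulus
#'
#' Combines the top half of one identity's rendering with the bottom half
#' of another's, at the same yaw. In the misaligned condition the bottom
#' half is shifted horizontally, breaking the normal face configuration.
#'
#' @param top,bottom `face_identity` objects supplying the top and bottom
#'   halves.
#' @param aligned If `TRUE` the halves share the same horizontal placement.
#' @param misalign_offset Horizontal shift of the bottom half in pixels
#'   (used only when `aligned = FALSE`); defaults to half the face width.
#' @param yaw Yaw in degrees (frontal, 0, is the standard condition).
#' @param size Image side in pixels.
#' @return A `size` x `size` numeric matrix.
#' @export
make_composite <- function(top, bottom, aligned = TRUE,
                           misalign_offset = NULL, yaw = 0, size = 64) {
  if (is.null(misalign_offset))
    misalign_offset <- round(top$params[["head_width"]] * size / 2)
  misalign_offset <- as.integer(misalign_offset)
  if (misalign_offset >= size / 2)
    stop("misalign_offset must be smaller than size/2 ",
         "(the shifted half would leave the canvas)")
  top_img <- render_face(top, yaw = yaw, size = size)
  bot_img <- render_face(bottom, yaw = yaw, size = size)
  half <- floor(size / 2)
  out <- top_img
  bot <- bot_img[(half + 1):size, , drop = FALSE]
  if (!aligned && misalign_offset > 0) {
    shifted <- matrix(0.5, nrow(bot), ncol(bot))
    shifted[, (misalign_offset + 1):size] <-
      bot[, 1:(size - misalign_offset)]
    bot <- shifted
  }
  out[(half + 1):size, ] <- bot
  out
}

#' Generate a multi-view face dataset
#'
#' Renders `n_identities` identities from one population at all 37 yaw
#' angles. When `dir` is given, images are written as 8-bit grayscale PNG
#' with a delimited manifest; otherwise images are returned in memory.
#' The full dataset is a pure function of `(seed, config)`.
#'
#' @param n_identities Number of identities (>= 1).
#' @param population Population label, `"A"` or `"B"`.
#' @param seed Integer seed; identity `i` is drawn with sub-seed
#'   `seed * 1000 + i`.
#' @param size Image side in pixels.
#' @param dir Optional output directory for PNG files and
#'   `manifest.tsv`.
#' @param config Population configuration.
#' @return A list with `identities` (list of `face_identity`), `images`
#'   (list of matrices, view-major: all identities at view 1, then view 2,
#'   ...; `NULL` when written to disk), and `manifest` (a tibble with
#'   columns path, id_label, yaw_deg, inplane_deg, inverted, condition,
#'   population).
#' @export
make_dataset <- function(n_identities, population = "A", seed = 1,
                         size = 64, dir = NULL,
                         config = face_population_config()) {
  if (!is.numeric(n_identities) || n_identities < 1)
    stop("n_identities must be >= 1")
  ids <- lapply(seq_len(n_identities), function(i)
    sample_identity(seed * 1000 + i, population, config))
  yaws <- yaw_grid()
  write_out <- !is.null(dir)
  if (write_out) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  images <- if (write_out) NULL else vector("list",
                                            n_identities * length(yaws))
  k <- 0
  for (v in seq_along(yaws)) {
    for (i in seq_len(n_identities)) {
      k <- k + 1
      img <- render_face(ids[[i]], yaw = yaws[v], size = size)
      path <- NA_character_
      if (write_out) {
        path <- file.path(dir, sprintf("%s_yaw%+04d.png",
                                       ids[[i]]$id_label, yaws[v]))
        png::writePNG(img, path)
      } else {
        images[[k]] <- img
      }
      rows[[k]] <- data.frame(path = path, id_label = ids[[i]]$id_label,
                              yaw_deg = yaws[v], inplane_deg = 0,
                              inverted = FALSE, condition = "upright",
                              population = population,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- tibble::as_tibble(do.call(rbind, rows))
  if (write_out)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(identities = ids, images = images, manifest = manifest)
}

# Render a full 37-view sweep for a list of identities, view-major order.
# Internal workhorse used by training and the experiments.
render_sweep <- function(ids, size = 64, yaws = yaw_grid(), ...) {
  imgs <- vector("list", length(ids) * length(yaws))
  prov <- data.frame(id_label = character(0), yaw_deg = numeric(0))
  k <- 0
  rows <- vector("list", length(ids) * length(yaws))
  for (v in seq_along(yaws)) {
    for (i in seq_along(ids)) {
      k <- k + 1
      imgs[[k]] <- render_face(ids[[i]], yaw = yaws[v], size = size, ...)
      rows[[k]] <- data.frame(id_label = ids[[i]]$id_label,
                              yaw_deg = yaws[v])
    }
  }
  list(images = imgs, provenance = do.call(rbind, rows))
}
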