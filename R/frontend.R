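#' Gabor filter bank configuration
#'
#' A reduced standard HMAX scheme: 4 orientations and 8 filter sizes
#' grouped into 4 scale bands of two adjacent sizes each. Wavelengths and
#' envelope widths per size follow the usual HMAX parameterisation; every
#' filter is zero-mean and unit-norm, so a uniform image yields exactly
#' zero S1 (and hence C1) response.
#'
#' @param n_orientations Number of orientations (equally spaced on
#'   \[0, pi)).
#' @param sizes Filter side lengths in pixels, two consecutive sizes per
#'   band.
#' @param sigma,lambda Gaussian envelope width and carrier wavelength per
#'   filter size.
#' @param aspect Envelope aspect ratio.
#' @param c1_pool Side of the C1 pooling neighbourhood per band.
#' @param c1_step Subsampling stride of the C1 grid per band.
#' @return A list of class `gabor_bank_config`.
#' @export
gabor_bank_config <- function(n_orientations = 4,
                              sizes = c(7, 9, 11, 13, 15, 17, 19, 21),
                              sigma = c(2.8, 3.6, 4.5, 5.4, 6.3, 7.3,
                                        8.2, 9.2),
                              lambda = c(3.5, 4.6, 5.6, 6.8, 7.9, 9.1,
                                         10.3, 11.5),
                              aspect = 0.3,
                              c1_pool = c(8, 10, 12, 14),
                              c1_step = c(3, 3, 3, 3)) {
  stopifnot(length(sizes) %% 2 == 0,
            length(sigma) == length(sizes),
            length(lambda) == length(sizes),
            length(c1_pool) == length(sizes) / 2,
            length(c1_step) == length(c1_pool))
  structure(list(n_orientations = n_orientations, sizes = sizes,
                 sigma = sigma, lambda = lambda, aspect = aspect,
                 c1_pool = c1_pool, c1_step = c1_step),
            class = "gabor_bank_config")
}

# One zero-mean, unit-norm Gabor filter.
gabor_filter <- function(size, theta, sigma, lambda, aspect) {
  half <- (size - 1) / 2
  g <- expand.grid(x = -half:half, y = -half:half)
  X <- g$x * cos(theta) + g$y * sin(theta)
  Y <- -g$x * sin(theta) + g$y * cos(theta)
  f <- exp(-(X^2 + (aspect * Y)^2) / (2 * sigma^2)) * cos(2 * pi * X / lambda)
  f <- matrix(f, size, size)
  f <- f - mean(f)
  f / sqrt(sum(f^2))
}

#' Build the Gabor filter bank
#'
#' @param config A [gabor_bank_config()].
#' @return A list of class `gabor_bank`: `filters[[size]][[orientation]]`
#'   matrices plus the configuration.
#' @export
gabor_bank <- function(config = gabor_bank_config()) {
  thetas <- (seq_len(config$n_orientations) - 1) * pi / config$n_orientations
  filters <- lapply(seq_along(config$sizes), function(i) {
    lapply(thetas, function(th)
      gabor_filter(config$sizes[i], th, config$sigma[i], config$lambda[i],
                   config$aspect))
  })
  structure(list(filters = filters, config = config, thetas = thetas),
            class = "gabor_bank")
}

#' S1 and C1 layers: Gabor filtering and local max pooling
#'
#' S1 convolves the (mean-subtracted) image with every Gabor filter and
#' rectifies. C1 takes, per orientation and scale band, the elementwise
#' max of the two S1 maps in the band followed by a local spatial max over
#' `c1_pool` x `c1_pool` neighbourhoods sampled with stride `c1_step`,
#' giving translation tolerance within the pooling radius.
#'
#' @param image A square numeric matrix (grayscale image).
#' @param bank A [gabor_bank()] (built from the default configuration if
#'   omitted).
#' @return A list of class `c1_stack`: one 3-D array
#'   (rows x cols x orientations) per scale band.
#' @export
s1_c1 <- function(image, bank = NULL) {
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0)
    stop("image must be a non-empty matrix")
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (any(!is.finite(image))) stop("image must be finite-valued")
  if (is.null(bank)) bank <- gabor_bank()
  cfg <- bank$config
  x <- image - mean(image)
  bands <- cpp_s1_c1(x, bank$filters, as.integer(cfg$c1_pool),
                     as.integer(cfg$c1_step))
  structure(bands, class = "c1_stack")
}

#' Learn a dictionary of S2 prototypes
#'
#' Cuts `n` patches from C1 responses to the training images: sizes are
#' assigned round-robin over `sizes` (so all sizes are represented), and
#' the source image, scale band and position are drawn uniformly among
#' valid choices. Each patch is stored zero-mean and unit-norm; input
#' patches are normalised identically before distance computation, which
#' makes responses contrast-tolerant and exactly 1 at the source location.
#'
#' @param images List of square grayscale matrices (training images).
#' @param n Number of prototypes (the standard full-run count is 1000;
#'   desk-scale experiment configurations in this package use 200).
#' @param sizes Patch side lengths on the C1 grid.
#' @param seed Integer seed; the dictionary is deterministic given the
#'   seed.
#' @param bank Gabor bank used to compute C1.
#' @param gamma Tuning sharpness of the radial-basis response
#'   `exp(-gamma * d^2)` on normalised patch distance (`d^2` is in
#'   \[0, 4\]).
#' @return A list of class `prototype_dictionary` with elements
#'   `prototypes` (list of k x k x orientations arrays), `provenance`
#'   (data frame: image, band, row, col, size) and `gamma`.
#' @export
learn_prototypes <- function(images, n = 1000, sizes = c(4, 8, 12, 16),
                             seed = 1, bank = NULL, gamma = 1) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(bank)) bank <- gabor_bank()
  c1s <- lapply(images, s1_c1, bank = bank)
  dims <- lapply(c1s[[1]], dim)
  min_dim <- min(vapply(dims, function(d) min(d[1], d[2]), numeric(1)))
  max_dim <- max(vapply(dims, function(d) min(d[1], d[2]), numeric(1)))
  if (any(sizes > max_dim))
    stop("patch size ", max(sizes), " exceeds the largest C1 map extent (",
         max_dim, ")")
  protos <- vector("list", n)
  prov <- data.frame(image = integer(n), band = integer(n),
                     row = integer(n), col = integer(n), size = integer(n))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      k <- sizes[(i - 1) %% length(sizes) + 1]
      repeat {
        im <- sample.int(length(images), 1)
        ok_bands <- which(vapply(c1s[[im]], function(a)
          dim(a)[1] >= k && dim(a)[2] >= k, logical(1)))
        b <- ok_bands[sample.int(length(ok_bands), 1)]
        a <- c1s[[im]][[b]]
        r <- sample.int(dim(a)[1] - k + 1, 1)
        cc <- sample.int(dim(a)[2] - k + 1, 1)
        patch <- a[r:(r + k - 1), cc:(cc + k - 1), , drop = FALSE]
        patch <- patch - mean(patch)
        nrm <- sqrt(sum(patch^2))
        if (nrm > 1e-12) {       # skip flat patches, carry no structure
          protos[[i]] <- patch / nrm
          prov[i, ] <- c(im, b, r, cc, k)
          break
        }
      }
    }
  })
  structure(list(prototypes = protos, provenance = prov, gamma = gamma,
                 sizes = sizes),
            class = "prototype_dictionary")
}

#' S2/C2 layer: radial-basis prototype matching with global max pooling
#'
#' For each prototype P the S2 response at a C1 position is
#' `exp(-gamma * ||patch_hat - P||^2)` where `patch_hat` is the local C1
#' patch normalised like the stored prototypes; C2 is the global max over
#' all positions and scale bands. A patch without any C1 energy gives
#' response 0 (baseline), so a blank image yields an all-zero C2 vector.
#'
#' @param c1 A `c1_stack` from [s1_c1()].
#' @param dict A `prototype_dictionary`.
#' @return Numeric C2 vector, one value per prototype, each in \[0, 1\].
#' @export
s2_c2 <- function(c1, dict) {
  if (!inherits(dict, "prototype_dictionary") ||
      length(dict$prototypes) == 0)
    stop("dict must be a non-empty prototype_dictionary")
  nor <- dim(c1[[1]])[3]
  ok <- vapply(dict$prototypes, function(p) dim(p)[3] == nor, logical(1))
  if (!all(ok)) stop("prototype orientation count does not match C1 stack")
  cpp_s2_c2(unclass(c1), dict$prototypes, dict$gamma)
}

#' Extract C2 feature vectors for a set of images
#'
#' @param images List of grayscale matrices.
#' @param dict Prototype dictionary.
#' @param bank Gabor bank.
#' @return Matrix with one row per image, one column per prototype.
#' @export
extract_c2 <- function(images, dict, bank = NULL) {
  if (is.null(bank)) bank <- gabor_bank()
  t(vapply(images, function(im) s2_c2(s1_c1(im, bank), dict),
           numeric(length(dict$prototypes))))
}

#' Write / read a feature cache
#'
#' One record per image: provenance columns followed by the feature
#' vector, as tab-delimited text at full printed precision (the
#' read/write round trip is bit-exact).
#'
#' @param features Numeric matrix, one row per image.
#' @param provenance Data frame with one row per image.
#' @param path Output file.
#' @return `read_features` returns a list with `features` and
#'   `provenance`.
#' @export
write_features <- function(features, provenance, path) {
  stopifnot(nrow(features) == nrow(provenance))
  vals <- apply(features, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  hdr <- paste(c(names(provenance),
                 paste0("f", seq_len(ncol(features)))), collapse = "\t")
  prov <- apply(provenance, 1, function(r) paste(r, collapse = "\t"))
  writeLines(c(hdr, paste(prov, vals, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  fcols <- grepl("^f[0-9]+$", names(d))
  list(features = as.matrix(d[, fcols, drop = FALSE]),
       provenance = d[, !fcols, drop = FALSE])
}
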