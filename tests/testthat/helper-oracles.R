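# Independent brute-force oracles used to validate the package's numeric
# routines. These deliberately re-derive every quantity with plain loops
# and share no code with the implementation under test.

# "same" convolution with zero padding, plain loops
oracle_conv_same <- function(image, kernel) {
  n <- nrow(image); k <- nrow(kernel); half <- (k - 1) %/% 2
  out <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    acc <- 0
    for (i in 1:k) for (j in 1:k) {
      # conv2: out(r,c) = sum image(r-i+half+1, c-j+half+1) * kernel(i,j)
      rr <- r - i + half + 1; cc <- c - j + half + 1
      if (rr >= 1 && rr <= n && cc >= 1 && cc <= n)
        acc <- acc + image[rr, cc] * kernel[i, j]
    }
    out[r, c] <- acc
  }
  out
}

# C1: max of |S1| over the two band scales and pool x pool neighbourhoods
oracle_s1_c1 <- function(image, bank) {
  cfg <- bank$config
  x <- image - mean(image)
  s1 <- lapply(seq_along(cfg$sizes), function(i)
    lapply(seq_len(cfg$n_orientations), function(o)
      abs(oracle_conv_same(x, bank$filters[[i]][[o]]))))
  lapply(seq_along(cfg$c1_pool), function(b) {
    pp <- cfg$c1_pool[b]; st <- cfg$c1_step[b]
    H <- nrow(s1[[1]][[1]])
    nr <- (H - pp) %/% st + 1
    arr <- array(0, dim = c(nr, nr, cfg$n_orientations))
    for (o in seq_len(cfg$n_orientations)) {
      m <- pmax(s1[[2 * b - 1]][[o]], s1[[2 * b]][[o]])
      for (i in 1:nr) for (j in 1:nr) {
        rows <- ((i - 1) * st + 1):((i - 1) * st + pp)
        cols <- ((j - 1) * st + 1):((j - 1) * st + pp)
        arr[i, j, o] <- max(m[rows, cols])
      }
    }
    arr
  })
}

# C2: exhaustive loop over all patch positions and bands
oracle_s2_c2 <- function(c1, dict) {
  vapply(dict$prototypes, function(P) {
    k <- dim(P)[1]
    best <- NA_real_
    for (band in c1) {
      H <- dim(band)[1]; W <- dim(band)[2]
      if (k > H || k > W) next
      for (r in 1:(H - k + 1)) for (cc in 1:(W - k + 1)) {
        patch <- band[r:(r + k - 1), cc:(cc + k - 1), , drop = FALSE]
        patch <- patch - mean(patch)
        nrm <- sqrt(sum(patch^2))
        resp <- if (nrm < 1e-12) 0 else
          exp(-dict$gamma * sum((patch / nrm - P)^2))
        if (is.na(best) || resp > best) best <- resp
      }
    }
    best
  }, numeric(1))
}

# two-loop Pearson similarity matrix
oracle_similarity <- function(features) {
  n <- nrow(features)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    out[i, j] <- stats::cor(features[i, ], features[j, ])
  out
}

# double-loop VSI / VISI on a view-major matrix with `block` identities
oracle_vsi <- function(m, block) {
  n <- nrow(m); num <- c(); den <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if ((i - 1) %/% block == (j - 1) %/% block) num <- c(num, m[i, j])
    else den <- c(den, m[i, j])
  }
  mean(num) / mean(den)
}

oracle_visi <- function(m, block) {
  n <- nrow(m); num <- c(); den <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if ((i - 1) %% block == (j - 1) %% block) num <- c(num, m[i, j])
    else den <- c(den, m[i, j])
  }
  mean(num) / mean(den)
}

# small Gabor bank for oracle-sized inputs
oracle_bank <- function() {
  gabor_bank(gabor_bank_config(
    n_orientations = 2, sizes = c(3, 5), sigma = c(1.2, 1.8),
    lambda = c(2.5, 3.6), c1_pool = 4, c1_step = 2))
}
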