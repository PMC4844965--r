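#' Create an empty view-selective layer (VSL) population
#'
#' VSL units are Gaussian radial-basis units in C2 space with a trace
#' memory: the instantaneous response to a C2 vector `x` is
#' `g_i = exp(-||x - P_i||^2 / (2 sigma^2))` where `P_i` is the stored
#' template, and the emitted activation adds a fraction `alpha` of the
#' unit's previous activation (the trace). New units are recruited under
#' an adaptive-resonance vigilance rule: when no existing unit matches the
#' input above `rho`, the input itself becomes a new template.
#'
#' @param dim C2 dimensionality (number of prototypes).
#' @param sigma Gaussian tuning width (fixed at 0.5).
#' @param alpha Trace coefficient (fixed at 0.3).
#' @param rho Vigilance threshold in (0, 1); see [tune_vigilance()] for
#'   the grid-search utility used to select it on an evaluation set.
#' @return An object of class `vsl_population`.
#' @export
vsl_population <- function(dim, sigma = 0.5, alpha = 0.3, rho = 0.9) {
  stopifnot(rho > 0, rho < 1, sigma > 0)
  structure(list(centers = matrix(numeric(0), 0, dim),
                 trace = numeric(0),
                 sigma = sigma, alpha = alpha, rho = rho),
            class = "vsl_population")
}

#' Create an empty identity-selective layer (ISL) population
#'
#' ISL units max-pool over a private set of VSL units (binary incoming
#' weights; each VSL unit wires to exactly one ISL unit) and mix that
#' pooled drive with their own trace:
#' `r_j = max_coeff * max_i(in_j) + trace_coeff * trace_j`.
#'
#' @param max_coeff,trace_coeff Mixing coefficients of the pooled input
#'   and the trace part.
#' @return An object of class `isl_population`.
#' @export
isl_population <- function(max_coeff = 0.7, trace_coeff = 0.3) {
  structure(list(incoming = list(), trace = numeric(0),
                 max_coeff = max_coeff, trace_coeff = trace_coeff),
            class = "isl_population")
}

# instantaneous (trace-free) VSL responses to one C2 vector
vsl_instant <- function(pop, c2) {
  if (nrow(pop$centers) == 0) return(numeric(0))
  d2 <- rowSums(sweep(pop$centers, 2, c2)^2)
  exp(-d2 / (2 * pop$sigma^2))
}

#' VSL response to a C2 vector
#'
#' Emits `r_i = g_i + alpha * trace_i` (clamped at 1 so activations stay
#' commensurate with the vigilance threshold). A stimulus with no
#' front-end energy (all-zero C2, e.g. a blank gray image) produces zero
#' activation and clears the trace: silence is the baseline state and
#' leaves no memory.
#'
#' @param pop A `vsl_population`.
#' @param c2 C2 feature vector.
#' @param update_trace If `TRUE`, each unit's trace is set to its emitted
#'   activation.
#' @return A list with `activation` (numeric vector, empty for an empty
#'   population) and `population` (with updated traces if requested).
#' @export
vsl_respond <- function(pop, c2, update_trace = FALSE) {
  if (nrow(pop$centers) > 0 && length(c2) != ncol(pop$centers))
    stop("c2 length does not match VSL center dimensionality")
  if (all(c2 == 0)) {
    act <- numeric(nrow(pop$centers))
    if (update_trace) pop$trace <- act
    return(list(activation = act, population = pop))
  }
  g <- vsl_instant(pop, c2)
  act <- pmin(g + pop$alpha * pop$trace, 1)
  if (update_trace) pop$trace <- act
  list(activation = act, population = pop)
}

#' Vigilance-gated VSL growth
#'
#' During learning only: if the best instantaneous (trace-free) response
#' among existing units is below the vigilance `rho` -- i.e. no template
#' represents the input well enough -- a new unit is appended whose centre
#' is the input itself (trace 0).
#'
#' @param pop A `vsl_population`.
#' @param c2 C2 feature vector of the current stimulus.
#' @return A list with `population` and `new_unit` (index of the added
#'   unit, or `NA` if none was added).
#' @export
vsl_grow <- function(pop, c2) {
  g <- vsl_instant(pop, c2)
  if (length(g) > 0 && max(g) >= pop$rho)
    return(list(population = pop, new_unit = NA_integer_))
  pop$centers <- rbind(pop$centers, matrix(c2, 1))
  pop$trace <- c(pop$trace, 0)
  list(population = pop, new_unit = nrow(pop$centers))
}

#' ISL response to a VSL activation vector
#'
#' Each ISL unit max-pools the activations of its incoming VSL units
#' (0 if it has none) and mixes in its trace. As in [vsl_respond()], a
#' fully silent input (all VSL activations zero) yields zero activation
#' and clears the trace.
#'
#' @param pop An `isl_population`.
#' @param vsl_acts VSL activation vector (indexed consistently with the
#'   incoming sets).
#' @param update_trace If `TRUE`, traces are set to the emitted
#'   activations (clamped at 1).
#' @return A list with `activation` and `population`.
#' @export
isl_respond <- function(pop, vsl_acts, update_trace = FALSE) {
  n <- length(pop$incoming)
  if (n > 0) {
    idx <- unlist(pop$incoming)
    if (length(idx) > 0 && (length(vsl_acts) == 0 ||
                            max(idx) > length(vsl_acts)))
      stop("incoming VSL index out of range")
  }
  if (length(vsl_acts) > 0 && all(vsl_acts == 0)) {
    act <- numeric(n)
    if (update_trace) pop$trace <- act
    return(list(activation = act, population = pop))
  }
  m <- vapply(pop$incoming, function(ii)
    if (length(ii) == 0) 0 else max(vsl_acts[ii]), numeric(1))
  act <- pmin(pop$max_coeff * m + pop$trace_coeff * pop$trace, 1)
  if (update_trace) pop$trace <- act
  list(activation = act, population = pop)
}

#' Wire a newly grown VSL unit to the winning ISL unit
#'
#' The winner is the ISL unit with the largest standing activation -- its
#' trace, i.e. its response to the previous stimulus. A positive trace
#' marks temporal continuity (same identity, earlier view), so the new
#' view-tuned unit joins that identity's pool. If every trace is zero
#' (start of a sequence, or after a blank-image reset) a fresh ISL unit is
#' created holding exactly the new VSL unit. Ties break to the lowest
#' unit index. Each VSL unit may be wired only once, which keeps the
#' incoming sets of distinct ISL units disjoint.
#'
#' @param pop An `isl_population`.
#' @param new_vsl_index Index of the VSL unit just created by
#'   [vsl_grow()].
#' @return A list with `population` and `winner` (index of the ISL unit
#'   that received the connection).
#' @export
wire_to_winner <- function(pop, new_vsl_index) {
  if (length(pop$incoming) > 0 &&
      new_vsl_index %in% unlist(pop$incoming))
    stop("VSL unit ", new_vsl_index, " is already wired to an ISL unit")
  if (length(pop$trace) > 0 && any(pop$trace > 0)) {
    w <- which.max(pop$trace)          # which.max takes the lowest index
    pop$incoming[[w]] <- c(pop$incoming[[w]], new_vsl_index)
  } else {
    pop$incoming[[length(pop$incoming) + 1]] <- new_vsl_index
    pop$trace <- c(pop$trace, 0)
    w <- length(pop$incoming)
  }
  list(population = pop, winner = w)
}

#' Reset all traces
#'
#' Zeroes the trace state of both layers; templates and wiring are
#' untouched. Presenting a blank gray image has the same effect end to
#' end, since a blank yields zero C2 activity and silence clears traces.
#'
#' @param vsl A `vsl_population`.
#' @param isl An `isl_population`.
#' @return A list with the two populations.
#' @export
reset_traces <- function(vsl, isl) {
  vsl$trace <- numeric(nrow(vsl$centers))
  isl$trace <- numeric(length(isl$incoming))
  list(vsl = vsl, isl = isl)
}

# Batch inference (traces held at zero): VSL and ISL feature matrices for
# a matrix of C2 row vectors. Used by evaluation and the experiments.
layer_features <- function(c2_mat, vsl, isl) {
  n <- nrow(c2_mat)
  if (nrow(vsl$centers) == 0) stop("VSL population is empty")
  cn2 <- rowSums(vsl$centers^2)
  d2 <- outer(rowSums(c2_mat^2), cn2, "+") -
    2 * c2_mat %*% t(vsl$centers)
  d2[d2 < 0] <- 0
  vslf <- exp(-d2 / (2 * vsl$sigma^2))
  blank <- rowSums(c2_mat != 0) == 0
  vslf[blank, ] <- 0
  islf <- matrix(0, n, length(isl$incoming))
  for (j in seq_along(isl$incoming)) {
    ii <- isl$incoming[[j]]
    if (length(ii) > 0)
      islf[, j] <- isl$max_coeff *
        apply(vslf[, ii, drop = FALSE], 1, max)
  }
  list(VSL = vslf, ISL = islf)
}
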