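#' Normalise Dirichlet counts into a likelihood matrix
#'
#' Each column of counts parameterises an independent Dirichlet belief about
#' the outcome distribution of one hidden state; the expected likelihood is
#' the column-normalised count matrix, `A[i, j] = a[i, j] / sum_k a[k, j]`.
#' The normalisation is invariant to rescaling the counts, which only
#' changes how much a new observation moves the belief.
#'
#' @param a Non-negative count matrix, outcomes x states; all entries must
#'   be strictly positive.
#' @return A column-stochastic matrix of the same shape.
#' @examples
#' normalize_counts(matrix(c(1, 3), 2, 1))
#' @export
normalize_counts <- function(a) {
  stopifnot(is.matrix(a))
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("Dirichlet counts must be strictly positive and finite", call. = FALSE)
  }
  sweep(a, 2, colSums(a), "/")
}

# log-softmax of a preference vector: proper log-probabilities ln P(o)
log_softmax <- function(x) {
  x <- x - max(x)
  x - log(sum(exp(x)))
}

softmax <- function(x) exp(log_softmax(x))

# one modality of a generative model
new_modality <- function(name, a = NULL, A = NULL, C, learn) {
  if (learn) {
    A <- normalize_counts(a)
  }
  stopifnot(is.matrix(A), length(C) == nrow(A))
  list(name = name, a = a, A = A, C = C, learn = learn)
}

# counts = e0 everywhere + e1 on the true outcome of each column
seed_counts <- function(true_outcome, n_out, e0, e1) {
  a <- matrix(e0, n_out, length(true_outcome))
  a[cbind(true_outcome, seq_along(true_outcome))] <- e0 + e1
  a
}

#' Build the flat 64-state cancellation-task model
#'
#' The hidden state is the fixated location (64 states). Two outcome
#' modalities: `visual` (white / black / red, 3 outcomes) with learnable
#' Dirichlet counts seeded near-uniform plus a weak increment on the true
#' outcome of each location, and `prop` (proprioception, 64 outcomes) mapped
#' by a fixed identity matrix so the agent always knows where it is looking.
#' Every location is reachable by a single saccade: 64 actions, each with a
#' deterministic transition matrix whose columns are the unit vector at the
#' destination. Policy priors `E` are uniform and proprioceptive preferences
#' flat in the healthy model.
#'
#' @param display A [generate_display()] result giving the true target
#'   layout (only target positions matter; cancelled cells count as targets
#'   that are already red).
#' @param config A [neglect_config()]. The lesion entry is applied with
#'   [apply_lesion()] before returning.
#' @return An object of class `neglect_model`.
#' @examples
#' m <- build_flat_model(generate_display(16, "balanced", seed = 1))
#' m
#' @export
build_flat_model <- function(display, config = neglect_config()) {
  stopifnot(inherits(display, "neglect_display"), inherits(config, "neglect_config"))
  true_vis <- display_cell(display, 0:63) + 1L
  modalities <- list(
    visual = new_modality(
      "visual",
      a = seed_counts(true_vis, 3L, config$e0, config$e1),
      C = c(config$c_white, config$c_black, config$c_red),
      learn = TRUE
    ),
    prop = new_modality("prop", A = diag(64), C = rep(0, 64), learn = FALSE)
  )
  finish_model("flat", modalities, display, config)
}

#' Build the multiscale (quadrant / subquadrant / cell) model
#'
#' The 64 locations are addressed by three factors of cardinality 4
#' (quadrant, subquadrant within quadrant, cell within subquadrant), giving
#' the same 4^3 = 64 joint states. Visual input arrives at three
#' resolutions: the number of targets in the fixated quadrant (0-16) and
#' subquadrant (0-4) — both colour-blind, counting targets whether cancelled
#' or not — and the fine white/black/red outcome, which alone distinguishes
#' cancelled targets. Each density modality has its own learnable Dirichlet
#' counts. Proprioception is one fixed identity mapping per factor
#' (3 sub-modalities of 4 outcomes), so preferences and lesions can be
#' scale-specific.
#'
#' @inheritParams build_flat_model
#' @return An object of class `neglect_model`.
#' @export
build_multiscale_model <- function(display, config = neglect_config()) {
  stopifnot(inherits(display, "neglect_display"), inherits(config, "neglect_config"))
  ft <- factor_table()
  true_vis <- display_cell(display, 0:63) + 1L
  dens <- vapply(0:63, function(i) {
    d <- display_densities(display, i)
    c(d$coarse, d$mid)
  }, numeric(2))
  prop_A <- function(f) {
    A <- matrix(0, 4, 64)
    A[cbind(f + 1L, 1:64)] <- 1
    A
  }
  modalities <- list(
    density_coarse = new_modality(
      "density_coarse",
      a = seed_counts(dens[1, ] + 1L, 17L, config$e0, config$e1),
      C = rep(0, 17), learn = TRUE
    ),
    density_mid = new_modality(
      "density_mid",
      a = seed_counts(dens[2, ] + 1L, 5L, config$e0, config$e1),
      C = rep(0, 5), learn = TRUE
    ),
    visual = new_modality(
      "visual",
      a = seed_counts(true_vis, 3L, config$e0, config$e1),
      C = c(config$c_white, config$c_black, config$c_red),
      learn = TRUE
    ),
    prop_q = new_modality("prop_q", A = prop_A(ft$quadrant), C = rep(0, 4), learn = FALSE),
    prop_s = new_modality("prop_s", A = prop_A(ft$subquadrant), C = rep(0, 4), learn = FALSE),
    prop_c = new_modality("prop_c", A = prop_A(ft$cell), C = rep(0, 4), learn = FALSE)
  )
  finish_model("multiscale", modalities, display, config)
}

finish_model <- function(kind, modalities, display, config) {
  D <- numeric(64)
  D[config$start + 1L] <- 1
  model <- structure(
    list(
      kind = kind,
      n_states = 64L,
      n_actions = 64L,
      modalities = modalities,
      D = D,
      E = rep(1 / 64, 64),
      gamma = config$gamma,
      start = config$start,
      config = config,
      lesion = NULL,
      label = "none"
    ),
    class = "neglect_model"
  )
  if (!is.null(config$lesion)) model <- apply_lesion(model, config$lesion)
  model
}

#' Deterministic saccade transition matrix
#'
#' Action `u` is "saccade to location `u`": every column of `B(u)` is the
#' unit vector at the destination, independent of the current location.
#'
#' @param model A `neglect_model`.
#' @param u Destination state index (0..63).
#' @return A 64 x 64 column-stochastic matrix.
#' @export
transition_matrix <- function(model, u) {
  check_index(u)
  B <- matrix(0, model$n_states, model$n_states)
  B[u + 1L, ] <- 1
  B
}

#' @export
print.neglect_model <- function(x, ...) {
  cat("<neglect_model> ", x$kind, "cancellation-task model\n")
  cat("  states:", x$n_states, " actions:", x$n_actions,
      " gamma:", x$gamma, "\n")
  cat("  modalities:",
      paste0(vapply(x$modalities, function(m)
        paste0(m$name, "(", nrow(m$A), if (m$learn) ", learned)" else ")"),
        character(1)), collapse = " "), "\n")
  cat("  lesion:", if (is.null(x$lesion)) "none" else format_lesion(x$lesion), "\n")
  invisible(x)
}

#' One-line summary of a generative model
#'
#' @param x A `neglect_model`.
#' @param ... Unused.
#' @return A one-row tibble with structural counts and the lesion label.
#' @export
glance.neglect_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_states = x$n_states,
    n_actions = x$n_actions,
    n_modalities = length(x$modalities),
    n_visual_outcomes = nrow(x$modalities$visual$A),
    gamma = x$gamma,
    lesion = x$label
  )
}
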