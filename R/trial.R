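VISUAL_LABELS <- c("white", "black", "red")

# observe a fixated location: onset outcome -> learn -> cancellation rule ->
# offset outcome -> learn. Returns the updated model/display plus outcomes.
observe_and_learn <- function(model, display, loc, posterior) {
  obs <- emit_outcomes(display, loc, model$kind)
  model <- learn_outcomes(model, obs$onset, posterior)
  model <- learn_outcomes(model, obs$offset, posterior)
  list(model = model, display = obs$display, onset = obs$onset, offset = obs$offset)
}

# posterior over locations after arriving at a destination: one-step belief
# update from the proprioceptive (and visual) evidence. With the identity
# proprioceptive mapping this is a point mass at the destination.
arrival_posterior <- function(model, u, onset) {
  lik <- rep(1, model$n_states)
  for (nm in names(model$modalities)) {
    lik <- lik * model$modalities[[nm]]$A[onset[[nm]], ]
  }
  prior <- numeric(model$n_states)
  prior[u + 1L] <- 1 # deterministic saccade
  post <- prior * lik
  post / sum(post)
}

#' Run one closed-loop cancellation trial
#'
#' The agent starts at the model's start location, observes it (onset,
#' cancellation rule, offset — both observations drive Dirichlet learning),
#' then repeats for each saccade: evaluate the expected free energy of all
#' 64 single-saccade policies, form the policy posterior
#' `softmax(ln E - gamma * G)`, select a saccade, execute it, observe and
#' learn at the new location. Everything is recorded per epoch. Runs are
#' fully deterministic given `(model, display, seed)`.
#'
#' @param model A `neglect_model` (its Dirichlet counts are copied, not
#'   mutated; counts reset between trials).
#' @param display A `neglect_display` giving the ground truth.
#' @param n_saccades Number of saccades (epochs) to simulate.
#' @param seed Integer seed for action sampling.
#' @param action_mode `"sample"` or `"argmax"`.
#' @return An object of class `neglect_trial`; see [tidy.neglect_trial()].
#' @examples
#' d <- generate_display(16, "balanced", seed = 1)
#' tr <- run_trial(build_flat_model(d), d, n_saccades = 5, seed = 1)
#' tidy(tr)
#' @export
run_trial <- function(model, display,
                      n_saccades = model$config$n_saccades,
                      seed = model$config$seed,
                      action_mode = model$config$action_mode) {
  stopifnot(inherits(model, "neglect_model"), inherits(display, "neglect_display"),
            n_saccades >= 0)
  action_mode <- match.arg(action_mode, c("sample", "argmax"))
  set.seed(seed)
  display_start <- display
  loc <- model$start
  s <- numeric(model$n_states)
  s[loc + 1L] <- 1
  st <- observe_and_learn(model, display, loc, s)
  model <- st$model
  display <- st$display
  start_outcomes <- list(onset = st$onset, offset = st$offset)

  epochs <- vector("list", n_saccades)
  q_mat <- matrix(NA_real_, n_saccades, model$n_actions)
  efe_rows <- vector("list", n_saccades)
  for (e in seq_len(n_saccades)) {
    ef <- efe_terms(model)
    q <- policy_posterior(model$E, ef$G, model$gamma)
    u <- select_action(q, action_mode) - 1L
    onset_pre <- emit_outcomes(display, u, model$kind)$onset
    post <- arrival_posterior(model, u, onset_pre)
    st <- observe_and_learn(model, display, u, post)
    model <- st$model
    display <- st$display
    loc <- u
    rc <- loc_rc(u)
    epochs[[e]] <- tibble::tibble(
      epoch = e, index = u, row = rc$row, col = rc$col,
      onset_visual = VISUAL_LABELS[st$onset[["visual"]]],
      offset_visual = VISUAL_LABELS[st$offset[["visual"]]],
      cost = ef$cost[u + 1L], salience = ef$salience[u + 1L],
      novelty = ef$novelty[u + 1L], G = ef$G[u + 1L],
      action_prob = q[u + 1L]
    )
    q_mat[e, ] <- q
    efe_rows[[e]] <- dplyr::mutate(ef, epoch = e, .before = 1)
  }
  structure(
    list(
      epochs = dplyr::bind_rows(epochs),
      policy_posterior = q_mat,
      efe = dplyr::bind_rows(efe_rows),
      bma = q_mat, # policy-averaged predicted fixation distribution per epoch
      display_start = display_start,
      display_end = display,
      start = model$start,
      start_outcomes = start_outcomes,
      model_label = model$label,
      kind = model$kind,
      n_saccades = as.integer(n_saccades),
      seed = as.integer(seed),
      action_mode = action_mode,
      config_hash = config_hash(model$config)
    ),
    class = "neglect_trial"
  )
}

#' @export
print.neglect_trial <- function(x, ...) {
  cat("<neglect_trial> ", x$n_saccades, "saccades,", x$kind, "model, lesion",
      x$model_label, ", seed", x$seed, "\n")
  if (x$n_saccades > 0) {
    print(laterality_stats(x))
  }
  invisible(x)
}

#' Per-epoch record of a trial
#'
#' @param x A `neglect_trial`.
#' @param ... Unused.
#' @return A tibble with one row per saccade: fixation (`index`, `row`,
#'   `col`), onset/offset visual outcomes, the chosen policy's
#'   expected-free-energy decomposition and its posterior probability.
#' @export
tidy.neglect_trial <- function(x, ...) x$epochs

#' @rdname laterality_stats
#' @export
glance.neglect_trial <- function(x, ...) laterality_stats(x)

#' Laterality summary of a trial
#'
#' @param trial A `neglect_trial` with at least one saccade.
#' @param x,... Method arguments (`glance()` forwards to
#'   `laterality_stats()`).
#' @return A one-row tibble: number of fixations; fraction of fixations in
#'   the left/right hemifield; conditional rightward fractions within each
#'   quadrant (`within_quadrant_right`) and within each subquadrant
#'   (`within_subquadrant_right`); and targets present / cancelled per
#'   hemifield (cancellation includes the start location if it held a
#'   target).
#' @export
laterality_stats <- function(trial) {
  stopifnot(inherits(trial, "neglect_trial"))
  if (trial$n_saccades == 0 || nrow(trial$epochs) == 0) {
    stop("laterality_stats needs a non-empty trial record", call. = FALSE)
  }
  ft <- loc_to_factors(trial$epochs$index)
  left <- trial$epochs$col <= 3
  start_cells <- display_cell(trial$display_start, 0:63)
  end_cells <- display_cell(trial$display_end, 0:63)
  targ <- start_cells %in% c(1L, 2L)
  canc <- end_cells == 2L
  lmask <- hemifield_mask("left")
  tibble::tibble(
    n_fix = nrow(trial$epochs),
    left_frac = mean(left),
    right_frac = mean(!left),
    within_quadrant_right = mean(ft$subquadrant %in% c(1L, 3L)),
    within_subquadrant_right = mean(ft$cell %in% c(1L, 3L)),
    targets_left = sum(targ & lmask),
    targets_right = sum(targ & !lmask),
    cancelled_left = sum(canc & lmask),
    cancelled_right = sum(canc & !lmask)
  )
}

#' Write / read a scanpath CSV
#'
#' One row per epoch with the fixation and visual outcomes; a `#`-prefixed
#' header embeds the model label, seed and config hash for provenance.
#'
#' @param trial A `neglect_trial`.
#' @param path CSV path.
#' @param trial_id Identifier written into the `trial_id` column.
#' @return `read_scanpath()` returns a tibble of the epoch rows (the header
#'   fields are attached as attributes `model_label`, `seed`,
#'   `config_hash`).
#' @export
write_scanpath <- function(trial, path, trial_id = 1L) {
  stopifnot(inherits(trial, "neglect_trial"))
  rows <- dplyr::mutate(
    trial$epochs[, c("epoch", "row", "col", "onset_visual", "offset_visual")],
    trial_id = trial_id, model_label = trial$model_label, seed = trial$seed,
    .before = 1
  )
  header <- c(
    paste0("# config_hash: ", trial$config_hash),
    paste0("# seed: ", trial$seed),
    paste0("# model_label: ", trial$model_label),
    paste0("# start: ", trial$start)
  )
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(rows, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, append = TRUE, quote = FALSE)
  )
  invisible(path)
}

#' @rdname write_scanpath
#' @export
read_scanpath <- function(path) {
  header <- grep("^#", readLines(path, n = 10), value = TRUE)
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), header, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else NA
  }
  attr(out, "model_label") <- field("model_label")
  attr(out, "seed") <- as.integer(field("seed"))
  attr(out, "config_hash") <- field("config_hash")
  attr(out, "start") <- as.integer(field("start"))
  out
}
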