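#' Build a bank of candidate lesion models
#'
#' All candidates share the same display, configuration and state/action
#' spaces, differing only in the lesion applied.
#'
#' @param display A `neglect_display`.
#' @param config A [neglect_config()]; its own lesion entry is ignored.
#' @param kind `"flat"` or `"multiscale"` models.
#' @param scale Lesion scale for multiscale banks (default `"coarse"`).
#' @param lesions Character vector of lesion kinds to include.
#' @param side Neglected side for the lesioned candidates.
#' @return A named list of `neglect_model` objects (class `model_bank`).
#' @export
model_bank <- function(display, config = neglect_config(),
                       kind = c("flat", "multiscale"), scale = NULL,
                       lesions = c("none", "A1", "E", "C2"), side = "left") {
  kind <- match.arg(kind)
  stopifnot(!anyDuplicated(lesions))
  if (kind == "multiscale" && is.null(scale)) scale <- "coarse"
  build <- if (kind == "flat") build_flat_model else build_multiscale_model
  config$lesion <- NULL
  healthy <- build(display, config)
  bank <- lapply(lesions, function(k) {
    apply_lesion(healthy, lesion_spec(k, side = side, scale = scale))
  })
  names(bank) <- lesions
  structure(bank, display = display, class = c("model_bank", "list"))
}

#' Log evidence of a recorded scanpath under a candidate model
#'
#' Replays the trial in open loop: the candidate model receives the same
#' observation stream the recorded agent saw (reconstructed by replaying
#' the display dynamics along the recorded fixations) and accumulates its
#' own Dirichlet counts, but its actions are clamped to the recorded
#' saccades. The log evidence is the sum over epochs of the log posterior
#' probability the candidate assigns to the recorded saccade. With no free
#' parameters this is the model's log likelihood for the data.
#'
#' @param record A `neglect_trial`, or an integer vector of 0-based fixation
#'   indices (one per saccade) together with `display` and `start`.
#' @param model The candidate `neglect_model`; must share the recorded
#'   trial's kind and start location.
#' @param display,start Only used when `record` is a raw fixation vector:
#'   the initial display and 0-based start location.
#' @return Scalar log evidence (nats).
#' @export
replay_log_evidence <- function(record, model, display = NULL, start = NULL) {
  stopifnot(inherits(model, "neglect_model"))
  if (inherits(record, "neglect_trial")) {
    if (!identical(record$kind, model$kind)) {
      stop("record and model use different state spaces", call. = FALSE)
    }
    if (!identical(record$start, model$start)) {
      stop("record and model disagree on the start location", call. = FALSE)
    }
    fixations <- record$epochs$index
    display <- record$display_start
    start <- record$start
  } else {
    fixations <- as.integer(record)
    stopifnot(inherits(display, "neglect_display"))
    if (is.null(start)) start <- model$start
    check_index(fixations)
  }
  loc <- start
  s <- numeric(model$n_states)
  s[loc + 1L] <- 1
  st <- observe_and_learn(model, display, loc, s)
  model <- st$model
  display <- st$display
  logev <- 0
  for (u in fixations) {
    ef <- efe_terms(model)
    q <- policy_posterior(model$E, ef$G, model$gamma)
    logev <- logev + log(q[u + 1L])
    onset_pre <- emit_outcomes(display, u, model$kind)$onset
    post <- arrival_posterior(model, u, onset_pre)
    st <- observe_and_learn(model, display, u, post)
    model <- st$model
    display <- st$display
  }
  logev
}

#' Posterior probabilities over candidate models
#'
#' Softmax of the log evidences under a uniform model prior.
#'
#' @param log_evidence Finite numeric vector (one entry per model).
#' @return A probability vector summing to 1.
#' @examples
#' model_posteriors(c(0, -log(2))) # c(2/3, 1/3)
#' @export
model_posteriors <- function(log_evidence) {
  stopifnot(all(is.finite(log_evidence)))
  softmax(log_evidence)
}

#' Lesion-decoding confusion experiment
#'
#' For each generating model in the bank, simulates trials (one display and
#' trial per seed), scores every trial under every candidate model by
#' [replay_log_evidence()], averages the log evidence over seeds, and
#' converts each generating model's row to a posterior over candidates with
#' [model_posteriors()].
#'
#' @param bank A [model_bank()] — or a function `(display, label)` returning
#'   one; by default banks are rebuilt per seed so each simulated trial gets
#'   a fresh display.
#' @param n_saccades Saccades per simulated trial (default 40).
#' @param n_seeds Number of simulated trials per generating model.
#' @param config,kind,scale,n_targets Used when `bank` is `NULL`: each
#'   seed's display is `generate_display(n_targets, "balanced", seed)` and a
#'   bank is built on it with [model_bank()].
#' @param seed Base seed; seed `i` of the experiment uses `seed * 1000 + i`.
#' @return An object of class `neglect_confusion`: a list with matrices
#'   `log_evidence` and `posterior` (rows = generating model, columns =
#'   candidate), plus the per-seed evidence array.
#' @export
confusion_experiment <- function(bank = NULL, n_saccades = 40, n_seeds = 10,
                                 config = neglect_config(),
                                 kind = "multiscale", scale = "coarse",
                                 n_targets = 16, seed = 1L) {
  labels <- if (is.null(bank)) c("none", "A1", "E", "C2") else names(bank)
  ev <- array(NA_real_, c(length(labels), length(labels), n_seeds),
              dimnames = list(generator = labels, candidate = labels, NULL))
  for (i in seq_len(n_seeds)) {
    seed_i <- seed * 1000L + i
    bank_i <- if (is.null(bank)) {
      model_bank(generate_display(n_targets, "balanced", seed = seed_i),
                 config = config, kind = kind, scale = scale, lesions = labels)
    } else {
      bank
    }
    disp <- attr(bank_i, "display")
    for (g in labels) {
      trial <- run_trial(bank_i[[g]], disp, n_saccades = n_saccades,
                         seed = seed_i, action_mode = "sample")
      for (m in labels) {
        ev[g, m, i] <- replay_log_evidence(trial, bank_i[[m]])
      }
    }
  }
  log_evidence <- apply(ev, c(1, 2), mean)
  posterior <- t(apply(log_evidence, 1, model_posteriors))
  dimnames(posterior) <- dimnames(log_evidence)
  structure(
    list(log_evidence = log_evidence, posterior = posterior,
         per_seed = ev, n_saccades = as.integer(n_saccades),
         n_seeds = as.integer(n_seeds), seed = as.integer(seed)),
    class = "neglect_confusion"
  )
}

#' @export
print.neglect_confusion <- function(x, ...) {
  cat("<neglect_confusion> ", x$n_seeds, "seeds x", x$n_saccades, "saccades\n")
  cat("posterior P(candidate | data from generator):\n")
  print(round(x$posterior, 3))
  invisible(x)
}

#' Tidy view of a confusion experiment
#'
#' @param x A `neglect_confusion`.
#' @param ... Unused.
#' @return A tibble with one row per (generator, candidate) pair and
#'   columns `log_evidence` and `posterior`.
#' @export
tidy.neglect_confusion <- function(x, ...) {
  labels <- rownames(x$posterior)
  tibble::tibble(
    generator = rep(labels, times = length(labels)),
    candidate = rep(labels, each = length(labels)),
    log_evidence = as.vector(x$log_evidence),
    posterior = as.vector(x$posterior)
  )
}

#' @rdname tidy.neglect_confusion
#' @return `glance()` returns a one-row tibble with the decoding accuracy
#'   (fraction of generators whose own candidate has the maximal posterior)
#'   and the mean diagonal posterior.
#' @export
glance.neglect_confusion <- function(x, ...) {
  diag_max <- mean(apply(x$posterior, 1, which.max) == seq_len(nrow(x$posterior)))
  tibble::tibble(
    n_models = nrow(x$posterior),
    n_seeds = x$n_seeds,
    n_saccades = x$n_saccades,
    accuracy = diag_max,
    mean_diag_posterior = mean(diag(x$posterior))
  )
}
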