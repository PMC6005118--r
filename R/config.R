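#' Simulation configuration
#'
#' Collects every tunable of the generative model and trial runner in one
#' list. All arguments have defaults; pass only what you want to change.
#'
#' @param c_white,c_black,c_red Log-preferences over the three fine visual
#'   outcomes (white = empty, black = uncancelled target, red = cancelled
#'   target). They are passed through a log-softmax before use, so only
#'   differences matter. Defaults 0, +4, -4: the agent expects to look at
#'   uncancelled targets and not at cancelled ones.
#' @param e0 Baseline Dirichlet count added to every outcome of every
#'   learnable likelihood column (default 0.25). Small values give one-shot
#'   learning: a single observation dominates the column.
#' @param e1 Extra Dirichlet count on the true outcome of each column
#'   (default 0.25) — the "very weak but accurate" prior knowledge of where
#'   the targets are.
#' @param gamma Policy precision (inverse temperature) scaling the expected
#'   free energy in policy selection (default 1).
#' @param eta Learning rate: Dirichlet count mass added per observation
#'   (default 1; 0 disables learning).
#' @param depth Policy depth. Only single-saccade policies (depth 1) are
#'   supported; the policy space is re-evaluated after every fixation.
#' @param n_saccades Trial length in saccades (default 20).
#' @param start Flat index of the initial fixation (default `loc_index(3, 3)`).
#' @param action_mode `"sample"` (default) draws the saccade from the policy
#'   posterior; `"argmax"` takes its mode.
#' @param seed Integer seed used by seeded operations when none is given.
#' @param lesion A [lesion_spec()], or `NULL` for a healthy model.
#' @return A list of class `neglect_config`.
#' @seealso [write_config()], [read_config()], [config_hash()]
#' @export
neglect_config <- function(c_white = 0, c_black = 4, c_red = -4,
                           e0 = 0.25, e1 = 0.25,
                           gamma = 1, eta = 1, depth = 1,
                           n_saccades = 20, start = loc_index(3, 3),
                           action_mode = c("sample", "argmax"),
                           seed = 1L, lesion = NULL) {
  action_mode <- match.arg(action_mode)
  stopifnot(e0 > 0, e1 >= 0, gamma >= 0, eta >= 0, n_saccades >= 0)
  if (!identical(as.integer(depth), 1L)) {
    stop("only depth-1 (single-saccade) policies are supported", call. = FALSE)
  }
  check_index(start)
  cfg <- list(
    c_white = c_white, c_black = c_black, c_red = c_red,
    e0 = e0, e1 = e1, gamma = gamma, eta = eta, depth = 1L,
    n_saccades = as.integer(n_saccades), start = as.integer(start),
    action_mode = action_mode, seed = as.integer(seed),
    lesion = lesion
  )
  structure(cfg, class = "neglect_config")
}

#' @export
print.neglect_config <- function(x, ...) {
  cat("<neglect_config>  hash:", config_hash(x), "\n")
  flat <- x[setdiff(names(x), "lesion")]
  cat(paste0("  ", names(flat), " = ", unlist(flat), collapse = "\n"), "\n")
  if (!is.null(x$lesion)) {
    cat("  lesion:", format_lesion(x$lesion), "\n")
  } else {
    cat("  lesion: none\n")
  }
  invisible(x)
}

#' Serialise and restore a configuration
#'
#' Configurations round-trip losslessly through YAML, so a run can be
#' reproduced from its config file alone.
#'
#' @param config A [neglect_config()].
#' @param path File path (`.yaml`).
#' @return `read_config()` returns a `neglect_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "neglect_config"))
  lst <- unclass(config)
  if (!is.null(lst$lesion)) lst$lesion <- unclass(lst$lesion)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lesion <- NULL
  if (!is.null(lst$lesion)) {
    lesion <- lesion_spec(
      kind = lst$lesion$kind, side = lst$lesion$side,
      magnitude = lst$lesion$magnitude,
      scale = lst$lesion$scale
    )
  }
  args <- lst[setdiff(names(lst), c("lesion", "depth"))]
  do.call(neglect_config, c(args, list(lesion = lesion)))
}

#' @rdname write_config
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "neglect_config"))
  rlang::hash(lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x))
}
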