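#' Specify an in-silico lesion
#'
#' Three functional lesions reproduce neglect-like search, all biasing
#' sampling away from the neglected side (left by default):
#' \describe{
#'   \item{`A1`}{multiplies the Dirichlet counts of the learnable visual
#'     likelihood(s) for neglected-side locations by `magnitude`
#'     (default 100). The likelihood probabilities are unchanged, but the
#'     neglected side becomes familiar, so only the intact side retains
#'     novelty. Models a disconnection of the tract linking the dorsal and
#'     ventral attention networks.}
#'   \item{`E`}{adds `magnitude` (default 4) to the log policy prior of
#'     every saccade whose destination lies on the intact side; a habitual
#'     bias of policy selection, as after putamen damage.}
#'   \item{`C2`}{sets the proprioceptive log-preference of intact-side
#'     locations to `magnitude` (default 4), so the agent expects to find
#'     itself looking at the intact side; models degraded pulvinar input to
#'     dorsal parietal cortex.}
#' }
#' In the multiscale model, `scale` chooses the quadtree level at which
#' "side" is evaluated: `"coarse"` (array halves, egocentric neglect),
#' `"mid"` (halves of each quadrant), or `"fine"` (halves of each
#' subquadrant, allocentric/object-centred neglect).
#'
#' @param kind One of `"none"`, `"A1"`, `"E"`, `"C2"`.
#' @param side The neglected side (`"left"` default); sampling is biased
#'   toward the opposite, intact side.
#' @param magnitude Positive lesion strength; defaults 100 (A1) or 4 (E, C2).
#' @param scale Quadtree level for multiscale models; ignored (and must be
#'   `NULL`) for flat models.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("none", "A1", "E", "C2"),
                        side = c("left", "right"),
                        magnitude = NULL, scale = NULL) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (is.null(magnitude)) magnitude <- if (kind == "A1") 100 else 4
  stopifnot(is.numeric(magnitude), magnitude > 0)
  if (!is.null(scale)) scale <- match.arg(scale, c("coarse", "mid", "fine"))
  structure(list(kind = kind, side = side, magnitude = magnitude, scale = scale),
            class = "lesion_spec")
}

format_lesion <- function(spec) {
  if (spec$kind == "none") return("none")
  paste0(spec$kind, " (", spec$side, "-neglect, magnitude ", spec$magnitude,
         if (!is.null(spec$scale)) paste0(", ", spec$scale, " scale"), ")")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat("<lesion_spec>", format_lesion(x), "\n")
  invisible(x)
}

# TRUE for the 64 states on the given side, at the lesion's scale for
# multiscale models or by hemifield for flat ones
lesion_side_mask <- function(model, spec, side) {
  if (model$kind == "flat") {
    if (!is.null(spec$scale)) {
      stop("lesion scale applies only to multiscale models", call. = FALSE)
    }
    hemifield_mask(side)
  } else {
    scale_side_mask(if (is.null(spec$scale)) "coarse" else spec$scale, side)
  }
}

#' Apply a lesion to a healthy generative model
#'
#' Dispatches on `spec$kind`; `kind = "none"` returns the model unchanged.
#' Lesions modify the agent's model only — the display and the outcomes it
#' emits are never altered. Every lesioned model remains a valid generative
#' model (stochastic matrices stay normalised).
#'
#' @param model A `neglect_model`.
#' @param spec A [lesion_spec()].
#' @return The lesioned `neglect_model`, with `label` set to the lesion kind.
#' @examples
#' m <- build_flat_model(generate_display(16, "balanced", seed = 1))
#' lesioned <- apply_lesion(m, lesion_spec("E"))
#' @export
apply_lesion <- function(model, spec) {
  stopifnot(inherits(model, "neglect_model"), inherits(spec, "lesion_spec"))
  model <- switch(spec$kind,
    none = model,
    A1 = lesion_A1(model, spec),
    E = lesion_E(model, spec),
    C2 = lesion_C2(model, spec)
  )
  model$lesion <- if (spec$kind == "none") NULL else spec
  model$label <- spec$kind
  model
}

# Inflate neglected-side Dirichlet counts of every learnable modality;
# A is unchanged because normalisation cancels the scaling.
lesion_A1 <- function(model, spec) {
  neglected <- lesion_side_mask(model, spec, spec$side)
  for (nm in names(model$modalities)) {
    m <- model$modalities[[nm]]
    if (!m$learn) next
    m$a[, neglected] <- m$a[, neglected] * spec$magnitude
    m$A <- normalize_counts(m$a)
    model$modalities[[nm]] <- m
  }
  model
}

# Habit bias: raise the log policy prior of intact-side destinations.
lesion_E <- function(model, spec) {
  intact <- lesion_side_mask(model, spec, setdiff(c("left", "right"), spec$side))
  logE <- log(model$E)
  logE[intact] <- logE[intact] + spec$magnitude
  model$E <- softmax(logE)
  model
}

# Proprioceptive preference bias: expect to be looking at the intact side.
# Flat model: the 64-outcome proprioceptive C; multiscale: the C of the
# proprioceptive sub-modality at the lesion's scale (outcomes are the 4
# factor values, of which 1 and 3 are the right-hand ones).
lesion_C2 <- function(model, spec) {
  intact_side <- setdiff(c("left", "right"), spec$side)
  if (model$kind == "flat") {
    intact <- lesion_side_mask(model, spec, intact_side)
    C <- rep(0, 64)
    C[intact] <- spec$magnitude
    model$modalities$prop$C <- C
  } else {
    scale <- if (is.null(spec$scale)) "coarse" else spec$scale
    nm <- switch(scale, coarse = "prop_q", mid = "prop_s", fine = "prop_c")
    C <- rep(0, 4)
    intact_vals <- if (intact_side == "right") c(2L, 4L) else c(1L, 3L)
    C[intact_vals] <- spec$magnitude
    model$modalities[[nm]]$C <- C
  }
  model
}
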