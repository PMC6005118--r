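#' Accumulate Dirichlet counts after an observation
#'
#' Implements likelihood learning as short-term synaptic memory: the count
#' of the observed outcome is incremented by the posterior probability of
#' each hidden state (scaled by the learning rate), so total count mass
#' grows by exactly `eta` per observation. Observing a target turn red makes
#' the agent expect red at that location on revisiting — raising its
#' expected cost and shrinking its novelty, which is how cancelled targets
#' are remembered within a trial.
#'
#' @param a Positive Dirichlet count matrix (outcomes x states).
#' @param outcome 1-based index of the observed outcome (or a one-hot
#'   vector over outcomes).
#' @param posterior Normalised posterior over hidden states.
#' @param eta Learning rate (count mass per observation, default 1).
#' @return The updated count matrix.
#' @examples
#' a <- matrix(0.25, 3, 2)
#' accumulate_counts(a, 2, c(1, 0)) # +1 at [2, 1]
#' @export
accumulate_counts <- function(a, outcome, posterior, eta = 1) {
  stopifnot(is.matrix(a), all(a > 0), length(posterior) == ncol(a))
  if (length(outcome) == 1L) {
    o <- numeric(nrow(a))
    o[outcome] <- 1
  } else {
    stopifnot(length(outcome) == nrow(a), sum(outcome == 1) == 1,
              all(outcome %in% c(0, 1)))
    o <- as.numeric(outcome)
  }
  if (abs(sum(posterior) - 1) > 1e-6) {
    stop("state posterior must be normalised", call. = FALSE)
  }
  a + eta * tcrossprod(o, posterior)
}

# update every learnable modality of a model from a named outcome vector
# (1-based indices, names matching modality names)
learn_outcomes <- function(model, outcomes, posterior) {
  eta <- model$config$eta
  if (eta == 0) return(model)
  for (nm in names(model$modalities)) {
    m <- model$modalities[[nm]]
    if (!m$learn) next
    o <- outcomes[[nm]]
    m$a <- accumulate_counts(m$a, o, posterior, eta)
    m$A <- normalize_counts(m$a)
    model$modalities[[nm]] <- m
  }
  model
}
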