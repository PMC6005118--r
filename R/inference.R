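# Belief updating and expected-free-energy evaluation.
#
# Two model shapes are accepted throughout: the cancellation-task
# `neglect_model`, and small hand-built MDPs (`toy_mdp`) used to validate
# the updates against brute-force enumeration.

#' Construct a small MDP for testing and exploration
#'
#' @param A List of likelihood matrices (outcomes x states), one per
#'   modality, column-stochastic.
#' @param B List of transition matrices (states x states), one per action,
#'   column-stochastic.
#' @param D Initial-state prior (sums to 1).
#' @return A list of class `toy_mdp`.
#' @export
toy_mdp <- function(A, B, D) {
  if (is.matrix(A)) A <- list(A)
  if (is.matrix(B)) B <- list(B)
  n <- length(D)
  stopifnot(
    all(vapply(A, ncol, 1L) == n),
    all(vapply(B, function(b) all(dim(b) == n), TRUE)),
    abs(sum(D) - 1) < 1e-9
  )
  structure(list(A = A, B = B, D = D, n_states = n), class = "toy_mdp")
}

# common internal view: list(A = list, D, n_states, B_fun(action))
as_mdp <- function(model) {
  if (inherits(model, "toy_mdp")) {
    list(A = model$A, D = model$D, n_states = model$n_states,
         B_fun = function(u) model$B[[u]])
  } else if (inherits(model, "neglect_model")) {
    list(A = lapply(model$modalities, `[[`, "A"), D = model$D,
         n_states = model$n_states,
         B_fun = function(u) transition_matrix(model, u - 1L))
  } else {
    stop("model must be a neglect_model or toy_mdp", call. = FALSE)
  }
}

LOG_EPS <- 1e-16

#' Posterior beliefs about hidden states along a policy
#'
#' Computes the per-time posteriors over hidden states given the
#' observations made so far and the (remaining) actions of a policy, by
#' iterating message-passing sweeps that combine the log-likelihood of each
#' observation with forward (transition-propagated) and backward messages
#' until the posteriors stop changing. On a single chain the fixed point is
#' the exact smoothing posterior. Time points beyond the last observation
#' are pure predictions.
#'
#' @param model A `neglect_model` or [toy_mdp()].
#' @param observations Integer matrix, time x modality, of 1-based outcome
#'   indices; `NA` marks an unobserved entry. May have fewer rows than the
#'   policy implies time points.
#' @param policy Integer vector of actions. For a `toy_mdp` these are
#'   1-based indices into its `B` list; for a `neglect_model`, 0-based
#'   saccade destinations. `policy[t]` moves the state from time `t` to
#'   `t + 1`, so the beliefs span `length(policy) + 1` time points (or the
#'   number of observation rows if larger requires a policy of that length).
#' @param tol,max_iter Convergence tolerance on the largest absolute change
#'   in any posterior entry between sweeps, and the sweep cap.
#' @return A list: `posterior` (time x states matrix, rows sum to 1),
#'   `F_trace` (variational free energy after each sweep), `n_iter`,
#'   `converged`.
#' @export
update_state_beliefs <- function(model, observations, policy = integer(0),
                                 tol = 1e-8, max_iter = 16) {
  mdp <- as_mdp(model)
  if (is.null(dim(observations))) observations <- matrix(observations, nrow = 1)
  if (inherits(model, "neglect_model") && length(policy)) policy <- policy + 1L
  tt <- max(nrow(observations), length(policy) + 1L)
  if (length(policy) < tt - 1L) {
    stop("policy too short for the number of observation rows", call. = FALSE)
  }
  n <- mdp$n_states
  lik <- matrix(1, tt, n) # per-time likelihood of each state
  for (tau in seq_len(nrow(observations))) {
    for (m in seq_along(mdp$A)) {
      o <- observations[tau, m]
      if (!is.na(o)) lik[tau, ] <- lik[tau, ] * mdp$A[[m]][o, ]
    }
  }
  Bs <- lapply(seq_len(tt - 1L), function(t) mdp$B_fun(policy[t]))
  norm1 <- function(x) x / sum(x)
  s <- matrix(1 / n, tt, n)
  F_trace <- free_energy(model, s, observations, policy)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    s_old <- s
    f <- matrix(0, tt, n)
    if (sum(mdp$D * lik[1, ]) == 0) {
      stop("observations have zero probability under the model", call. = FALSE)
    }
    f[1, ] <- norm1(mdp$D * lik[1, ])
    if (tt > 1) for (tau in 2:tt) {
      f[tau, ] <- norm1(lik[tau, ] * drop(Bs[[tau - 1L]] %*% f[tau - 1L, ]))
    }
    b <- matrix(1, tt, n)
    if (tt > 1) for (tau in (tt - 1L):1L) {
      b[tau, ] <- norm1(drop(crossprod(Bs[[tau]], lik[tau + 1L, ] * b[tau + 1L, ])))
    }
    s <- f * b
    s <- s / rowSums(s)
    F_trace <- c(F_trace, free_energy(model, s, observations, policy))
    converged <- max(abs(s - s_old)) < tol
  }
  if (!converged) {
    stop("belief updating failed to converge within ", max_iter, " sweeps",
         call. = FALSE)
  }
  list(posterior = s, F_trace = F_trace, n_iter = iter, converged = converged)
}

#' Variational free energy of a set of state beliefs
#'
#' Evaluates the mean-field free energy
#' \eqn{F = E_Q[\ln Q(\tilde s) - \ln P(\tilde o, \tilde s)]}
#' for factorised beliefs `Q = prod_t q(s_t)`. `F` upper-bounds the surprise
#' `-ln P(o)`; the bound is tight exactly when `Q` equals the joint
#' posterior, which factorised beliefs can represent whenever the posterior
#' factorises over time (always true for a single time step).
#'
#' @inheritParams update_state_beliefs
#' @param beliefs Time x states matrix of normalised state beliefs.
#' @return The free energy (scalar, nats).
#' @export
free_energy <- function(model, beliefs, observations, policy = integer(0)) {
  mdp <- as_mdp(model)
  if (is.null(dim(observations))) observations <- matrix(observations, nrow = 1)
  if (is.null(dim(beliefs))) beliefs <- matrix(beliefs, nrow = 1)
  if (inherits(model, "neglect_model") && length(policy)) policy <- policy + 1L
  tt <- nrow(beliefs)
  f <- sum(beliefs * log(beliefs + LOG_EPS))
  f <- f - sum(beliefs[1, ] * log(mdp$D + LOG_EPS))
  if (tt > 1) for (tau in 2:tt) {
    B <- mdp$B_fun(policy[tau - 1L])
    f <- f - sum(beliefs[tau, ] * (log(B + LOG_EPS) %*% beliefs[tau - 1L, ]))
  }
  for (tau in seq_len(min(tt, nrow(observations)))) {
    for (m in seq_along(mdp$A)) {
      o <- observations[tau, m]
      if (!is.na(o)) f <- f - sum(beliefs[tau, ] * log(mdp$A[[m]][o, ] + LOG_EPS))
    }
  }
  f
}

# predictive state distribution one step ahead under action u (0-based for
# neglect models). For the cancellation task this is a delta at u because
# saccades are deterministic and location-independent.
predict_states <- function(model, u, s) {
  if (inherits(model, "neglect_model")) {
    out <- numeric(model$n_states)
    out[u + 1L] <- 1
    out
  } else {
    drop(model$B[[u]] %*% s)
  }
}

#' Expected cost of a single-saccade policy
#'
#' The cost term of the expected free energy: the negative expected
#' log-preference of the outcomes predicted under the policy,
#' \eqn{-\sum_m E_{Q(o|\pi)}[\ln P(o)]}, with each modality's preference
#' vector `C` converted to a proper log-probability by log-softmax.
#'
#' @param model A `neglect_model`.
#' @param u Saccade destination (0..63).
#' @param s Current state belief (defaults to the model's initial prior).
#' @return Non-negative scalar (nats).
#' @export
expected_cost <- function(model, u, s = model$D) {
  s_pred <- predict_states(model, u, s)
  sum(vapply(model$modalities, function(m) {
    -sum(drop(m$A %*% s_pred) * log_softmax(m$C))
  }, numeric(1)))
}

#' Salience (state information gain) of a single-saccade policy
#'
#' The expected KL divergence from the predictive state belief to the
#' posterior that each counterfactual outcome would induce, summed over
#' modalities. With an identity proprioceptive mapping the predictive state
#' is already certain, so this term is zero — and thus identical for every
#' policy — in both cancellation-task models.
#'
#' @inheritParams expected_cost
#' @return Non-negative scalar (nats).
#' @export
salience_term <- function(model, u, s = model$D) {
  s_pred <- predict_states(model, u, s)
  A_list <- if (inherits(model, "neglect_model")) {
    lapply(model$modalities, `[[`, "A")
  } else {
    model$A
  }
  total <- 0
  for (A in A_list) {
    o_pred <- drop(A %*% s_pred)
    for (i in which(o_pred > 0)) {
      post <- A[i, ] * s_pred
      post <- post / sum(post)
      keep <- post > 0
      total <- total + o_pred[i] * sum(post[keep] * log(post[keep] / s_pred[keep]))
    }
  }
  total
}

#' KL divergence between two Dirichlet distributions
#'
#' @param alpha,beta Positive concentration-parameter vectors of equal
#'   length; the divergence is `KL(Dir(alpha) || Dir(beta))`.
#' @return Non-negative scalar (nats).
#' @export
dirichlet_kl <- function(alpha, beta) {
  stopifnot(length(alpha) == length(beta), all(alpha > 0), all(beta > 0))
  a0 <- sum(alpha)
  lgamma(a0) - sum(lgamma(alpha)) - lgamma(sum(beta)) + sum(lgamma(beta)) +
    sum((alpha - beta) * (digamma(alpha) - digamma(a0)))
}

#' Novelty of one learnable likelihood mapping under a predictive state
#'
#' The expected KL divergence from the current Dirichlet belief about a
#' likelihood matrix to the belief that would follow a single observation,
#' averaged over the outcomes predicted under the policy. Large counts make
#' every update small, so saturated (familiar) columns have vanishing
#' novelty; near-uniform small counts make a location epistemically
#' attractive.
#'
#' @param a Positive Dirichlet count matrix (outcomes x states).
#' @param s_pred Predictive state distribution under the policy.
#' @return Non-negative scalar (nats).
#' @export
dirichlet_novelty <- function(a, s_pred) {
  stopifnot(is.matrix(a), length(s_pred) == ncol(a))
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("Dirichlet counts must be strictly positive and finite", call. = FALSE)
  }
  o_pred <- drop(normalize_counts(a) %*% s_pred)
  total <- 0
  js <- which(s_pred > 0)
  for (i in which(o_pred > 0)) {
    kl <- 0
    for (j in js) {
      ap <- a[, j]
      ap[i] <- ap[i] + s_pred[j]
      kl <- kl + dirichlet_kl(ap, a[, j])
    }
    total <- total + o_pred[i] * kl
  }
  total
}

#' Novelty of a single-saccade policy
#'
#' Sum of [dirichlet_novelty()] over the model's learnable modalities.
#'
#' @inheritParams expected_cost
#' @return Non-negative scalar (nats).
#' @export
novelty_term <- function(model, u, s = model$D) {
  s_pred <- predict_states(model, u, s)
  total <- 0
  for (m in model$modalities) {
    if (m$learn) total <- total + dirichlet_novelty(m$a, s_pred)
  }
  total
}

#' Expected-free-energy decomposition over all policies
#'
#' Evaluates cost, salience and novelty for every single-saccade policy and
#' returns `G = cost - salience - novelty`. Because saccades are
#' deterministic and location-independent, the predictive state under
#' policy `u` is a point mass at `u`; salience is then exactly zero for
#' every policy and the novelty reduces to a closed-form function of the
#' destination's Dirichlet columns, evaluated vectorised.
#'
#' @param model A `neglect_model` (counts as currently accumulated).
#' @return A 64-row tibble: `policy` (0-based destination), `cost`,
#'   `salience`, `novelty`, `G`.
#' @export
efe_terms <- function(model) {
  stopifnot(inherits(model, "neglect_model"))
  cost <- numeric(model$n_actions)
  novelty <- numeric(model$n_actions)
  for (m in model$modalities) {
    cost <- cost - drop(crossprod(m$A, log_softmax(m$C)))
    if (m$learn && !isTRUE(model$ablate_novelty)) {
      a0 <- colSums(m$a)
      p <- sweep(m$a, 2, a0, "/")
      kl_unit <- sweep(-log(m$a) + digamma(m$a + 1), 2,
                       log(a0) - digamma(a0 + 1), "+")
      novelty <- novelty + colSums(p * kl_unit)
    }
  }
  salience <- numeric(model$n_actions) # exactly 0: point-mass predictions
  tibble::tibble(
    policy = 0:(model$n_actions - 1L),
    cost = cost, salience = salience, novelty = novelty,
    G = cost - salience - novelty
  )
}

#' Disable the novelty drive of a model
#'
#' Returns a model whose expected free energy omits the novelty term, so
#' policy selection is driven by preferences alone. Used to demonstrate
#' that the epistemic (novelty) drive is what makes the healthy agent seek
#' out unvisited targets.
#'
#' @param model A `neglect_model`.
#' @param ablate Set `FALSE` to restore the novelty term.
#' @return The modified model.
#' @export
ablate_novelty <- function(model, ablate = TRUE) {
  stopifnot(inherits(model, "neglect_model"))
  model$ablate_novelty <- isTRUE(ablate)
  model
}

#' Posterior over policies
#'
#' `softmax(ln E - gamma * G)`: baseline policy priors `E` biased by the
#' expected free energy `G` with precision `gamma`.
#'
#' @param E Strictly positive prior over policies (need not be normalised).
#' @param G Expected free energy per policy.
#' @param gamma Non-negative precision.
#' @return A probability vector over policies.
#' @examples
#' policy_posterior(c(1, 1), c(1, 2), gamma = 1) # softmax(-1, -2)
#' @export
policy_posterior <- function(E, G, gamma = 1) {
  stopifnot(length(E) == length(G), all(E > 0), all(is.finite(log(E))),
            gamma >= 0)
  if (any(!is.finite(G))) stop("expected free energy must be finite", call. = FALSE)
  softmax(log(E) - gamma * G)
}

#' Bayesian model average of per-policy state beliefs
#'
#' @param S Matrix of per-policy state posteriors (policies x states), or a
#'   list of state-posterior vectors.
#' @param q Policy posterior (probability vector).
#' @return The policy-weighted state posterior (sums to 1).
#' @export
bma_states <- function(S, q) {
  if (is.list(S)) S <- do.call(rbind, S)
  stopifnot(nrow(S) == length(q))
  drop(crossprod(S, q))
}

#' Select a saccade from the policy posterior
#'
#' @param q Probability vector over policies.
#' @param mode `"sample"` draws from `q`; `"argmax"` returns the most
#'   probable policy, ties broken by the lowest index.
#' @param seed Optional integer seed (sets the RNG before sampling);
#'   normally the caller manages the RNG stream instead.
#' @return A 1-based policy index.
#' @export
select_action <- function(q, mode = c("sample", "argmax"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(q >= 0), abs(sum(q) - 1) < 1e-6)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "argmax") which.max(q) else sample.int(length(q), 1L, prob = q)
}
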