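# Independent oracles and fixture generators, built in code at test time.

# random small MDP: Dirichlet-ish random stochastic columns
rand_mdp <- function(n_states = 4, n_out = 3, n_actions = 2, n_modalities = 1) {
  rand_stoch <- function(nr, nc) {
    m <- matrix(stats::rgamma(nr * nc, shape = 1), nr, nc)
    sweep(m, 2, colSums(m), "/")
  }
  A <- replicate(n_modalities, rand_stoch(n_out, n_states), simplify = FALSE)
  B <- replicate(n_actions, rand_stoch(n_states, n_states), simplify = FALSE)
  D <- as.numeric(rand_stoch(n_states, 1))
  toy_mdp(A, B, D)
}

# exact posterior marginals and -ln P(o) by enumerating every state sequence
enum_posterior <- function(model, observations, policy = integer(0)) {
  if (is.null(dim(observations))) observations <- matrix(observations, nrow = 1)
  tt <- max(nrow(observations), length(policy) + 1L)
  n <- model$n_states
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), tt)))
  joint <- apply(seqs, 1, function(ss) {
    p <- model$D[ss[1]]
    if (tt > 1) for (t in 2:tt) p <- p * model$B[[policy[t - 1L]]][ss[t], ss[t - 1L]]
    for (tau in seq_len(nrow(observations))) {
      for (m in seq_along(model$A)) {
        o <- observations[tau, m]
        if (!is.na(o)) p <- p * model$A[[m]][o, ss[tau]]
      }
    }
    p
  })
  evidence <- sum(joint)
  marg <- matrix(0, tt, n)
  for (t in 1:tt) {
    for (s in 1:n) marg[t, s] <- sum(joint[seqs[, t] == s])
  }
  list(posterior = marg / evidence, neg_log_evidence = -log(evidence))
}

# direct-definition salience for a toy model: expected KL from predictive
# prior to outcome-conditional posterior, enumerating outcomes explicitly
enum_salience <- function(model, u, s) {
  s_pred <- drop(model$B[[u]] %*% s)
  total <- 0
  for (A in model$A) {
    for (i in seq_len(nrow(A))) {
      p_o <- sum(A[i, ] * s_pred)
      if (p_o == 0) next
      post <- A[i, ] * s_pred / p_o
      keep <- post > 0
      total <- total + p_o * sum(post[keep] * (log(post[keep]) - log(s_pred[keep])))
    }
  }
  total
}

# balanced fixture display + flat/multiscale models under default config
fixture_display <- function(seed = 1, n_targets = 16) {
  generate_display(n_targets, "balanced", seed = seed)
}

median_over_seeds <- function(seeds, f) stats::median(vapply(seeds, f, numeric(1)))

# internal helpers under test
hemifield_mask_for_test <- neglectr:::hemifield_mask
scale_mask_for_test <- neglectr:::scale_side_mask

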