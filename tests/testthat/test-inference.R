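test_that("state beliefs match brute-force enumeration on random small models", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    tt <- sample(1:3, 1)
    m <- rand_mdp(n_states = n, n_out = 3, n_actions = 2,
                  n_modalities = sample(1:2, 1))
    policy <- sample(1:2, tt - 1, replace = TRUE)
    obs <- matrix(sample(1:3, tt * length(m$A), replace = TRUE), tt, length(m$A))
    fit <- update_state_beliefs(m, obs, policy)
    oracle <- enum_posterior(m, obs, policy)
    expect_equal(fit$posterior, oracle$posterior, tolerance = 1e-6)
    expect_equal(rowSums(fit$posterior), rep(1, tt), tolerance = 1e-10)
  }
})

test_that("identity proprioception gives a certain location posterior", {
  d <- fixture_display(1)
  m <- build_flat_model(d)
  m$D <- rep(1 / 64, 64) # agnostic prior: proprioception must resolve it
  obs <- matrix(c(NA, 23L), 1, 2) # proprioceptive outcome only
  fit <- update_state_beliefs(m, obs)
  expect_equal(which(fit$posterior[1, ] == 1), 23L)
  # no observations, uniform prior -> uniform posterior
  m2 <- rand_mdp(4, 3, 1)
  m2$D <- rep(0.25, 4)
  fit2 <- update_state_beliefs(m2, matrix(NA_integer_, 1, 1))
  expect_equal(fit2$posterior[1, ], rep(0.25, 4))
})

test_that("free energy bounds surprise, is tight at representable posteriors, and descends", {
  set.seed(11)
  worst_gap <- Inf
  for (rep in 1:100) {
    n <- sample(2:5, 1)
    tt <- sample(1:3, 1)
    m <- rand_mdp(n_states = n, n_out = 3, n_actions = 2)
    policy <- sample(1:2, tt - 1, replace = TRUE)
    obs <- matrix(sample(1:3, tt, replace = TRUE), tt, 1)
    oracle <- enum_posterior(m, obs, policy)
    # arbitrary normalised beliefs respect the bound
    q <- matrix(stats::rgamma(tt * n, 1), tt, n)
    q <- q / rowSums(q)
    expect_gte(free_energy(m, q, obs, policy), oracle$neg_log_evidence - 1e-10)
    # and so do the fitted beliefs
    fit <- update_state_beliefs(m, obs, policy)
    f_fit <- free_energy(m, fit$posterior, obs, policy)
    expect_gte(f_fit, oracle$neg_log_evidence - 1e-10)
    worst_gap <- min(worst_gap, f_fit - oracle$neg_log_evidence)
    # belief updating never increases the free energy from its initialisation
    expect_lte(min(diff(fit$F_trace)), 1e-9)
    expect_lte(fit$F_trace[length(fit$F_trace)], fit$F_trace[1] + 1e-9)
  }
  expect_gte(worst_gap, -1e-10)
  # single time step: the factorised posterior is the exact posterior,
  # so the bound is an equality
  for (rep in 1:20) {
    m <- rand_mdp(n_states = sample(2:6, 1), n_out = 4, n_actions = 1)
    obs <- matrix(sample(1:4, 1), 1, 1)
    fit <- update_state_beliefs(m, obs)
    oracle <- enum_posterior(m, obs)
    expect_equal(free_energy(m, fit$posterior, obs), oracle$neg_log_evidence,
                 tolerance = 1e-10)
  }
})

test_that("expected cost ranks target > empty > cancelled and ignores flat preferences", {
  d <- generate_display(0, seed = 1)
  g <- unclass(d)
  g[10 + 1] <- 1L # a target at index 10
  g[20 + 1] <- 2L # a cancelled target at index 20
  d <- neglectr:::new_display(g)
  m <- build_flat_model(d)
  cost_target <- expected_cost(m, 10)
  cost_empty <- expected_cost(m, 30)
  cost_cancelled <- expected_cost(m, 20)
  expect_lt(cost_target, cost_empty)
  expect_lt(cost_empty, cost_cancelled)
  # uniform preferences in every modality -> cost constant across policies
  m_flatpref <- m
  m_flatpref$modalities$visual$C <- rep(2, 3) # only differences matter
  cost_flat <- efe_terms(m_flatpref)$cost
  expect_lt(max(cost_flat) - min(cost_flat), 1e-12)
  expect_equal(cost_flat[1], log(3) + log(64), tolerance = 1e-12)
})

test_that("salience vanishes under deterministic likelihoods and matches enumeration", {
  # deterministic (identity) likelihood + delta prediction -> zero gain
  d <- fixture_display(1)
  m <- build_flat_model(d)
  expect_equal(salience_term(m, 12), 0)
  # flat cancellation model: identical (zero) for all 64 policies
  sal <- vapply(0:63, function(u) salience_term(m, u), numeric(1))
  expect_lt(max(sal) - min(sal), 1e-10)
  expect_equal(efe_terms(m)$salience, rep(0, 64))
  # noisy 2-state toy: matches the exhaustive outcome enumeration oracle
  set.seed(5)
  for (rep in 1:5) {
    toy <- rand_mdp(n_states = 2, n_out = 3, n_actions = 2, n_modalities = 2)
    s <- c(0.3, 0.7)
    expect_equal(salience_term(toy, 1, s), enum_salience(toy, 1, s),
                 tolerance = 1e-12)
    expect_gte(salience_term(toy, 1, s), 0)
  }
})

test_that("novelty has the Dirichlet-KL closed form and saturates with counts", {
  a <- matrix(c(2, 3, 4), 3, 1)
  # quadrature oracle: KL between the two Dirichlet densities on the simplex
  dir_lpdf <- function(x1, x2, al) {
    lgamma(sum(al)) - sum(lgamma(al)) + (al[1] - 1) * log(x1) +
      (al[2] - 1) * log(x2) + (al[3] - 1) * log(1 - x1 - x2)
  }
  kl_quad <- function(al, be) {
    f <- function(x1, x2) {
      lp <- dir_lpdf(x1, x2, al)
      exp(lp) * (lp - dir_lpdf(x1, x2, be))
    }
    pracma::integral2(Vectorize(f), 0, 1, 0, function(x) 1 - x,
                      reltol = 1e-12)$Q
  }
  p <- as.numeric(a / sum(a))
  oracle <- sum(vapply(1:3, function(i) {
    ap <- a[, 1]
    ap[i] <- ap[i] + 1
    p[i] * kl_quad(ap, a[, 1])
  }, numeric(1)))
  expect_equal(dirichlet_novelty(a, 1), oracle, tolerance = 1e-6)

  # saturation: huge counts -> no novelty; inflation strictly decreases it
  expect_lt(dirichlet_novelty(a * 1e6, 1), 1e-5)
  novs <- vapply(c(1, 2, 5, 20, 100), function(k) dirichlet_novelty(a * k, 1),
                 numeric(1))
  expect_true(all(diff(novs) < 0))
  expect_true(all(novs > 0))
  expect_error(dirichlet_novelty(matrix(c(1, 0), 2, 1), 1), "positive")
})

test_that("vectorised EFE table agrees with the per-policy term functions", {
  d <- fixture_display(3)
  for (build in list(build_flat_model, build_multiscale_model)) {
    m <- build(d)
    ef <- efe_terms(m)
    for (u in c(0L, 9L, 36L, 63L)) {
      expect_equal(ef$cost[u + 1], expected_cost(m, u), tolerance = 1e-10)
      expect_equal(ef$novelty[u + 1], novelty_term(m, u), tolerance = 1e-10)
      expect_equal(ef$salience[u + 1], salience_term(m, u), tolerance = 1e-10)
    }
    expect_equal(ef$G, ef$cost - ef$salience - ef$novelty, tolerance = 1e-10)
    expect_true(all(ef$novelty >= 0))
  }
})

test_that("policy posterior is softmax(ln E - gamma G)", {
  expect_equal(policy_posterior(c(1, 1), c(5, 5), gamma = 0), c(0.5, 0.5))
  expect_equal(policy_posterior(c(1, 2), c(3, 3), gamma = 1), c(1, 2) / 3)
  expect_equal(policy_posterior(c(1, 1), c(1, 2), gamma = 1),
               c(0.7310585786300049, 0.2689414213699951), tolerance = 1e-12)
  q <- policy_posterior(runif(64) + 0.1, rnorm(64), gamma = 2)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_error(policy_posterior(c(1, 1), c(Inf, 0)), "finite")
})

test_that("BMA mixes per-policy posteriors by the policy posterior", {
  s1 <- c(1, 0, 0)
  s2 <- c(0, 0, 1)
  expect_equal(bma_states(rbind(s1), 1), s1)
  expect_equal(bma_states(rbind(s1, s2), c(0.5, 0.5)), c(0.5, 0, 0.5))
  set.seed(2)
  S <- matrix(stats::rgamma(5 * 4, 1), 5, 4)
  S <- S / rowSums(S)
  q <- as.numeric(stats::rgamma(5, 1))
  q <- q / sum(q)
  expect_equal(bma_states(S, q), colSums(q * S), tolerance = 1e-12)
  expect_equal(sum(bma_states(S, q)), 1, tolerance = 1e-12)
})

test_that("action selection is reproducible and matches the posterior in frequency", {
  q_delta <- c(0, 0, 1, 0)
  expect_equal(select_action(q_delta, "sample"), 3L)
  expect_equal(select_action(q_delta, "argmax"), 3L)
  expect_equal(select_action(c(0.5, 0.5), "argmax"), 1L) # tie -> lowest index
  set.seed(99)
  draws1 <- replicate(20, select_action(c(0.2, 0.8)))
  set.seed(99)
  draws2 <- replicate(20, select_action(c(0.2, 0.8)))
  expect_identical(draws1, draws2)
  q <- c(0.1, 0.3, 0.6)
  set.seed(123)
  n <- 1e5
  freq <- tabulate(replicate(n, select_action(q)), 3) / n
  se <- sqrt(q * (1 - q) / n)
  expect_true(all(abs(freq - q) < 3 * se + 1e-12))
  expect_error(select_action(q, "banana"))
})
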