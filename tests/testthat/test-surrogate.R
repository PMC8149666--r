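# Small self-simulated dataset from the surrogate's own generative model.
simulate_mixture_data <- function(n = 400, means = list(c(-2, -2), c(2, 2)),
                                  sds = list(c(1, 1), c(1, 1)),
                                  beta1 = c(0, 4), noise = 1, seed = 1,
                                  task = "regression") {
  set.seed(seed)
  K <- length(means)
  comp <- sample(rep_len(seq_len(K), n))
  X <- t(vapply(comp, function(k)
    stats::rnorm(2, means[[k]], sds[[k]]), numeric(2)))
  mu <- beta1[comp]
  y <- if (task == "regression") stats::rnorm(n, mu, noise)
       else stats::rbinom(n, 1, stats::plogis(mu))
  sch <- variable_schema(c("x1", "x2", "y"), "continuous",
                         c("explanatory", "explanatory", "response"),
                         intervenable = c(TRUE, TRUE, FALSE))
  data <- as_dataset(data.frame(x1 = X[, 1], x2 = X[, 2], y = y), sch)
  list(data = data, y = y, comp = comp)
}

fast_mcmc <- function(seed = 1, chains = 1)
  mcmc_control(iterations = 300, warmup = 150, chains = chains, seed = seed)

test_that("fixed response noise is exactly half the held-out RMSE", {
  sim <- simulate_mixture_data(n = 80, seed = 2)
  m <- fit_surrogate(sim$data, sim$y, K = 1, task = "regression",
                     rmse_test = 4, mcmc = fast_mcmc())
  expect_identical(m$sigma, 2)
  expect_error(fit_surrogate(sim$data, sim$y, K = 1, task = "regression",
                             mcmc = fast_mcmc()),
               "rmse_test")
})

test_that("draws respect simplex, positivity and bookkeeping invariants", {
  sim <- simulate_mixture_data(n = 120, seed = 3)
  m <- fit_surrogate(sim$data, sim$y, K = 3, task = "regression",
                     rmse_test = 2, mcmc = fast_mcmc(chains = 2))
  expect_equal(nrow(m$draws), 2 * (300 - 150))  # chains x (iter - warmup)
  ex <- actionpath:::extract_draws(m)
  expect_true(all(abs(rowSums(ex$pi) - 1) < 1e-8))
  expect_true(all(ex$pi > 0))
  expect_true(all(ex$sd > 0))
  # K = 1: the mixture weight is identically one in every draw
  m1 <- fit_surrogate(sim$data, sim$y, K = 1, task = "regression",
                      rmse_test = 2, mcmc = fast_mcmc())
  expect_true(all(actionpath:::extract_draws(m1)$pi == 1))
  expect_error(fit_surrogate(sim$data, sim$y, K = 0, task = "regression",
                             rmse_test = 2), "K")
  expect_error(fit_surrogate(sim$data, sim$y[-1], K = 1, task = "regression",
                             rmse_test = 2), "y_pred")
})

test_that("state log density matches an independently coded mixture formula", {
  for (with_disc in c(FALSE, TRUE)) {
    model <- random_draws_model(seed = 17 + with_disc, with_disc = with_disc)
    for (trial in 1:5) {
      set.seed(100 + trial)
      x <- stats::rnorm(2)
      g <- sample(c("a", "b", "c"), 1)
      y <- stats::rnorm(1)
      state <- if (with_disc) data.frame(x1 = x[1], x2 = x[2], g = g)
               else data.frame(x1 = x[1], x2 = x[2])
      got <- log_state_probability(model, state, y = y)
      want <- mixture_logdensity_oracle(model, x,
                                        if (with_disc) match(g, c("a", "b", "c"))
                                        else integer(0), y = y)
      expect_equal(got, want, tolerance = 1e-10)
      # response term can be disabled
      got2 <- log_state_probability(model, state, include_response = FALSE)
      want2 <- mixture_logdensity_oracle(model, x,
                                         if (with_disc) match(g, c("a", "b", "c"))
                                         else integer(0),
                                         include_response = FALSE)
      expect_equal(got2, want2, tolerance = 1e-10)
    }
  }
})

test_that("classification state density matches the Bernoulli-head formula", {
  model <- random_draws_model(seed = 5, task = "classification")
  for (y in c(0, 1)) {
    got <- log_state_probability(model, data.frame(x1 = 0.4, x2 = -1), y = y)
    want <- mixture_logdensity_oracle(model, c(0.4, -1), y = y)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("density is invariant to component relabeling and duplication", {
  # a single standard-normal component at its mode, response disabled
  one <- surrogate_from_draws(pi = matrix(1, 1, 1),
                              m = array(0, c(1, 1, 2)),
                              sd = array(1, c(1, 1, 2)))
  expect_equal(log_state_probability(one, data.frame(x1 = 0, x2 = 0),
                                     include_response = FALSE),
               -log(2 * pi), tolerance = 1e-12)
  # two identical components == one component
  two <- surrogate_from_draws(pi = matrix(0.5, 1, 2),
                              m = array(0, c(1, 2, 2)),
                              sd = array(1, c(1, 2, 2)))
  x <- data.frame(x1 = 0.7, x2 = -0.2)
  expect_equal(log_state_probability(two, x, include_response = FALSE),
               log_state_probability(one, x, include_response = FALSE),
               tolerance = 1e-12)
  # label switching: permuting the components of every draw changes nothing
  model <- random_draws_model(seed = 23)
  ex <- actionpath:::extract_draws(model)
  perm <- surrogate_from_draws(pi = ex$pi[, 2:1],
                               m = ex$m[, 2:1, , drop = FALSE],
                               sd = ex$sd[, 2:1, , drop = FALSE],
                               beta1 = ex$beta1[, 2:1],
                               eta2 = ex$eta2[, 2:1, , drop = FALSE],
                               sigma = model$sigma)
  st <- data.frame(x1 = 0.3, x2 = 0.9)
  expect_equal(log_state_probability(perm, st, y = 0.5),
               log_state_probability(model, st, y = 0.5), tolerance = 1e-10)
})

test_that("WBIC prefers the true component count on separated data", {
  for (seed in 1:3) {
    sim <- simulate_mixture_data(n = 300, seed = seed)
    w1 <- as.numeric(wbic(sim$data, sim$y, 1, "regression", rmse_test = 2,
                          mcmc = fast_mcmc(seed = seed)))
    w2 <- as.numeric(wbic(sim$data, sim$y, 2, "regression", rmse_test = 2,
                          mcmc = fast_mcmc(seed = seed)))
    expect_lt(w2, w1)
  }
  # determinism under a fixed seed
  sim <- simulate_mixture_data(n = 100, seed = 9)
  wa <- as.numeric(wbic(sim$data, sim$y, 2, "regression", rmse_test = 2,
                        mcmc = fast_mcmc(seed = 4)))
  wb <- as.numeric(wbic(sim$data, sim$y, 2, "regression", rmse_test = 2,
                        mcmc = fast_mcmc(seed = 4)))
  expect_identical(wa, wb)
  # the tempered regime needs log n > 1
  tiny <- subset(sim$data$data, seq_len(nrow(sim$data$data)) <= 2)
  sch <- sim$data$schema
  expect_error(wbic(as_dataset(tiny, sch), sim$y[1:2], 1, "regression",
                    rmse_test = 2), "n >= 3")
  # singleton k_range returns trivially
  sel <- select_k_by_wbic(sim$data, sim$y, k_range = 3, task = "regression",
                          rmse_test = 2, mcmc = fast_mcmc(seed = 5))
  expect_equal(sel$best_k, 3)
  expect_equal(nrow(sel$wbic), 1)
})

test_that("classification surrogate recovers well-separated component means", {
  sim <- simulate_mixture_data(n = 300, seed = 6, beta1 = c(-2, 2),
                               task = "classification")
  m <- fit_surrogate(sim$data, sim$y, K = 2, task = "classification",
                     mcmc = mcmc_control(iterations = 400, warmup = 200,
                                         chains = 1, seed = 7))
  pm <- posterior_component_means(m)
  truth <- rbind(c(-2, -2), c(2, 2))
  err <- min(vapply(actionpath:::all_perms(2), function(p)
    max(abs(pm[p, ] - truth)), 0))
  expect_lt(err, 0.2)
})
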