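#' MCMC control settings for surrogate fitting
#'
#' Defaults follow the reference procedure: 1500 iterations per chain of
#' which 500 are warm-up, so each chain contributes 1000 retained draws.
#' Four chains are run by default so that split-chain scale-reduction
#' diagnostics can be computed.
#'
#' @param iterations sampler sweeps per chain, including warm-up.
#' @param warmup warm-up sweeps discarded per chain.
#' @param chains number of chains.
#' @param seed integer base seed; chain seeds are derived from it.
#' @return list of class `ap_mcmc_control`.
#' @export
mcmc_control <- function(iterations = 1500L, warmup = 500L, chains = 4L,
                         seed = 1L) {
  stopifnot(iterations > warmup, warmup >= 2, chains >= 1)
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 chains = as.integer(chains), seed = seed),
            class = "ap_mcmc_control")
}

#' Prior hyperparameters of the surrogate
#'
#' Component means get independent Normal(0, `m_sd`) priors, per-coordinate
#' standard deviations half-Cauchy(0, `cauchy_scale`), mixture weights and
#' category probabilities flat Dirichlet(1), and response-head coefficients
#' double-exponential (Laplace) with unit scale. Regression intercepts are
#' Normal(`y_mean`, 5 `y_std`) on the prediction scale; classification
#' intercepts Normal(0, 5).
#'
#' @param m_sd,cauchy_scale prior scales (defaults 5 and 2.5).
#' @return list of class `ap_surrogate_prior`.
#' @export
surrogate_prior <- function(m_sd = 5, cauchy_scale = 2.5) {
  structure(list(m_sd = m_sd, cauchy_scale = cauchy_scale),
            class = "ap_surrogate_prior")
}

# Parameter layout mirroring src/surrogate_density.cpp.
par_layout <- function(K, dc, Cj) {
  D <- sum(Cj)
  p <- 0L
  o <- list(K = K, dc = dc, Cj = Cj, D = D)
  o$upi <- p; p <- p + K - 1L
  o$m <- p; p <- p + K * dc
  o$ls <- p; p <- p + K * dc
  o$phi <- p; p <- p + K * sum(pmax(Cj - 1L, 0L))
  o$b1 <- p; p <- p + K
  o$e2 <- p; p <- p + K * dc
  o$e3 <- p; p <- p + K * D
  o$P <- p
  o
}

simplex_to_unconstrained <- function(p) {
  K <- length(p)
  if (K == 1L) return(numeric(0))
  u <- numeric(K - 1L)
  rest <- 1
  for (k in seq_len(K - 1L)) {
    z <- min(max(p[k] / rest, 1e-10), 1 - 1e-10)
    u[k] <- log(z / (1 - z)) + log(K - k)
    rest <- rest - p[k]
  }
  u
}

unconstrained_to_simplex <- function(u) {
  K <- length(u) + 1L
  p <- numeric(K)
  rest <- 1
  for (k in seq_len(K - 1L)) {
    z <- stats::plogis(u[k] - log(K - k))
    p[k] <- rest * z
    rest <- rest - p[k]
  }
  p[K] <- rest
  p
}

# Pack constrained parameters into the unconstrained vector the sampler uses.
pack_params <- function(pi, m, s, phi, b1, e2, e3, K, dc, Cj) {
  th <- simplex_to_unconstrained(pi)
  th <- c(th, as.numeric(t(m)))        # m is K x dc, row-major per component
  th <- c(th, log(as.numeric(t(s))))
  for (j in seq_along(Cj)) {
    for (k in seq_len(K)) th <- c(th, simplex_to_unconstrained(phi[[j]][k, ]))
  }
  c(th, b1, as.numeric(t(e2)),
    if (sum(Cj) > 0) as.numeric(t(e3)) else numeric(0))
}

# Unpack an S x P draw matrix into constrained arrays.
extract_draws <- function(model) {
  K <- model$K
  dc <- length(model$cont_vars)
  Cj <- model$Cj
  D <- sum(Cj)
  lay <- par_layout(K, dc, Cj)
  th <- model$draws
  S <- nrow(th)
  get_block <- function(off, len) th[, off + seq_len(len), drop = FALSE]
  pi <- if (K == 1L) matrix(1, S, 1)
        else t(apply(get_block(lay$upi, K - 1L), 1, unconstrained_to_simplex))
  m <- aperm(array(t(get_block(lay$m, K * dc)), dim = c(dc, K, S)), c(3, 2, 1))
  s <- aperm(array(t(exp(get_block(lay$ls, K * dc))), dim = c(dc, K, S)),
             c(3, 2, 1))
  phi <- list()
  pos <- lay$phi
  for (j in seq_along(Cj)) {
    C <- Cj[j]
    arr <- array(NA_real_, dim = c(S, K, C))
    for (k in seq_len(K)) {
      u <- get_block(pos, C - 1L)
      arr[, k, ] <- t(apply(u, 1, unconstrained_to_simplex))
      pos <- pos + C - 1L
    }
    phi[[j]] <- arr
  }
  b1 <- get_block(lay$b1, K)
  e2 <- aperm(array(t(get_block(lay$e2, K * dc)), dim = c(dc, K, S)),
              c(3, 2, 1))
  e3 <- if (D > 0)
    aperm(array(t(get_block(lay$e3, K * D)), dim = c(D, K, S)), c(3, 2, 1))
  else NULL
  list(pi = pi, m = m, sd = s, phi = phi, beta1 = b1, eta2 = e2, eta3 = e3)
}

# Design matrices the surrogate consumes: standardized continuous explanatory
# values and 1-based category indices for discrete explanatory values.
surrogate_matrices <- function(df, schema, cont_vars, disc_vars, categories) {
  Xc <- as.matrix(as.data.frame(lapply(df[cont_vars], as.numeric)))
  if (length(cont_vars) == 0) Xc <- matrix(0, nrow(df), 0)
  Xd <- matrix(0L, nrow(df), length(disc_vars))
  for (j in seq_along(disc_vars)) {
    v <- disc_vars[j]
    idx <- match(df[[v]], categories[[v]])
    if (anyNA(idx) && !anyNA(df[[v]]))
      stop("unknown category in '", v, "'")
    if (anyNA(idx)) stop("missing value in discrete variable '", v, "'")
    Xd[, j] <- idx
  }
  storage.mode(Xc) <- "double"
  list(Xc = Xc, Xd = Xd)
}

init_theta_kmeans <- function(Xc, Xd, y, K, Cj, task, seed) {
  dc <- ncol(Xc)
  n <- nrow(Xc)
  local_seed(seed, {
    if (K == 1L) {
      cl <- rep(1L, n)
      centers <- matrix(colMeans(Xc), 1, dc)
    } else if (dc > 0) {
      km <- suppressWarnings(stats::kmeans(Xc, centers = K, nstart = 3))
      cl <- km$cluster
      centers <- km$centers
    } else {
      cl <- sample(rep_len(seq_len(K), n))
      centers <- matrix(0, K, 0)
    }
    pi <- as.numeric(table(factor(cl, levels = seq_len(K)))) / n
    pi <- (pi + 0.05) / sum(pi + 0.05)
    m <- centers
    s <- matrix(1, K, dc)
    for (k in seq_len(K)) {
      rows <- which(cl == k)
      if (length(rows) > 2 && dc > 0)
        s[k, ] <- pmax(apply(Xc[rows, , drop = FALSE], 2, stats::sd), 0.3)
    }
    phi <- lapply(seq_along(Cj), function(j) {
      C <- Cj[j]
      pr <- matrix(NA_real_, K, C)
      for (k in seq_len(K)) {
        cnt <- table(factor(Xd[cl == k, j], levels = seq_len(C)))
        pr[k, ] <- (as.numeric(cnt) + 1) / sum(as.numeric(cnt) + 1)
      }
      pr
    })
    b1 <- vapply(seq_len(K), function(k) {
      yy <- y[cl == k]
      if (task == "regression") mean(yy) else 0
    }, 0)
    e2 <- matrix(0, K, dc)
    e3 <- matrix(0, K, sum(Cj))
    th <- pack_params(pi, m, s, phi, b1, e2, e3, K, dc, Cj)
    th + stats::rnorm(length(th), 0, 0.05)
  })
}

fit_surrogate_engine <- function(Xc, Xd, y, K, task, sigma, y_mean, y_std,
                                 prior, mcmc, temperature) {
  Cj <- if (ncol(Xd) > 0) apply(Xd, 2, max) else integer(0)
  Cj <- as.integer(Cj)
  task_i <- if (task == "regression") 0L else 1L
  b1_mean <- if (task == "regression") y_mean else 0
  b1_sd <- if (task == "regression") 5 * y_std else 5
  lp_fun <- function(theta) {
    ap_log_posterior(theta, Xc, Xd, y, task_i, sigma, prior$m_sd,
                     prior$cauchy_scale, b1_mean, b1_sd, temperature, K, Cj)
  }
  draws <- NULL
  chain_id <- integer(0)
  for (ch in seq_len(mcmc$chains)) {
    seed_ch <- derive_seed(mcmc$seed, K, ch, round(temperature * 1e6))
    th0 <- init_theta_kmeans(Xc, Xd, y, K, Cj, task, seed_ch)
    d <- run_slice_chain(th0, lp_fun, mcmc$iterations, mcmc$warmup,
                         seed = derive_seed(seed_ch, 2L))
    draws <- rbind(draws, d)
    chain_id <- c(chain_id, rep(ch, nrow(d)))
  }
  list(draws = draws, chain = chain_id, Cj = Cj, b1_mean = b1_mean,
       b1_sd = b1_sd)
}

#' Fit the stochastic surrogate model (Step 2)
#'
#' Fits a hierarchical Bayesian mixture to the explanatory variables and the
#' prediction model's outputs. Per mixture component the generative model is:
#' continuous variables Normal with component mean and diagonal covariance,
#' discrete variables Categorical, and the predicted response Normal around a
#' component-specific linear head (regression, with fixed noise
#' `sigma = rmse_test / 2`) or Bernoulli through a logistic link
#' (classification). Component labels are marginalized analytically and all
#' remaining parameters are sampled by component-wise slice sampling in an
#' unconstrained parameterization.
#'
#' The classification surrogate trains by default on the predicted class
#' label at threshold 0.5; set `class_target = "probability"` to weight the
#' Bernoulli likelihood by the predicted probability instead.
#'
#' @param data `ap_dataset` of training rows, already standardized (continuous
#'   explanatory variables) and 3-sigma filtered; no missing cells.
#' @param y_pred prediction-model outputs aligned with the rows of `data`.
#' @param K number of mixture components (>= 1).
#' @param task `"regression"` or `"classification"`.
#' @param rmse_test held-out RMSE of the regression model (required for
#'   regression; the fixed response noise is exactly half of it).
#' @param mcmc an [mcmc_control()].
#' @param prior an [surrogate_prior()].
#' @param temperature inverse temperature of the likelihood (1 for the
#'   ordinary posterior; [wbic()] uses `1/log(n)`).
#' @param class_target `"label"` or `"probability"` (classification only).
#' @return An object of class `surrogate_model` holding the retained draws
#'   (`chains * (iterations - warmup)` of them), the fixed `sigma`, prediction
#'   scale constants, and split-chain scale-reduction diagnostics (when at
#'   least two chains are run).
#' @export
fit_surrogate <- function(data, y_pred, K, task = c("regression", "classification"),
                          rmse_test = NULL, mcmc = mcmc_control(),
                          prior = surrogate_prior(), temperature = 1,
                          class_target = c("label", "probability")) {
  task <- match.arg(task)
  class_target <- match.arg(class_target)
  if (K < 1) stop("K must be >= 1")
  schema <- data$schema
  if (length(y_pred) != n_instances(data))
    stop("y_pred length (", length(y_pred), ") does not match data rows (",
         n_instances(data), ")")
  if (any(data$mask)) stop("data has missing cells; impute first")
  cont_vars <- continuous_vars(schema, role = "explanatory")
  disc_vars <- discrete_vars(schema, role = "explanatory")
  categories <- stats::setNames(
    lapply(disc_vars, function(v) var_categories(schema, v)), disc_vars)
  mats <- surrogate_matrices(data$data, schema, cont_vars, disc_vars,
                             categories)
  if (task == "regression") {
    if (is.null(rmse_test))
      stop("rmse_test is required for a regression surrogate (sigma = rmse_test/2)")
    sigma <- rmse_test / 2
    y <- as.numeric(y_pred)
    y_mean <- mean(y)
    y_std <- stats::sd(y)
    if (!is.finite(y_std) || y_std == 0) y_std <- 1
  } else {
    sigma <- 0
    y <- if (class_target == "label") as.numeric(y_pred >= 0.5)
         else as.numeric(y_pred)
    y_mean <- mean(y)
    y_std <- 1
  }
  fit <- fit_surrogate_engine(mats$Xc, mats$Xd, y, K, task, sigma,
                              y_mean, y_std, prior, mcmc, temperature)
  rhat <- split_rhat(fit$draws, fit$chain)
  model <- structure(
    list(K = as.integer(K), task = task, sigma = sigma,
         y_mean = y_mean, y_std = y_std, prior = prior,
         draws = fit$draws, chain = fit$chain,
         cont_vars = cont_vars, disc_vars = disc_vars,
         categories = categories, Cj = fit$Cj,
         mcmc = c(unclass(mcmc), list(temperature = temperature)),
         rhat = rhat, wbic = NA_real_),
    class = "surrogate_model")
  model
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("<surrogate_model> K =", x$K, " task:", x$task,
      " draws:", nrow(x$draws), "\n")
  if (x$task == "regression") cat("  sigma (rmse_test/2):", x$sigma, "\n")
  if (!is.null(x$rhat))
    cat("  max split-Rhat:", round(max(x$rhat), 3), "\n")
  if (!is.na(x$wbic)) cat("  WBIC:", x$wbic, "\n")
  invisible(x)
}

state_matrices <- function(model, x) {
  df <- if (inherits(x, "ap_dataset")) x$data
        else if (is.data.frame(x)) x
        else as.data.frame(as.list(x))
  surrogate_matrices(df, NULL, model$cont_vars, model$disc_vars,
                     model$categories)
}

#' Posterior-predictive log probability of a variable state
#'
#' Evaluates the log of the posterior-predictive density of a full
#' explanatory state `x` together with a predicted response `y`: the mean
#' over posterior draws of the mixture density, computed in the log domain.
#' This is the node probability used by the planner. With
#' `include_response = FALSE`, only the explanatory-variable density is
#' scored.
#'
#' @param model a `surrogate_model`.
#' @param x a data frame (one state per row), named vector or list of
#'   explanatory values.
#' @param y predicted response per row (regression: real value on the
#'   prediction scale; classification: predicted class 0/1). Ignored when
#'   `include_response = FALSE`.
#' @param include_response score the response term as well? Default `TRUE`.
#' @return Numeric vector of log densities, one per row; finite for all
#'   finite inputs.
#' @export
log_state_probability <- function(model, x, y = NULL,
                                  include_response = TRUE) {
  mats <- state_matrices(model, x)
  n <- nrow(mats$Xc)
  if (include_response) {
    if (is.null(y)) stop("y is required when include_response = TRUE")
    y <- rep_len(as.numeric(y), n)
    if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  } else {
    y <- rep(0, n)
  }
  if (anyNA(mats$Xc) || any(!is.finite(mats$Xc)))
    stop("x must be finite and complete")
  ap_state_logdensity(model$draws, mats$Xc, mats$Xd, y,
                      as.integer(include_response),
                      if (model$task == "regression") 0L else 1L,
                      model$sigma, model$K, as.integer(model$Cj))
}

total_loglik_per_draw <- function(model, Xc, Xd, y) {
  task_i <- if (model$task == "regression") 0L else 1L
  vapply(seq_len(nrow(model$draws)), function(s) {
    sum(ap_loglik_rows(model$draws[s, ], Xc, Xd, y, task_i, model$sigma,
                       model$K, as.integer(model$Cj)))
  }, 0)
}

#' Widely applicable Bayesian information criterion for a component count
#'
#' Samples the surrogate posterior at inverse temperature `1/log(n)` and
#' returns the expectation, over those tempered draws, of the total negative
#' log-likelihood of the data. Lower is better.
#'
#' @inheritParams fit_surrogate
#' @return The WBIC value (numeric scalar), with the tempered fit attached as
#'   attribute `model`.
#' @export
wbic <- function(data, y_pred, K, task = c("regression", "classification"),
                 rmse_test = NULL, mcmc = mcmc_control(),
                 prior = surrogate_prior(),
                 class_target = c("label", "probability")) {
  task <- match.arg(task)
  n <- n_instances(data)
  if (n < 3) stop("WBIC needs n >= 3 (log n must exceed 1)")
  model <- fit_surrogate(data, y_pred, K, task, rmse_test = rmse_test,
                         mcmc = mcmc, prior = prior,
                         temperature = 1 / log(n),
                         class_target = class_target)
  mats <- state_matrices(model, data)
  y <- if (task == "regression") as.numeric(y_pred)
       else if (match.arg(class_target) == "label") as.numeric(y_pred >= 0.5)
       else as.numeric(y_pred)
  ll <- total_loglik_per_draw(model, mats$Xc, mats$Xd, y)
  val <- mean(-ll)
  model$wbic <- val
  attr(val, "model") <- model
  val
}

#' Select the number of mixture components by WBIC
#'
#' Computes [wbic()] for every candidate component count and returns the
#' minimizer together with the full WBIC curve for reporting.
#'
#' @inheritParams fit_surrogate
#' @param k_range candidate component counts (default 1 to 8).
#' @return list with `best_k`, `wbic` (data frame of K and WBIC), and
#'   `models` (the tempered fits, named by K).
#' @export
select_k_by_wbic <- function(data, y_pred, k_range = 1:8,
                             task = c("regression", "classification"),
                             rmse_test = NULL, mcmc = mcmc_control(),
                             prior = surrogate_prior(),
                             class_target = c("label", "probability")) {
  if (length(k_range) == 0) stop("k_range is empty")
  task <- match.arg(task)
  vals <- numeric(length(k_range))
  models <- list()
  for (i in seq_along(k_range)) {
    v <- wbic(data, y_pred, k_range[i], task, rmse_test = rmse_test,
              mcmc = mcmc, prior = prior, class_target = class_target)
    models[[as.character(k_range[i])]] <- attr(v, "model")
    vals[i] <- as.numeric(v)
  }
  list(best_k = k_range[which.min(vals)],
       wbic = data.frame(K = k_range, wbic = vals),
       models = models)
}

#' Build a surrogate model from explicit parameter draws
#'
#' Constructs a `surrogate_model` directly from given mixture parameters -
#' one draw per element of the supplied lists - without any sampling. Used
#' for simulation studies, quadrature checks and tests; the resulting object
#' supports [log_state_probability()] exactly like a fitted one.
#'
#' @param pi matrix S x K of mixture weights (rows sum to 1).
#' @param m,sd arrays S x K x d of component means / standard deviations.
#' @param phi optional list (one per discrete variable) of S x K x C arrays
#'   of category probabilities.
#' @param beta1 S x K intercepts (default 0).
#' @param eta2 S x K x d continuous coefficients (default 0).
#' @param eta3 optional S x K x D one-hot coefficients (default 0).
#' @param task,sigma response model; `sigma` is the fixed regression noise.
#' @param cont_vars,disc_vars,categories variable naming for state lookups.
#' @return A `surrogate_model`.
#' @export
surrogate_from_draws <- function(pi, m, sd, phi = NULL, beta1 = NULL,
                                 eta2 = NULL, eta3 = NULL,
                                 task = "regression", sigma = 1,
                                 cont_vars = NULL, disc_vars = character(0),
                                 categories = list()) {
  S <- nrow(pi)
  K <- ncol(pi)
  dc <- dim(m)[3]
  if (is.null(cont_vars)) cont_vars <- paste0("x", seq_len(dc))
  Cj <- as.integer(vapply(categories, length, 0L))
  D <- sum(Cj)
  if (is.null(beta1)) beta1 <- matrix(0, S, K)
  if (is.null(eta2)) eta2 <- array(0, dim = c(S, K, dc))
  if (is.null(eta3) && D > 0) eta3 <- array(0, dim = c(S, K, D))
  draws <- t(vapply(seq_len(S), function(s) {
    phis <- lapply(seq_along(Cj), function(j)
      matrix(phi[[j]][s, , ], K, Cj[j]))
    pack_params(pi[s, ], matrix(m[s, , ], K, dc), matrix(sd[s, , ], K, dc),
                phis, beta1[s, ],
                matrix(eta2[s, , ], K, dc),
                if (D > 0) matrix(eta3[s, , ], K, D) else matrix(0, K, 0),
                K, dc, Cj)
  }, numeric(par_layout(K, dc, Cj)$P)))
  if (S == 1L) draws <- matrix(draws, nrow = 1)
  structure(
    list(K = K, task = task, sigma = sigma, y_mean = 0, y_std = 1,
         prior = surrogate_prior(), draws = draws,
         chain = rep(1L, S), cont_vars = cont_vars, disc_vars = disc_vars,
         categories = categories, Cj = Cj,
         mcmc = list(iterations = S, warmup = 0, chains = 1, seed = NA,
                     temperature = 1),
         rhat = NULL, wbic = NA_real_),
    class = "surrogate_model")
}

#' Posterior component means after label alignment
#'
#' Mixture posteriors are invariant under component relabeling, so draws are
#' aligned before averaging: within each chain, each draw keeps its sampled
#' labels (slice chains do not hop modes in practice), chains are aligned to
#' the first chain by the component-mean permutation minimizing squared
#' distance, and the pooled mean is returned.
#'
#' @param model a `surrogate_model`.
#' @return K x d matrix of aligned posterior component means.
#' @export
posterior_component_means <- function(model) {
  ex <- extract_draws(model)
  K <- model$K
  dc <- length(model$cont_vars)
  chain_means <- lapply(unique(model$chain), function(ch) {
    rows <- model$chain == ch
    matrix(apply(ex$m[rows, , , drop = FALSE], c(2, 3), mean), K, dc)
  })
  ref <- chain_means[[1]]
  aligned <- lapply(chain_means, function(cm) {
    best <- NULL
    best_d <- Inf
    for (p in all_perms(K)) {
      d <- sum((cm[p, , drop = FALSE] - ref)^2)
      if (d < best_d) {
        best_d <- d
        best <- cm[p, , drop = FALSE]
      }
    }
    best
  })
  out <- Reduce(`+`, aligned) / length(aligned)
  dimnames(out) <- list(paste0("k", seq_len(K)), model$cont_vars)
  out
}
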