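# Shared fixtures and independent oracles, all built in code.

# Mixed-type schema: two intervenable continuous variables, one discrete,
# one continuous response.
mixed_schema <- function() {
  variable_schema(
    name = c("x1", "x2", "sex", "y"),
    kind = c("continuous", "continuous", "discrete", "continuous"),
    role = c("explanatory", "explanatory", "explanatory", "response"),
    intervenable = c(TRUE, TRUE, FALSE, FALSE),
    direction = c("decrease", "decrease", "free", "free"),
    categories = list(sex = c("F", "M"))
  )
}

# A grid over abstract offset space, for planner tests driven by stub
# evaluators (origin 0, unit steps).
stub_grid <- function(lower, upper, directions = NULL) {
  d <- length(lower)
  vars <- paste0("v", seq_len(d))
  if (is.null(directions)) directions <- rep("decrease", d)
  schema <- variable_schema(
    name = c(vars, "y"), kind = "continuous",
    role = c(rep("explanatory", d), "response"),
    intervenable = c(rep(TRUE, d), FALSE),
    direction = c(directions, "free"))
  structure(list(vars = vars,
                 origin = stats::setNames(rep(0, d), vars),
                 step = stats::setNames(rep(1, d), vars),
                 lower = stats::setNames(as.integer(lower), vars),
                 upper = stats::setNames(as.integer(upper), vars),
                 instance = as.data.frame(as.list(stats::setNames(rep(0, d), vars))),
                 schema = schema),
            class = "ap_grid")
}

# Evaluator driven by closed-form functions of the offsets.
stub_evaluator <- function(logp_fun, pred_fun) {
  function(offsets) {
    if (is.null(dim(offsets))) offsets <- matrix(offsets, nrow = 1)
    data.frame(
      key = apply(offsets, 1, paste, collapse = ","),
      logp = apply(offsets, 1, logp_fun),
      pred = apply(offsets, 1, pred_fun),
      stringsAsFactors = FALSE)
  }
}

grid_nodes <- function(grid) {
  ranges <- lapply(seq_along(grid$vars),
                   function(i) grid$lower[i]:grid$upper[i])
  m <- as.matrix(expand.grid(ranges))
  dimnames(m) <- list(NULL, grid$vars)
  m
}

# Independent shortest-path oracle: Bellman-Ford over the node-weighted
# lattice (weight of entering a node = -logp; the start node's own weight is
# charged once).
bellman_ford_costs <- function(grid, logp_fun) {
  nodes <- grid_nodes(grid)
  keys <- apply(nodes, 1, paste, collapse = ",")
  w <- -apply(nodes, 1, logp_fun)
  dist <- stats::setNames(rep(Inf, nrow(nodes)), keys)
  start_key <- paste(rep(0L, ncol(nodes)), collapse = ",")
  dist[start_key] <- w[match(start_key, keys)]
  nb_keys <- lapply(seq_len(nrow(nodes)), function(i) {
    nb <- neighbors(nodes[i, ], grid)
    if (nrow(nb) == 0) character(0) else apply(nb, 1, paste, collapse = ",")
  })
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(nodes))) {
      if (!is.finite(dist[i])) next
      for (k2 in nb_keys[[i]]) {
        nd <- dist[i] + w[match(k2, keys)]
        if (nd < dist[k2]) {
          dist[k2] <- nd
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

# Fully independent exhaustive oracle for tiny grids: depth-first search over
# all simple paths from the start, tracking the best cost per node.
exhaustive_costs <- function(grid, logp_fun) {
  nodes <- grid_nodes(grid)
  keys <- apply(nodes, 1, paste, collapse = ",")
  best <- stats::setNames(rep(Inf, nrow(nodes)), keys)
  start <- rep(0L, ncol(nodes))
  # No pruning: every simple path is enumerated (tiny grids only).
  recurse <- function(offs, visited, cost) {
    key <- paste(offs, collapse = ",")
    cost <- cost - logp_fun(offs)
    if (cost < best[key]) best[key] <<- cost
    nb <- neighbors(offs, grid)
    for (i in seq_len(nrow(nb))) {
      k2 <- paste(nb[i, ], collapse = ",")
      if (!(k2 %in% visited)) recurse(nb[i, ], c(visited, k2), cost)
    }
  }
  recurse(start, paste(start, collapse = ","), 0)
  best
}

# Independent R evaluation of the posterior-predictive mixture log density,
# written directly from the generative formulas.
mixture_logdensity_oracle <- function(model, x_cont, x_disc_idx = integer(0),
                                      y = NULL, include_response = TRUE) {
  ex <- actionpath:::extract_draws(model)
  S <- nrow(ex$pi)
  K <- ncol(ex$pi)
  per_draw <- vapply(seq_len(S), function(s) {
    comp <- vapply(seq_len(K), function(k) {
      v <- log(ex$pi[s, k]) +
        sum(stats::dnorm(x_cont, ex$m[s, k, ], ex$sd[s, k, ], log = TRUE))
      for (j in seq_along(x_disc_idx))
        v <- v + log(ex$phi[[j]][s, k, x_disc_idx[j]])
      if (include_response) {
        mu <- ex$beta1[s, k] + sum(ex$eta2[s, k, ] * x_cont)
        for (j in seq_along(x_disc_idx)) {
          off <- c(0, cumsum(model$Cj))[j]
          mu <- mu + ex$eta3[s, k, off + x_disc_idx[j]]
        }
        if (model$task == "regression") {
          v <- v + stats::dnorm(y, mu, model$sigma, log = TRUE)
        } else {
          th <- stats::plogis(mu)
          v <- v + y * log(th) + (1 - y) * log(1 - th)
        }
      }
      v
    }, 0)
    m <- max(comp)
    m + log(sum(exp(comp - m)))
  }, 0)
  m <- max(per_draw)
  m + log(mean(exp(per_draw - m)))
}

# Random surrogate built from explicit draws (no MCMC), for density tests.
random_draws_model <- function(seed, S = 5, K = 2, d = 2, with_disc = FALSE,
                               task = "regression", sigma = 1.3) {
  set.seed(seed)
  pi <- matrix(stats::rgamma(S * K, 2), S, K)
  pi <- pi / rowSums(pi)
  m <- array(stats::rnorm(S * K * d), dim = c(S, K, d))
  sd <- array(exp(stats::rnorm(S * K * d, 0, 0.3)), dim = c(S, K, d))
  b1 <- matrix(stats::rnorm(S * K), S, K)
  e2 <- array(stats::rnorm(S * K * d, 0, 0.5), dim = c(S, K, d))
  phi <- NULL
  e3 <- NULL
  categories <- list()
  disc_vars <- character(0)
  if (with_disc) {
    C <- 3
    arr <- array(stats::rgamma(S * K * C, 2), dim = c(S, K, C))
    for (s in seq_len(S)) for (k in seq_len(K))
      arr[s, k, ] <- arr[s, k, ] / sum(arr[s, k, ])
    phi <- list(arr)
    e3 <- array(stats::rnorm(S * K * C, 0, 0.5), dim = c(S, K, C))
    categories <- list(g = c("a", "b", "c"))
    disc_vars <- "g"
  }
  surrogate_from_draws(pi, m, sd, phi = phi, beta1 = b1, eta2 = e2, eta3 = e3,
                       task = task, sigma = sigma,
                       cont_vars = paste0("x", seq_len(d)),
                       disc_vars = disc_vars, categories = categories)
}

# Write a dataset data frame to a temp csv and return the path.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}
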