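test_that("grid specs center on the instance and keep offset zero in bounds", {
  d <- standardize(generate_synthetic3d(seed = 2))
  inst <- d$data[5, c("x1", "x2", "x3")]
  g <- grid_spec(inst, d)
  expect_equal(g$vars, c("x1", "x2", "x3"))
  expect_equal(unname(g$origin), unlist(inst, use.names = FALSE))
  expect_true(all(g$step > 0))
  expect_equal(unname(g$step), rep(0.2, 3), tolerance = 0.05)
  expect_true(all(g$lower <= 0 & g$upper >= 0))
  inst_na <- inst
  inst_na$x1 <- NA_real_
  expect_error(grid_spec(inst_na, d), "missing")
  expect_error(grid_spec(inst, d, intervention_vars = "y"), "intervenable")
})

test_that("neighbour enumeration matches brute force on the lattice", {
  g <- stub_grid(lower = c(-2, -2, -2), upper = c(2, 2, 2))
  expect_equal(nrow(neighbors(c(0L, 0L, 0L), g)), 6)  # interior degree 2d
  g2 <- stub_grid(lower = c(0, 0), upper = c(3, 3))
  expect_equal(nrow(neighbors(c(0L, 0L), g2)), 2)     # corner
  set.seed(1)
  for (trial in 1:20) {
    lower <- -sample(0:3, 2)
    upper <- sample(0:3, 2)
    gg <- stub_grid(lower, upper)
    node <- as.integer(c(sample(lower[1]:upper[1], 1),
                         sample(lower[2]:upper[2], 1)))
    got <- neighbors(node, gg)
    # brute force: all +/-1 unit vectors, bound-filtered
    cand <- rbind(node + c(1, 0), node + c(-1, 0),
                  node + c(0, 1), node + c(0, -1))
    keep <- apply(cand, 1, function(x)
      all(x >= lower & x <= upper))
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(cand[keep, , drop = FALSE], 1, paste, collapse = ","))
  }
})

test_that("uniform probabilities reduce planning to best-response descent", {
  g <- stub_grid(lower = c(-3, -3), upper = c(3, 3))
  ev <- stub_evaluator(function(o) log(0.5),
                       function(o) o[1])  # response increases in v1 only
  plan <- plan_path(NULL, NULL, NULL, g, objective = "minimize", L = 1000,
                    evaluator = ev)
  expect_equal(plan$termination, "frontier_empty")
  expect_equal(unname(plan$destination), c(-3L, 0L))
  offs <- plan$path$offsets
  expect_equal(nrow(offs), 4)                       # straight monotone descent
  expect_true(all(diff(offs[, 1]) == -1))
  expect_true(all(offs[, 2] == 0))
})

test_that("ties on predicted response resolve to the cheaper node", {
  g <- stub_grid(lower = c(0, 0), upper = c(1, 1))
  # both (1,0) and (0,1) share the best prediction; (0,1) is cheaper
  logp <- function(o) {
    key <- paste(o, collapse = ",")
    c("0,0" = -1, "1,0" = -3, "0,1" = -1.5, "1,1" = -1)[key]
  }
  pred <- function(o) if (sum(o) == 1) -5 else 0
  plan <- plan_path(NULL, NULL, NULL, g, objective = "minimize", L = 100,
                    evaluator = stub_evaluator(logp, pred))
  expect_equal(unname(plan$destination), c(0L, 1L))
  expect_equal(plan$path$cost, 1 + 1.5, tolerance = 1e-12)
})

test_that("per-node costs are optimal: exhaustive and Bellman-Ford oracles", {
  # fully exhaustive simple-path enumeration on a 3x3 grid
  set.seed(31)
  for (trial in 1:5) {
    g <- stub_grid(lower = c(-1, -1), upper = c(1, 1))
    probs <- stats::setNames(log(stats::runif(9, 0.05, 1)),
                             apply(grid_nodes(g), 1, paste, collapse = ","))
    logp_fun <- function(o) probs[[paste(o, collapse = ",")]]
    plan <- plan_path(NULL, NULL, NULL, g, L = 100,
                      evaluator = stub_evaluator(logp_fun, function(o) 0))
    want <- exhaustive_costs(g, logp_fun)
    got <- stats::setNames(plan$costs$cost, plan$costs$key)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # Bellman-Ford cross-check on larger random grids, exact equality
  for (trial in 1:5) {
    g <- stub_grid(lower = c(-2, -1, -2), upper = c(1, 2, 1))
    nodes <- grid_nodes(g)
    probs <- stats::setNames(log(stats::runif(nrow(nodes), 0.05, 1)),
                             apply(nodes, 1, paste, collapse = ","))
    logp_fun <- function(o) probs[[paste(o, collapse = ",")]]
    plan <- plan_path(NULL, NULL, NULL, g, L = 10000,
                      evaluator = stub_evaluator(logp_fun, function(o) 0))
    want <- bellman_ford_costs(g, logp_fun)
    got <- stats::setNames(plan$costs$cost, plan$costs$key)
    expect_identical(sort(names(got)), sort(names(want)))
    expect_equal(got[names(want)], want, tolerance = 0)
  }
})

test_that("finalization order, path cost and L monotonicity invariants hold", {
  set.seed(77)
  g <- stub_grid(lower = c(-2, -2), upper = c(2, 2))
  nodes <- grid_nodes(g)
  probs <- stats::setNames(log(stats::runif(nrow(nodes), 0.02, 1)),
                           apply(nodes, 1, paste, collapse = ","))
  logp_fun <- function(o) probs[[paste(o, collapse = ",")]]
  pred_fun <- function(o) sum(o)
  ev <- stub_evaluator(logp_fun, pred_fun)
  plan <- plan_path(NULL, NULL, NULL, g, L = 1000, evaluator = ev)
  # min-cost finalization order is non-decreasing in cost
  expect_true(all(diff(plan$costs$cost) >= -1e-12))
  # the returned path's independently recomputed cost matches
  recomputed <- -sum(apply(plan$path$offsets, 1, logp_fun))
  expect_equal(plan$path$cost, recomputed, tolerance = 1e-9)
  expect_equal(plan$path$actionability, exp(-plan$path$cost), tolerance = 1e-9)
  # consecutive path nodes differ by one unit step in one variable
  steps <- diff(plan$path$offsets)
  expect_true(all(rowSums(abs(steps)) == 1))
  # increasing L never worsens the destination's predicted response
  dests <- vapply(c(3, 6, 12, 25), function(L) {
    p <- plan_path(NULL, NULL, NULL, g, L = L, evaluator = ev)
    p$path$pred[length(p$path$pred)]
  }, 0)
  expect_true(all(diff(dests) <= 1e-12))
  # L caps the number of finalizations
  p3 <- plan_path(NULL, NULL, NULL, g, L = 3, evaluator = ev)
  expect_equal(p3$n_expanded, 3)
  expect_equal(p3$termination, "L_exhausted")
})

test_that("fifo expansion converges to the same optimal costs when uncapped", {
  set.seed(13)
  g <- stub_grid(lower = c(-1, -1), upper = c(2, 2))
  nodes <- grid_nodes(g)
  probs <- stats::setNames(log(stats::runif(nrow(nodes), 0.05, 1)),
                           apply(nodes, 1, paste, collapse = ","))
  logp_fun <- function(o) probs[[paste(o, collapse = ",")]]
  ev <- stub_evaluator(logp_fun, function(o) sum(o))
  a <- plan_path(NULL, NULL, NULL, g, L = 10000, evaluator = ev)
  b <- plan_path(NULL, NULL, NULL, g, L = 10000, evaluator = ev,
                 expansion = "fifo")
  ga <- stats::setNames(a$costs$cost, a$costs$key)
  gb <- stats::setNames(b$costs$cost, b$costs$key)
  expect_equal(gb[names(ga)], ga, tolerance = 1e-12)
  expect_equal(b$destination, a$destination)
})

test_that("degenerate and erroneous planner inputs are handled", {
  g <- stub_grid(lower = c(-2, 0), upper = c(2, 0))
  # start already optimal -> single-node path
  ev <- stub_evaluator(function(o) -1, function(o) abs(o[1]))
  plan <- plan_path(NULL, NULL, NULL, g, objective = "minimize", L = 100,
                    evaluator = ev)
  expect_equal(nrow(plan$path$offsets), 1)
  expect_equal(unname(plan$destination), c(0L, 0L))
  # zero-probability start
  ev0 <- stub_evaluator(function(o) -Inf, function(o) 0)
  expect_error(plan_path(NULL, NULL, NULL, g, L = 10, evaluator = ev0),
               "zero probability")
})

test_that("realized paths report original units and per-step changes", {
  d <- generate_synthetic3d(seed = 4)
  parts <- split_train_test(d, 0.8, seed = 1)
  train <- standardize(parts$train, parts$train)
  inst <- train$data[1, c("x1", "x2", "x3")]
  g <- grid_spec(inst, train)
  offs <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, -1L, 0L), c(2L, -1L, 0L))
  colnames(offs) <- g$vars
  path <- actionpath:::new_path(offs, logp = rep(-1, 4), pred = 4:1)
  rep4 <- realize_path(path, standardization = train$standardization, grid = g)
  expect_equal(nrow(rep4), 4)
  expect_equal(rep4$variable[-1], c("x1", "x2", "x1"))
  expect_equal(rep4$direction[-1], c("increase", "decrease", "increase"))
  # step 0 equals the instance in original units
  st <- train$standardization
  expect_equal(rep4$x1[1],
               as.numeric(inst$x1) * st$sd["x1"] + st$mean["x1"],
               tolerance = 1e-12, ignore_attr = TRUE)
  # one grid step in x1 is 0.2 training sd in original units
  expect_equal(rep4$x1[2] - rep4$x1[1],
               unname(g$step["x1"] * st$sd["x1"]), tolerance = 1e-12)
  # single-node path -> single-row report
  p0 <- actionpath:::new_path(offs[1, , drop = FALSE], -1, 2)
  expect_equal(nrow(realize_path(p0, train$standardization, g)), 1)
})
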