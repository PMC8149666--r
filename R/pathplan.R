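#' Discretize the intervention-variable space around an instance
#'
#' Builds the grid graph for path planning: every intervenable variable gets
#' a unit step of `step_sd` training standard deviations (0.2 by default; in
#' standardized units the step is simply `step_sd`), the grid origin is the
#' instance's own values, and offset bounds default to the training data's
#' observed range per variable, clamped to `bounds_sd` standard deviations -
#' the surrogate is not trusted under extrapolation. Bounds always include
#' offset zero.
#'
#' @param instance one-row data frame (or named vector) of the instance's
#'   explanatory values on the same (standardized) scale as `train`.
#' @param train training `ap_dataset` the surrogate was fitted on.
#' @param intervention_vars variables to grid (default: all schema variables
#'   flagged intervenable). Must be continuous, intervenable and free of
#'   missing values in the instance.
#' @param step_sd unit cell size in training standard deviations.
#' @param bounds_sd hard clamp on the grid extent, in standard deviations.
#' @return An object of class `ap_grid` with per-variable origin, step and
#'   integer offset bounds.
#' @export
grid_spec <- function(instance, train, intervention_vars = NULL,
                      step_sd = 0.2, bounds_sd = 4) {
  schema <- train$schema
  if (is.null(intervention_vars)) intervention_vars <- schema$name[schema$intervenable]
  if (length(intervention_vars) == 0) stop("no intervention variables")
  ok <- intervention_vars %in% schema$name[schema$intervenable &
                                           schema$kind == "continuous"]
  if (!all(ok))
    stop("not continuous intervenable variables: ",
         paste(intervention_vars[!ok], collapse = ", "))
  if (step_sd <= 0) stop("step_sd must be positive")
  inst <- if (is.data.frame(instance)) instance else as.data.frame(as.list(instance))
  origin <- vapply(intervention_vars, function(v) as.numeric(inst[[v]][1]), 0)
  if (anyNA(origin))
    stop("instance has missing values in intervention variable(s)")
  # Training scale: sd per variable (1 if the data are standardized).
  sds <- vapply(intervention_vars, function(v) {
    x <- train$data[[v]][!train$mask[, v]]
    stats::sd(x)
  }, 0)
  mns <- vapply(intervention_vars, function(v) {
    x <- train$data[[v]][!train$mask[, v]]
    mean(x)
  }, 0)
  step <- step_sd * sds
  lower <- upper <- stats::setNames(integer(length(intervention_vars)),
                                    intervention_vars)
  for (i in seq_along(intervention_vars)) {
    v <- intervention_vars[i]
    x <- train$data[[v]][!train$mask[, v]]
    lo <- max(min(x), mns[i] - bounds_sd * sds[i])
    hi <- min(max(x), mns[i] + bounds_sd * sds[i])
    lower[v] <- min(0L, as.integer(ceiling((lo - origin[i]) / step[i])))
    upper[v] <- max(0L, as.integer(floor((hi - origin[i]) / step[i])))
  }
  structure(list(vars = intervention_vars,
                 origin = stats::setNames(origin, intervention_vars),
                 step = stats::setNames(step, intervention_vars),
                 lower = lower, upper = upper,
                 instance = inst, schema = schema),
            class = "ap_grid")
}

#' @export
print.ap_grid <- function(x, ...) {
  cat("<ap_grid> ", length(x$vars), " intervention variable(s)\n", sep = "")
  print(data.frame(variable = x$vars, origin = x$origin, step = x$step,
                   lower = x$lower, upper = x$upper, row.names = NULL))
  invisible(x)
}

node_key <- function(offsets) paste(offsets, collapse = ",")

key_to_offsets <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

#' Enumerate grid neighbours of a node
#'
#' All in-bounds offset vectors differing from `offsets` by plus or minus one
#' unit in exactly one variable (at most `2 * d` of them).
#'
#' @param offsets integer offset vector over the grid's variables.
#' @param grid an [grid_spec()].
#' @return Integer matrix, one neighbour per row.
#' @export
neighbors <- function(offsets, grid) {
  d <- length(grid$vars)
  stopifnot(length(offsets) == d)
  out <- matrix(0L, 0L, d)
  for (i in seq_len(d)) {
    for (delta in c(-1L, 1L)) {
      cand <- offsets
      cand[i] <- cand[i] + delta
      if (cand[i] >= grid$lower[i] && cand[i] <= grid$upper[i])
        out <- rbind(out, cand)
    }
  }
  dimnames(out) <- list(NULL, grid$vars)
  out
}

realized_state <- function(offsets, grid) {
  row <- grid$instance
  row[grid$vars] <- as.list(grid$origin + offsets * grid$step)
  row
}

#' Node evaluator: surrogate probability and prediction per grid node
#'
#' Returns a memoizing evaluator used by the planner and the scoring
#' functions. For a matrix of offset vectors it realizes the full explanatory
#' state (instance values with the gridded variables displaced), obtains the
#' prediction-model output, and scores the state's log probability under the
#' surrogate (for classification the response term scores the predicted class
#' label at threshold 0.5).
#'
#' @param surrogate a `surrogate_model`.
#' @param predictor a `prediction_model`.
#' @param grid an [grid_spec()].
#' @param include_response include the response term in the node probability?
#' @return A function `f(offset_matrix) -> data.frame(key, logp, pred)`;
#'   results are cached per offset vector.
#' @export
node_evaluator <- function(surrogate, predictor, grid,
                           include_response = TRUE) {
  memo <- new.env(parent = emptyenv())
  evars <- explanatory_vars(grid$schema)
  function(offsets) {
    if (is.null(dim(offsets))) offsets <- matrix(offsets, nrow = 1)
    keys <- apply(offsets, 1, node_key)
    todo <- !vapply(keys, function(k) exists(k, envir = memo), TRUE)
    if (any(todo)) {
      rows <- do.call(rbind, lapply(which(todo), function(i)
        realized_state(offsets[i, ], grid)))
      rows <- rows[, evars, drop = FALSE]
      pred <- predict_table(predictor, rows)
      y <- if (surrogate$task == "classification") as.numeric(pred >= 0.5)
           else pred
      logp <- log_state_probability(surrogate, rows, y = y,
                                    include_response = include_response)
      for (j in seq_along(which(todo))) {
        i <- which(todo)[j]
        assign(keys[i], list(logp = logp[j], pred = pred[j]), envir = memo)
      }
    }
    vals <- lapply(keys, get, envir = memo)
    data.frame(key = keys,
               logp = vapply(vals, `[[`, 0, "logp"),
               pred = vapply(vals, `[[`, 0, "pred"),
               stringsAsFactors = FALSE)
  }
}

# Binary min-heap of (cost, key) with lazy invalidation.
heap_new <- function() {
  h <- new.env(parent = emptyenv())
  h$cost <- numeric(256)
  h$key <- character(256)
  h$n <- 0L
  h
}

heap_push <- function(h, cost, key) {
  n <- h$n + 1L
  if (n > length(h$cost)) {
    h$cost <- c(h$cost, numeric(length(h$cost)))
    h$key <- c(h$key, character(length(h$key)))
  }
  h$cost[n] <- cost
  h$key[n] <- key
  h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$cost[p] <= h$cost[i]) break
    tmp <- h$cost[p]; h$cost[p] <- h$cost[i]; h$cost[i] <- tmp
    tmpk <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tmpk
    i <- p
  }
}

heap_pop <- function(h) {
  if (h$n == 0L) return(NULL)
  top <- list(cost = h$cost[1L], key = h$key[1L])
  h$cost[1L] <- h$cost[h$n]
  h$key[1L] <- h$key[h$n]
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    small <- i
    if (l <= h$n && h$cost[l] < h$cost[small]) small <- l
    if (r <= h$n && h$cost[r] < h$cost[small]) small <- r
    if (small == i) break
    tmp <- h$cost[small]; h$cost[small] <- h$cost[i]; h$cost[i] <- tmp
    tmpk <- h$key[small]; h$key[small] <- h$key[i]; h$key[i] <- tmpk
    i <- small
  }
  top
}

#' Plan the most actionable path for an instance (Step 3)
#'
#' Runs the capped-iteration optimal-path search on the instance's grid
#' graph. The cost of a path is the sum over its nodes (the start node
#' included) of the negative log node probability, so minimizing cost
#' maximizes actionability, the product of nodal probabilities. Nodes are
#' finalized in order of minimal cost (uniform-cost search, which makes every
#' finalized node's path provably optimal); a first-in-first-out expansion
#' order is available via `expansion = "fifo"` for fidelity experiments. The
#' search stops after `L` finalizations or when the frontier empties; the
#' destination is the finalized node with the best predicted response in the
#' requested direction, ties broken by minimal cost, then by lexicographically
#' smallest offsets.
#'
#' @param instance one-row data frame of explanatory values (standardized
#'   scale); must be complete in the intervention variables.
#' @param surrogate a `surrogate_model`.
#' @param predictor a `prediction_model`.
#' @param grid an [grid_spec()] with this instance at its origin.
#' @param objective `"minimize"` (default) or `"maximize"` the predicted
#'   response.
#' @param L search iteration cap: maximum node finalizations (default 20000).
#' @param include_response passed to [node_evaluator()].
#' @param expansion `"mincost"` (default) or `"fifo"`.
#' @param evaluator optional evaluator closure overriding the default (used
#'   for testing and for sharing a cache across calls).
#' @return An object of class `ap_plan`: the optimal `path` (offsets, log
#'   probabilities, predictions, cost, actionability), the `destination`
#'   offsets, `n_expanded`, a data frame `costs` of all finalized nodes, and
#'   the `termination` reason (`"L_exhausted"` or `"frontier_empty"`).
#' @export
plan_path <- function(instance, surrogate, predictor, grid,
                      objective = c("minimize", "maximize"), L = 20000L,
                      include_response = TRUE,
                      expansion = c("mincost", "fifo"), evaluator = NULL) {
  objective <- match.arg(objective)
  expansion <- match.arg(expansion)
  if (is.null(evaluator))
    evaluator <- node_evaluator(surrogate, predictor, grid, include_response)
  d <- length(grid$vars)
  start <- rep(0L, d)
  start_key <- node_key(start)
  ev0 <- evaluator(matrix(start, 1))
  if (!is.finite(ev0$logp[1]))
    stop("start node has zero probability under the surrogate")
  cost <- new.env(parent = emptyenv())   # best known cost per key
  parent <- new.env(parent = emptyenv())
  done <- new.env(parent = emptyenv())   # finalized keys
  info <- new.env(parent = emptyenv())   # logp/pred per key
  assign(start_key, -ev0$logp[1], envir = cost)
  assign(start_key, ev0, envir = info)
  h <- heap_new()
  heap_push(h, -ev0$logp[1], start_key)
  fifo <- character(0)
  if (expansion == "fifo") fifo <- start_key
  n_expanded <- 0L
  cap <- max(16L, min(L, 1000000L))
  finalized <- character(cap)
  final_cost <- numeric(cap)
  termination <- "frontier_empty"
  repeat {
    if (n_expanded >= L) {
      termination <- "L_exhausted"
      break
    }
    if (expansion == "mincost") {
      top <- heap_pop(h)
      if (is.null(top)) break
      key <- top$key
      if (exists(key, envir = done)) next
      if (top$cost > get(key, envir = cost) + 1e-12) next  # stale entry
      assign(key, TRUE, envir = done)
    } else {
      # label-correcting FIFO: nodes may be re-queued when their cost improves
      if (length(fifo) == 0L) break
      key <- fifo[1L]
      fifo <- fifo[-1L]
    }
    n_expanded <- n_expanded + 1L
    if (n_expanded > length(finalized)) {
      finalized <- c(finalized, character(length(finalized)))
      final_cost <- c(final_cost, numeric(length(final_cost)))
    }
    finalized[n_expanded] <- key
    final_cost[n_expanded] <- get(key, envir = cost)
    offs <- key_to_offsets(key)
    nb <- neighbors(offs, grid)
    if (nrow(nb) > 0) {
      ev <- evaluator(nb)
      base <- get(key, envir = cost)
      for (i in seq_len(nrow(nb))) {
        k2 <- ev$key[i]
        if (exists(k2, envir = done)) next
        new_cost <- base - ev$logp[i]
        old <- if (exists(k2, envir = cost)) get(k2, envir = cost) else Inf
        if (new_cost < old) {
          assign(k2, new_cost, envir = cost)
          assign(k2, key, envir = parent)
          assign(k2, list(logp = ev$logp[i], pred = ev$pred[i]), envir = info)
          if (expansion == "mincost") heap_push(h, new_cost, k2)
          else if (!(k2 %in% fifo)) fifo <- c(fifo, k2)
        }
      }
    }
  }
  # Settled nodes: under min-cost expansion the finalized nodes (each once,
  # in non-decreasing cost order); under FIFO every reached node at its
  # converged cost.
  if (expansion == "mincost") {
    keys_out <- finalized[seq_len(n_expanded)]
    costs_out <- final_cost[seq_len(n_expanded)]
  } else {
    keys_out <- ls(cost)
    costs_out <- vapply(keys_out, get, 0, envir = cost)
  }
  # Destination: best predicted response among settled nodes; ties by
  # minimal cost, then lexicographically smallest offsets.
  stats_fin <- data.frame(
    key = keys_out,
    cost = costs_out,
    logp = vapply(keys_out, function(k) get(k, envir = info)$logp, 0),
    pred = vapply(keys_out, function(k) get(k, envir = info)$pred, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  best_pred <- if (objective == "minimize") min(stats_fin$pred)
               else max(stats_fin$pred)
  tied <- which(stats_fin$pred == best_pred)
  tied <- tied[stats_fin$cost[tied] == min(stats_fin$cost[tied])]
  if (length(tied) > 1) {
    om <- as.data.frame(do.call(rbind, lapply(stats_fin$key[tied],
                                              key_to_offsets)))
    tied <- tied[do.call(order, om)[1]]
  }
  dest_key <- stats_fin$key[tied]
  chain <- dest_key
  while (exists(chain[1], envir = parent))
    chain <- c(get(chain[1], envir = parent), chain)
  offsets <- do.call(rbind, lapply(chain, key_to_offsets))
  dimnames(offsets) <- list(NULL, grid$vars)
  logp <- vapply(chain, function(k) get(k, envir = info)$logp, 0)
  pred <- vapply(chain, function(k) get(k, envir = info)$pred, 0)
  path <- new_path(offsets, logp, pred)
  structure(list(path = path, destination = key_to_offsets(dest_key),
                 n_expanded = n_expanded, costs = stats_fin,
                 termination = termination, objective = objective, L = L,
                 grid = grid, evaluator = evaluator),
            class = "ap_plan")
}

new_path <- function(offsets, logp, pred) {
  cost <- sum(-logp)
  structure(list(offsets = offsets, logp = logp, pred = pred,
                 cost = cost, actionability = exp(-cost)),
            class = "ap_path")
}

#' @export
print.ap_path <- function(x, ...) {
  cat("<ap_path> ", nrow(x$offsets), " node(s), cost ",
      signif(x$cost, 6), ", log-actionability ", signif(-x$cost, 6), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.ap_plan <- function(x, ...) {
  cat("<ap_plan> objective:", x$objective, " expanded:", x$n_expanded,
      " termination:", x$termination, "\n")
  cat("  destination offsets:", paste(x$destination, collapse = ","),
      " predicted response:", signif(x$path$pred[length(x$path$pred)], 6), "\n")
  print(x$path)
  invisible(x)
}

#' Render a planned path as a stepwise report in original units
#'
#' Produces the textual counterpart of the step plots: one row per node,
#' naming the variable changed at each step, the direction (up/down arrows
#' in the figures), the realized intervention-variable values de-standardized
#' back to original units, and the predicted response.
#'
#' @param plan an `ap_plan` (or `ap_path` plus `grid`).
#' @param standardization the standardization record of the training data
#'   (e.g. `train$standardization`), or a standardized `ap_dataset`; `NULL`
#'   leaves values on the working scale.
#' @param grid required when `plan` is a bare `ap_path`.
#' @return Data frame with columns `step`, `variable`, `direction`, one
#'   column per intervention variable (original units) and `predicted`.
#' @export
realize_path <- function(plan, standardization = NULL, grid = NULL) {
  if (inherits(plan, "ap_plan")) {
    grid <- plan$grid
    path <- plan$path
  } else {
    path <- plan
    if (is.null(grid)) stop("grid is required for a bare path")
  }
  if (inherits(standardization, "ap_dataset"))
    standardization <- standardization$standardization
  offs <- path$offsets
  n <- nrow(offs)
  vals <- sweep(offs, 2, grid$step[grid$vars], `*`)
  vals <- sweep(vals, 2, grid$origin[grid$vars], `+`)
  if (!is.null(standardization)) {
    for (v in intersect(colnames(vals), names(standardization$mean)))
      vals[, v] <- vals[, v] * standardization$sd[v] + standardization$mean[v]
  }
  variable <- direction <- rep(NA_character_, n)
  if (n > 1) {
    for (i in 2:n) {
      ch <- which(offs[i, ] != offs[i - 1, ])
      variable[i] <- grid$vars[ch]
      direction[i] <- if (offs[i, ch] > offs[i - 1, ch]) "increase" else "decrease"
    }
  }
  out <- data.frame(step = seq_len(n) - 1L, variable = variable,
                    direction = direction, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals))
  out$predicted <- path$pred
  out
}
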