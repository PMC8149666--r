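#' Random Manhattan-shortest baseline paths between two nodes
#'
#' A baseline path connects the endpoints of an optimal path by the shortest
#' procedure in a random order: the multiset of per-variable unit moves
#' required to go from `start` to `end` is shuffled uniformly, so every path
#' is a monotone-per-variable lattice path of length equal to the Manhattan
#' distance. Node log probabilities are filled in via the evaluator.
#'
#' @param start,end integer offset vectors on the same grid.
#' @param n number of paths to sample.
#' @param seed integer seed.
#' @param evaluator a [node_evaluator()] closure (or any function with its
#'   contract).
#' @return List of `ap_path` objects; when `start == end` each path has a
#'   single node.
#' @export
random_shortest_paths <- function(start, end, n, seed, evaluator) {
  stopifnot(length(start) == length(end))
  delta <- end - start
  moves <- integer(0)
  for (i in seq_along(delta)) {
    if (delta[i] != 0)
      moves <- c(moves, rep(i * sign(delta[i]), abs(delta[i])))
  }
  local_seed(seed, {
    lapply(seq_len(n), function(p) {
      ord <- if (length(moves) > 1) sample(moves) else moves
      offs <- matrix(start, nrow = 1)
      cur <- start
      for (mv in ord) {
        cur[abs(mv)] <- cur[abs(mv)] + sign(mv)
        offs <- rbind(offs, cur)
      }
      ev <- evaluator(offs)
      new_path(offs, ev$logp, ev$pred)
    })
  })
}

#' Actionability score of an optimal path
#'
#' `log(optimal path actionability) - log(baseline path actionability)`,
#' where the baseline actionability is the geometric mean of the
#' actionabilities of `n_baseline` random shortest paths sharing the optimal
#' path's endpoints. A score of zero means the planned path is exactly as
#' actionable as a naive shortest connection (it is exactly zero whenever
#' every baseline is node-identical to the optimal path, e.g. a monotone
#' single-variable path); higher is better.
#'
#' When the optimal path is longer than the Manhattan distance between its
#' endpoints, baselines have fewer nodes and the score is the log-actionability
#' difference as defined, with no per-node normalization.
#'
#' @param optimal an `ap_plan` or `ap_path` (the planned path).
#' @param evaluator the [node_evaluator()] the path was planned with (taken
#'   from an `ap_plan` automatically).
#' @param n_baseline number of baseline paths (default 10).
#' @param seed integer seed for baseline sampling.
#' @return An object of class `ap_actionability_score` with fields
#'   `optimal_log_actionability`, `baseline_log_actionability`, `score`,
#'   `n_baseline`, `seed` and `degenerate` (TRUE when a baseline node had
#'   zero probability, in which case the score is `+Inf` by convention).
#' @export
actionability_score <- function(optimal, evaluator = NULL, n_baseline = 10L,
                                seed = 1L) {
  if (inherits(optimal, "ap_plan")) {
    if (is.null(evaluator)) evaluator <- optimal$evaluator
    optimal <- optimal$path
  }
  if (is.null(evaluator)) stop("an evaluator is required for a bare path")
  offs <- optimal$offsets
  start <- offs[1, ]
  end <- offs[nrow(offs), ]
  baselines <- random_shortest_paths(start, end, n_baseline, seed, evaluator)
  base_la <- vapply(baselines, function(p) -p$cost, 0)
  opt_la <- -optimal$cost
  degenerate <- any(!is.finite(base_la))
  score <- if (degenerate) Inf else opt_la - mean(base_la)
  structure(list(optimal_log_actionability = opt_la,
                 baseline_log_actionability = if (degenerate) -Inf
                                              else mean(base_la),
                 score = score, n_baseline = n_baseline, seed = seed,
                 degenerate = degenerate, baselines = baselines),
            class = "ap_actionability_score")
}

#' @export
print.ap_actionability_score <- function(x, ...) {
  cat("<actionability score> ", signif(x$score, 6),
      " (optimal ", signif(x$optimal_log_actionability, 6),
      " vs baseline ", signif(x$baseline_log_actionability, 6),
      ", n = ", x$n_baseline, ")\n", sep = "")
  invisible(x)
}

#' Random guideline-direction comparator paths
#'
#' Emulates the comparator used in the clinician assessment: random paths in
#' which the intervention variables are changed in random order, each move in
#' its declared guideline direction, with the same number of steps as the
#' framework-planned path. Variables standing at their grid bound in the
#' required direction are resampled; it is an error if all of them are.
#'
#' @param grid an [grid_spec()]; paths start at its origin (offset zero).
#' @param n_steps number of unit moves per path (>= 1), normally the planned
#'   path's step count.
#' @param n_paths number of comparator paths (default 9).
#' @param seed integer seed.
#' @param directions named character vector overriding the schema's declared
#'   directions (`"increase"`/`"decrease"` per intervention variable).
#' @param evaluator optional [node_evaluator()] to attach log probabilities
#'   and predictions to each node.
#' @return List of `ap_path` objects (log probabilities and predictions are
#'   `NA` when no evaluator is given).
#' @export
random_intervention_paths <- function(grid, n_steps, n_paths = 9L, seed = 1L,
                                      directions = NULL, evaluator = NULL) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  vars <- grid$vars
  if (is.null(directions)) {
    sch <- grid$schema
    directions <- stats::setNames(sch$direction[match(vars, sch$name)], vars)
  }
  directions <- directions[vars]
  if (any(!directions %in% c("increase", "decrease")))
    stop("every intervention variable needs a declared direction ",
         "('increase' or 'decrease'): ",
         paste(vars[!directions %in% c("increase", "decrease")],
               collapse = ", "))
  stepdir <- ifelse(directions == "increase", 1L, -1L)
  local_seed(seed, {
    lapply(seq_len(n_paths), function(p) {
      cur <- rep(0L, length(vars))
      offs <- matrix(cur, nrow = 1)
      for (s in seq_len(n_steps)) {
        movable <- which(
          (stepdir > 0 & cur + 1L <= grid$upper) |
          (stepdir < 0 & cur - 1L >= grid$lower))
        if (length(movable) == 0)
          stop("all intervention variables are at their bound in the ",
               "declared direction")
        i <- if (length(movable) == 1) movable else sample(movable, 1)
        cur[i] <- cur[i] + stepdir[i]
        offs <- rbind(offs, cur)
      }
      dimnames(offs) <- list(NULL, vars)
      if (!is.null(evaluator)) {
        ev <- evaluator(offs)
        new_path(offs, ev$logp, ev$pred)
      } else {
        new_path(offs, rep(NA_real_, nrow(offs)), rep(NA_real_, nrow(offs)))
      }
    })
  })
}

#' Two-sided Welch's t-test
#'
#' Compares two groups (e.g. predicted-response reductions of
#' framework-planned versus clinician-selected paths) with unequal-variance
#' degrees of freedom (Welch-Satterthwaite).
#'
#' @param group_a,group_b numeric vectors, each with at least two values and
#'   positive variance.
#' @return list with `statistic`, `df`, `p_value` (two-sided).
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("both groups have zero variance")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
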