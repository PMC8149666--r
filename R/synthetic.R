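#' Specify a Gaussian-mixture generator for benchmark tables
#'
#' Describes a mixture of multivariate normal components over the continuous
#' explanatory variables, optional per-component categorical tables for
#' discrete variables, and a response rule. Component sample sizes are fixed
#' counts, not multinomial draws, so empirical proportions match the
#' configuration exactly.
#'
#' @param means list of numeric mean vectors, one per component (equal length).
#' @param covariances list of symmetric positive-definite covariance matrices
#'   (scalars and vectors are promoted to diagonal matrices).
#' @param sizes integer vector of per-component sample sizes.
#' @param response list with elements `kind` (`"linear-sum"` or `"custom"`),
#'   `coefficients` (required for `"custom"`; one per continuous variable),
#'   `noise_sd` (nonnegative), and optionally `threshold`: when present the
#'   response is binarized as `value > threshold`.
#' @param categorical optional list (one element per component) of named lists
#'   mapping each discrete variable to its category-probability vector.
#' @return An object of class `ap_mixture_spec`.
#' @export
mixture_spec <- function(means, covariances, sizes,
                         response = list(kind = "linear-sum", noise_sd = 2),
                         categorical = NULL) {
  stopifnot(length(means) == length(covariances),
            length(means) == length(sizes))
  d <- length(means[[1]])
  covariances <- lapply(covariances, function(S) {
    if (is.null(dim(S))) S <- diag(rep_len(S, d), d)
    S
  })
  for (i in seq_along(means)) {
    if (length(means[[i]]) != d) stop("component mean dimensions differ")
    S <- covariances[[i]]
    if (!all(dim(S) == c(d, d))) stop("covariance dimension mismatch")
    if (max(abs(S - t(S))) > 1e-8) stop("covariance matrix not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance matrix not positive definite")
  }
  if (any(sizes < 1)) stop("component sizes must be >= 1")
  if (!response$kind %in% c("linear-sum", "custom"))
    stop("response kind must be 'linear-sum' or 'custom'")
  if (response$kind == "custom" && length(response$coefficients) != d)
    stop("need one response coefficient per continuous variable")
  if (is.null(response$noise_sd) || response$noise_sd < 0)
    stop("response noise_sd must be a nonnegative number")
  if (!is.null(categorical)) {
    stopifnot(length(categorical) == length(means))
    for (comp in categorical) {
      for (p in comp) {
        if (abs(sum(p) - 1) > 1e-8)
          stop("categorical probability rows must sum to 1")
      }
    }
  }
  structure(list(means = means, covariances = covariances,
                 sizes = as.integer(sizes), response = response,
                 categorical = categorical,
                 weights = sizes / sum(sizes), d = d),
            class = "ap_mixture_spec")
}

# Default geometry of the 3D benchmark: one well-separated component plus two
# components overlapping along a single axis, so the density has two
# effective modes and the straight line between typical high- and low-response
# points crosses a low-density valley.
benchmark3d_means <- function() list(c(3, 3, 3), c(0, 0, 0.75), c(0, 0, -0.75))

#' Generate the three-cluster 3D regression benchmark
#'
#' Draws `n_per_component` points from each of three trivariate normal
#' distributions (600 rows under the defaults) and sets the response to
#' `y = x1 + x2 + x3 + e`, `e ~ Normal(0, noise_sd)`. The component layout is
#' chosen so that straight paths between high- and low-response regions are
#' not always actionable: two components overlap into one elongated density
#' mode and the third sits well apart.
#'
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param n_per_component points per component (default 200).
#' @param noise_sd response noise standard deviation (default 2).
#' @param means,covariances optional overrides of the three components.
#' @return An `ap_dataset` with columns `x1, x2, x3, y`; all explanatory
#'   variables are flagged intervenable. The generating `ap_mixture_spec` and
#'   true component labels are attached as attributes `generator` and
#'   `component`.
#' @export
generate_synthetic3d <- function(seed = 1L, n_per_component = 200L,
                                 noise_sd = 2,
                                 means = benchmark3d_means(),
                                 covariances = list(diag(3), diag(3), diag(3))) {
  if (n_per_component < 1) stop("n_per_component must be >= 1")
  spec <- mixture_spec(means, covariances,
                       sizes = rep(n_per_component, 3L),
                       response = list(kind = "linear-sum",
                                       noise_sd = noise_sd))
  schema <- variable_schema(
    name = c("x1", "x2", "x3", "y"),
    kind = "continuous",
    role = c(rep("explanatory", 3), "response"),
    intervenable = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("decrease", "decrease", "decrease", "free")
  )
  generate_mixture_table(spec, schema, seed = seed, missing_rate = 0)
}

rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(cov), 2, mean, `+`)
}

#' Generate a mixed-type table from a mixture specification
#'
#' Continuous explanatory columns are drawn from the specified Gaussian
#' mixture with fixed per-component counts; discrete explanatory columns are
#' drawn from per-component categorical tables; the response is computed from
#' the response rule (thresholded to the two schema categories, or to 0/1,
#' when a threshold is given); missing cells are then planted uniformly at
#' random over the explanatory cells at `missing_rate`.
#'
#' @param spec an [mixture_spec()].
#' @param schema an [variable_schema()]; the count of continuous explanatory
#'   variables must match the spec dimension.
#' @param seed integer seed.
#' @param missing_rate proportion in `[0, 1)` of explanatory cells masked.
#' @return An `ap_dataset`; attributes `generator` (the spec) and `component`
#'   (true component labels) are attached.
#' @export
generate_mixture_table <- function(spec, schema, seed = 1L,
                                   missing_rate = 0) {
  stopifnot(inherits(spec, "ap_mixture_spec"))
  validate_schema(schema)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  cvars <- continuous_vars(schema, role = "explanatory")
  dvars <- discrete_vars(schema, role = "explanatory")
  yvar <- response_var(schema)
  if (length(cvars) != spec$d)
    stop("spec dimension (", spec$d, ") does not match the ",
         length(cvars), " continuous explanatory variables")
  if (length(dvars) > 0 && is.null(spec$categorical))
    stop("schema has discrete variables but spec has no categorical tables")
  local_seed(seed, {
    comp <- rep(seq_along(spec$sizes), spec$sizes)
    n <- length(comp)
    X <- matrix(NA_real_, n, spec$d, dimnames = list(NULL, cvars))
    D <- matrix(NA_character_, n, length(dvars),
                dimnames = list(NULL, dvars))
    for (k in seq_along(spec$sizes)) {
      rows <- which(comp == k)
      X[rows, ] <- rmvnorm_chol(length(rows), spec$means[[k]],
                                spec$covariances[[k]])
      for (v in dvars) {
        p <- spec$categorical[[k]][[v]]
        cats <- var_categories(schema, v)
        if (length(p) != length(cats))
          stop("categorical table for '", v, "' has ", length(p),
               " probabilities but schema lists ", length(cats), " categories")
        D[rows, v] <- sample(cats, length(rows), replace = TRUE, prob = p)
      }
    }
    coefs <- if (spec$response$kind == "linear-sum") rep(1, spec$d)
             else spec$response$coefficients
    y_cont <- drop(X %*% coefs) +
      stats::rnorm(n, 0, spec$response$noise_sd)
    df <- as.data.frame(X)
    for (v in dvars) df[[v]] <- D[, v]
    if (!is.null(spec$response$threshold)) {
      pos <- y_cont > spec$response$threshold
      if (schema$kind[schema$name == yvar] == "discrete") {
        cats <- var_categories(schema, yvar)
        df[[yvar]] <- ifelse(pos, cats[2], cats[1])
      } else {
        df[[yvar]] <- as.numeric(pos)
      }
    } else {
      df[[yvar]] <- y_cont
    }
    if (missing_rate > 0) {
      evars <- c(cvars, dvars)
      cells <- expand.grid(row = seq_len(n), var = evars,
                           stringsAsFactors = FALSE)
      hit <- stats::runif(nrow(cells)) < missing_rate
      for (i in which(hit)) df[cells$row[i], cells$var[i]] <- NA
    }
    out <- as_dataset(df, schema)
    attr(out, "generator") <- spec
    attr(out, "component") <- comp
    out
  })
}
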