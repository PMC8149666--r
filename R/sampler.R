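# Component-wise slice sampler (Neal 2003, stepping-out + shrinkage) over the
# unconstrained parameterization of the surrogate posterior. Tuning-free up to
# the initial bracket width, which is adapted once from warm-up draws.

slice_update1 <- function(theta, i, lp_fun, lp_cur, w, max_steps = 30L) {
  x0 <- theta[i]
  logy <- lp_cur - stats::rexp(1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  f <- function(x) {
    theta[i] <- x
    lp_fun(theta)
  }
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1L - j
  while (j > 0 && f(lo) > logy) {
    lo <- lo - w
    j <- j - 1L
  }
  while (k > 0 && f(hi) > logy) {
    hi <- hi + w
    k <- k - 1L
  }
  for (tries in 1:100) {
    x1 <- stats::runif(1, lo, hi)
    lp1 <- f(x1)
    if (lp1 >= logy) {
      theta[i] <- x1
      return(list(theta = theta, lp = lp1))
    }
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  # degenerate shrinkage: keep the current point (always in the slice)
  list(theta = theta, lp = lp_cur)
}

run_slice_chain <- function(theta0, lp_fun, iterations, warmup, seed,
                            w0 = 1) {
  P <- length(theta0)
  stopifnot(iterations > warmup)
  local_seed(seed, {
    w <- rep(w0, P)
    keep <- matrix(NA_real_, iterations - warmup, P)
    warm <- matrix(NA_real_, warmup, P)
    th <- theta0
    lp <- lp_fun(th)
    if (!is.finite(lp)) stop("non-finite log posterior at initialization")
    adapt_at <- max(2L, floor(warmup / 2))
    for (it in seq_len(iterations)) {
      for (i in seq_len(P)) {
        upd <- slice_update1(th, i, lp_fun, lp, w[i])
        th <- upd$theta
        lp <- upd$lp
      }
      if (it <= warmup) {
        warm[it, ] <- th
        if (it == adapt_at) {
          sds <- apply(warm[seq_len(it), , drop = FALSE], 2, stats::sd)
          w <- pmin(4, pmax(0.25, 2.5 * sds))
        }
      } else {
        keep[it - warmup, ] <- th
      }
    }
    keep
  })
}

# Split-chain potential scale reduction factor per column of `draws`.
split_rhat <- function(draws, chain) {
  seqs <- list()
  for (ch in unique(chain)) {
    d <- draws[chain == ch, , drop = FALSE]
    h <- floor(nrow(d) / 2)
    if (h < 2) return(NULL)
    seqs <- c(seqs, list(d[seq_len(h), , drop = FALSE],
                         d[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(seqs)
  n <- nrow(seqs[[1]])
  means <- sapply(seqs, colMeans)
  vars <- sapply(seqs, function(s) apply(s, 2, stats::var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}
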