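# Shared fixtures: everything is generated in code at test time.

# A tiny network configuration for fast exact tests (double precision so
# finite-difference gradient checks are meaningful).
tiny_fcn_config <- function(...) {
  fcn_config(block_channels = c(3L, 4L), conv_kernel = 3L,
             head_channels = 5L, precision = "double", ...)
}

# Small phantom parameters for quick rendering.
small_phantom <- function(...) {
  args <- utils::modifyList(list(height = 64L, width = 64L), list(...))
  do.call(phantom_params, args)
}

# Random scored set with ties, for metric oracles.
random_scored <- function(n, seed) {
  withr::with_seed(seed, {
    scores <- round(runif(n), 2)          # rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    scored_set(scores, labels)
  })
}

# Independent pairwise-concordance AUC (Mann-Whitney with half-credit ties).
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct population-moment statistics (the brute-force oracle).
moment_stats <- function(x) {
  mu <- sum(x) / length(x)
  ctr <- x - mu
  m2 <- sum(ctr^2) / length(x)
  list(kurtosis = (sum(ctr^4) / length(x)) / m2^2,
       skewness = (sum(ctr^3) / length(x)) / m2^1.5)
}
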