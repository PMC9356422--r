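## Shared fixtures. The desk-scale end-to-end experiment (cohort, three
## trained seeds, slide predictions, statistics) is expensive, so it is run
## once per session and memoized; every test needing a trained model or the
## end-to-end statistics reuses it.

.srh_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (is.null(.srh_cache$run)) {
    cfg <- experimentConfig(out_dir = file.path(tempdir(), "srh-desk-exp"))
    .srh_cache$run <- runExperiment(cfg, verbose = FALSE)
  }
  .srh_cache$run
}

desk_model <- function(i = 1L) desk_experiment()$models[[i]]

## independent ANOVA oracle for the absolute-agreement single-measure ICC:
## direct sums-of-squares arithmetic, no model fitting
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); gm <- mean(m)
  SSR <- k * sum((rowMeans(m) - gm)^2)
  SSC <- n * sum((colMeans(m) - gm)^2)
  SSE <- sum((m - gm)^2) - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

## exhaustive pair-counting AUC oracle (ties count 1/2)
auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## random simplex draws
rsimplex <- function(n) {
  m <- matrix(stats::rexp(3 * n), n, 3)
  m / rowSums(m)
}
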