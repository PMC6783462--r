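# shared fixtures: all synthetic, built in code at test time

ccle_doses <- function() dose_design("CCLE")$doses

make_series <- function(form, params, doses = ccle_doses(), sigma = 0,
                        seed = NULL) {
  y <- evaluate_curve(form, params, doses)
  if (sigma > 0) {
    set.seed(seed)
    y <- y + rnorm(length(doses), 0, sigma)
  }
  list(dose = doses, response = y)
}

# random logistic parameter draws on plausible viability-screen scales
random_logistic_params <- function(n, form = "4P", seed = 1) {
  set.seed(seed)
  b1 <- runif(n, 0, 30)
  b2 <- runif(n, 80, 120)
  b3 <- runif(n, log(0.05), log(4))
  b4 <- runif(n, 0.5, 3) * sample(c(-1, 1), n, replace = TRUE)
  if (form == "4P") cbind(b1, b2, b3, b4) else cbind(b2, b3, b4)
}

# dense rss grid around a 4P parameter vector; independent brute-force
# check that a returned optimum is not beaten anywhere nearby
grid_min_rss_4p <- function(dose, response, center, span, n_grid = 10L) {
  ax <- lapply(1:4, function(j) {
    seq(center[j] - span[j], center[j] + span[j], length.out = n_grid)
  })
  g <- as.matrix(expand.grid(ax))
  l <- log(dose)
  best <- Inf
  for (k in seq_len(nrow(g))) {
    mu <- g[k, 1] + (g[k, 2] - g[k, 1]) * plogis(-g[k, 4] * (l - g[k, 3]))
    best <- min(best, sum((response - mu)^2))
  }
  best
}

# independent mid-rank oracle: counting definition of average ranks, then
# the moment formula for Pearson correlation
midrank_pearson_oracle <- function(x, y) {
  mr <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2,
           numeric(1))
  }
  rx <- mr(x); ry <- mr(y)
  n <- length(x)
  (mean(rx * ry) - mean(rx) * mean(ry)) /
    sqrt((mean(rx^2) - mean(rx)^2) * (mean(ry^2) - mean(ry)^2))
}
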