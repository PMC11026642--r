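# Independent brute-force oracles, deliberately written without reusing the
# package's fitting code paths.

# Exhaustive contact-point search: at every interior sample position fit a
# baseline (lm on the prefix) and a Hertz power law (lm through the origin on
# delta^1.5 over the suffix), and return the sample z minimising the total SSE.
oracle_contact_point_nm <- function(curve, min_pre = 20L, min_post = 20L) {
  app <- curve$data[curve$data$segment == "approach", ]
  z <- app$z_nm * 1e-9
  f <- curve$k * app$deflection_nm * 1e-9
  n <- length(z)
  best_sse <- Inf
  best_z0 <- NA_real_
  for (i in seq(min_pre + 1L, n - min_post)) {
    z0 <- z[i]
    pre <- seq_len(i - 1L)
    bl <- lm(f[pre] ~ z[pre])
    fc <- f - (coef(bl)[1] + coef(bl)[2] * z)
    post <- i:n
    x <- pmax((z[post] - z0) - fc[post] / curve$k, 0)^1.5
    a <- if (sum(x^2) > 0) max(0, sum(fc[post] * x) / sum(x^2)) else 0
    sse <- sum(fc[pre]^2) + sum((fc[post] - a * x)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_z0 <- z0
    }
  }
  best_z0 * 1e9
}

# 1-D grid search over the Young's modulus minimising the SSE of the Hertz
# sphere law on given force-indentation points.
oracle_hertz_E_grid <- function(delta_m, force_N, R_m, nu,
                                E_grid = seq(50, 2000, by = 0.5)) {
  sse <- vapply(E_grid, function(E) {
    pred <- (4 / 3) * (E / (1 - nu^2)) * sqrt(R_m) * delta_m^1.5
    sum((force_N - pred)^2)
  }, numeric(1))
  E_grid[which.min(sse)]
}

# Two-way ANOVA with interaction via nested-model residual-SS comparisons
# (Type II main effects; interaction against the full model), F tested on
# the full-model residual.
oracle_two_way_anova <- function(y, a, b) {
  d <- data.frame(y = y, a = factor(a), b = factor(b))
  rss <- function(fm) sum(resid(lm(fm, data = d))^2)
  rss_full <- rss(y ~ a * b)
  df_res <- nrow(d) - 4L
  ms_res <- rss_full / df_res
  ss <- c(a = rss(y ~ b) - rss(y ~ a + b),
          b = rss(y ~ a) - rss(y ~ a + b),
          ab = rss(y ~ a + b) - rss_full)
  f <- ss / 1 / ms_res
  p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
  list(ss = ss, f = f, p = p, rss_full = rss_full, df_res = df_res)
}

# direct pixel-count activated fraction
oracle_activated_fraction <- function(px, lower, upper) {
  (sum(px >= lower) - sum(px > upper)) / length(px)
}
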