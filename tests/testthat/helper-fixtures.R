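# Shared fixtures and independent oracles for the suite.

# a representative PAH-range scalar state (NYHA II-ish)
fix_state <- function() {
  hemo_state(hr = 75, mpap = 47.4, pp = 38, sv = 74.7, co = 75 * 74.7,
             mrv_ep = 52.4, rv_edp = 8, rv_edv = 162.4)
}

# fine-grid trapezoidal quadrature oracle: integral of f on [a, b]
quad_oracle <- function(f, a, b, rate = 10000) {
  x <- seq(a, b, length.out = max(3, ceiling((b - a) * rate) + 1))
  y <- f(x)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# normal-equations OLS oracle (explicit closed form, no lm)
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       slope_se = sqrt(se2 / sxx),
       intercept_se = sqrt(se2 * (1 / n + mean(x)^2 / sxx)))
}

# Pillai's trace computed directly from SSCP matrices (independent of
# stats::manova); g is a two-level factor
pillai_trace <- function(Y, g) {
  G <- stats::model.matrix(~g)
  fit <- stats::lm.fit(G, Y)
  E <- crossprod(fit$residuals)
  Yc <- scale(Y, scale = FALSE)
  H <- crossprod(Yc) - E
  sum(diag(H %*% solve(H + E)))
}

# two-group multivariate fixture with moderate separation, used for the
# MANOVA/permutation comparison
manova_fixture <- function(seed = 42, n1 = 7, n2 = 7) {
  set.seed(seed)
  data.frame(
    group = rep(c("NYHA_II", "NYHA_III"), c(n1, n2)),
    efficiency_elbeery = c(rnorm(n1, 0.40, 0.08), rnorm(n2, 0.30, 0.08)),
    efficiency_adjusted = c(rnorm(n1, 0.50, 0.10), rnorm(n2, 0.40, 0.10)),
    mvo2_ml_min = c(rnorm(n1, 4.0, 1.0), rnorm(n2, 5.0, 1.0))
  )
}
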