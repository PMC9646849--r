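# Independent oracles, deliberately written as naive loops / separate
# computational routes from the package implementation.

# IEC by explicit double loop over every automated-human and human-pair
# squared difference.
brute_force_iec <- function(quads) {
  tr <- c(); rr <- c()
  for (i in seq_len(nrow(quads))) {
    h <- c(quads$R1[i], quads$R2[i], quads$R3[i])
    a <- quads$AUTO[i]
    for (j in 1:3) tr <- c(tr, (a - h[j])^2)
    for (j in 1:2) for (k in (j + 1):3) rr <- c(rr, (h[j] - h[k])^2)
  }
  (mean(tr) - mean(rr)) / (mean(rr) / 2)
}

# ICC(2,1) and residual RMSE via R's linear-model ANOVA rather than
# direct mean-square arithmetic.
anova_oracle <- function(m) {
  df <- data.frame(
    value = as.vector(m),
    study = factor(rep(seq_len(nrow(m)), ncol(m))),
    reader = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- anova(lm(value ~ study + reader, data = df))
  msr <- tab["study", "Mean Sq"]
  msc <- tab["reader", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  list(
    icc = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    rmse = sqrt(mse)
  )
}

# Lin's CCC via the precision x accuracy factorisation:
# CCC = r * C_b,  C_b = 2 s_x s_y / (s_x^2 + s_y^2 + (mx - my)^2),
# with population (1/n) moments.
ccc_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  r <- cor(x, y)
  cb <- 2 * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
  r * cb
}
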