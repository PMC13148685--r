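# Shared fixtures and an independent polychoric oracle.

# write a small indicator CSV and return its path
write_indicator_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

malawi_record <- function() {
  data.frame(country = "Malawi", che_per_capita_usd = 40,
             external_share_pct = 64.7, budget_space = "stagnation",
             debt_risk = "in_distress_or_very_high",
             stringsAsFactors = FALSE)
}

nigeria_record <- function() {
  data.frame(country = "Nigeria", che_per_capita_usd = 91,
             external_share_pct = 6.8, budget_space = "expansion",
             debt_risk = "low_or_na", stringsAsFactors = FALSE)
}

# --- independent polychoric oracle ------------------------------------
# Brute-force grid search over rho in {-0.99, ..., 0.99}, with bivariate
# normal rectangle probabilities computed by adaptive quadrature
# (stats::integrate), i.e. a different numerical route from the package.
oracle_cell_probs <- function(a, b, rho) {
  xa <- c(-Inf, a, Inf)
  yb <- c(-Inf, b, Inf)
  s <- sqrt(1 - rho^2)
  nr <- length(xa) - 1L
  nc <- length(yb) - 1L
  P <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      f <- function(z) dnorm(z) * (pnorm((yb[j + 1] - rho * z) / s) -
                                     pnorm((yb[j] - rho * z) / s))
      P[i, j] <- integrate(f, max(xa[i], -10), min(xa[i + 1], 10),
                           rel.tol = 1e-10)$value
    }
  }
  P
}

oracle_polychoric_rho <- function(x, y, grid = seq(-0.99, 0.99, by = 0.01)) {
  tab <- table(x, y)
  a <- qnorm(cumsum(rowSums(tab)) / sum(tab))
  a <- a[-length(a)]
  b <- qnorm(cumsum(colSums(tab)) / sum(tab))
  b <- b[-length(b)]
  ll <- vapply(grid, function(r)
    sum(tab * log(pmax(oracle_cell_probs(a, b, r), 1e-12))), numeric(1))
  grid[which.max(ll)]
}

# draw a thresholded latent bivariate normal pair
draw_ordinal_pair <- function(n, rho, thresholds_x = c(-0.5, 0.5),
                              thresholds_y = c(-0.5, 0.5)) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(x = 1L + findInterval(z1, thresholds_x),
       y = 1L + findInterval(z2, thresholds_y))
}
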