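# Polychoric correlation: two-step (Olsson-style) maximum likelihood for
# pairs of ordinal variables assumed to arise by thresholding a latent
# bivariate standard normal. Thresholds come from the marginal cumulative
# proportions; the latent correlation maximizes the multinomial likelihood
# of the observed contingency table under bivariate-normal cell
# probabilities. Deterministic: bounded 1-D optimization, no random starts.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

.gl24 <- gauss_legendre(24L)

# Bivariate-normal rectangle probabilities for the full grid of cells cut by
# thresholds a (rows) and b (columns). Integrates the conditional normal over
# each row band with fixed quadrature; tails truncated at +/-8 latent SD.
bvn_cell_probs <- function(a, b, rho, gl = .gl24) {
  xa <- c(-8, a, 8)
  yb <- c(-8, b, 8)
  s <- sqrt(max(1 - rho^2, 1e-12))
  nr <- length(xa) - 1L
  nc <- length(yb) - 1L
  P <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    half <- (xa[i + 1] - xa[i]) / 2
    x <- xa[i] + half * (gl$x + 1)
    wt <- half * gl$w * stats::dnorm(x)
    Z <- outer(x, yb, function(xx, yy) stats::pnorm((yy - rho * xx) / s))
    P[i, ] <- colSums(wt * (Z[, -1, drop = FALSE] - Z[, -(nc + 1), drop = FALSE]))
  }
  P
}

#' Latent-normal thresholds from an ordinal margin
#'
#' Threshold k is the standard-normal quantile of the cumulative proportion
#' of observations at or below the k-th observed category, for k = 1 ..
#' (observed categories - 1). Unobserved categories contribute no threshold.
#'
#' @param levels integer (or factor) vector of ordinal observations.
#' @param max_level optional declared maximum level (used only to validate).
#' @return Strictly increasing numeric vector of cut-points.
#' @export
#' @examples
#' estimate_thresholds(c(1, 1, 2, 2))  # 0
estimate_thresholds <- function(levels, max_level = NULL) {
  levels <- as.integer(as.character(factor(levels)))
  if (anyNA(levels)) stop("levels must be integer-coded ordinals")
  if (!is.null(max_level) && any(levels > max_level))
    stop("observed level exceeds max_level")
  tab <- table(levels)
  if (length(tab) < 2)
    stop("degenerate variable: a single observed category")
  p <- cumsum(as.numeric(tab)) / sum(tab)
  stats::qnorm(p[-length(p)])
}

# log-likelihood of the contingency table at latent correlation rho
.poly_loglik <- function(rho, tab, a, b) {
  P <- bvn_cell_probs(a, b, rho)
  sum(tab * log(pmax(P, 1e-12)))
}

#' Polychoric correlation between two ordinal variables
#'
#' Two-step estimator: thresholds fixed from the marginal distributions,
#' then the latent correlation maximizing the multinomial log-likelihood of
#' the cross-tabulation under bivariate-normal cell probabilities, bounded to
#' (-0.999, 0.999). If the bounded optimizer fails, a coarse grid search over
#' rho is used and the result flagged as not converged.
#'
#' @param x,y equal-length ordinal vectors (n >= 10), both with at least two
#'   observed categories.
#' @return List with `rho`, `loglik`, `thresholds` (list for x and y),
#'   `converged` flag.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(200)
#' estimate_polychoric_rho(findInterval(z, c(-0.5, 0.5)),
#'                         findInterval(z + rnorm(200), c(-0.5, 0.5)))$rho
estimate_polychoric_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("need at least 10 paired observations")
  a <- estimate_thresholds(x)
  b <- estimate_thresholds(y)
  tab <- table(x, y)
  fit <- tryCatch(
    stats::optimize(.poly_loglik, interval = c(-0.999, 0.999), maximum = TRUE,
                    tol = 1e-6, tab = tab, a = a, b = b),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$objective)) {
    grid <- seq(-0.99, 0.99, by = 0.01)
    ll <- vapply(grid, .poly_loglik, numeric(1), tab = tab, a = a, b = b)
    best <- which.max(ll)
    return(list(rho = grid[best], loglik = ll[best],
                thresholds = list(x = a, y = b), converged = FALSE))
  }
  list(rho = fit$maximum, loglik = fit$objective,
       thresholds = list(x = a, y = b), converged = TRUE)
}

# nearest-PSD smoothing: clip negative eigenvalues, rescale to unit diagonal
smooth_psd <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(list(corr = R, smoothed = FALSE))
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  list(corr = (S + t(S)) / 2, smoothed = TRUE)
}

#' Polychoric correlation matrix of an ordinal dataset
#'
#' Pairwise two-step polychoric estimation over all factor pairs. Degenerate
#' factors (a single observed category) are excluded with a warning. If the
#' assembled pairwise matrix has a negative eigenvalue it is smoothed to the
#' nearest positive semi-definite correlation matrix (eigenvalue clipping at
#' `1e-6`, then rescaling to unit diagonal).
#'
#' @param data an [ordinal_dataset], or an integer matrix of levels.
#' @return An object of class `polychoric_result`: list with `corr`,
#'   `thresholds` (per retained factor), `n_obs`, `converged` (logical matrix
#'   per pair), `smoothed`, `excluded` (names of degenerate factors).
#' @export
polychoric_matrix <- function(data) {
  lev <- if (inherits(data, "ordinal_dataset")) data$levels else as.matrix(data)
  fnames <- colnames(lev) %||% paste0("f", seq_len(ncol(lev)))
  k0 <- ncol(lev)
  if (k0 < 2) stop("need at least two factors")
  degenerate <- vapply(seq_len(k0),
                       function(j) length(unique(lev[, j])) < 2, logical(1))
  if (any(degenerate))
    warning("excluding degenerate factor(s): ",
            paste(fnames[degenerate], collapse = ", "))
  keep <- which(!degenerate)
  if (length(keep) < 2) stop("fewer than two non-degenerate factors")
  k <- length(keep)
  R <- diag(k)
  conv <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      fit <- estimate_polychoric_rho(lev[, keep[i]], lev[, keep[j]])
      R[i, j] <- R[j, i] <- fit$rho
      conv[i, j] <- conv[j, i] <- fit$converged
    }
  }
  dimnames(R) <- list(fnames[keep], fnames[keep])
  sm <- smooth_psd(R)
  thresholds <- lapply(keep, function(j) estimate_thresholds(lev[, j]))
  names(thresholds) <- fnames[keep]
  structure(
    list(corr = sm$corr, thresholds = thresholds, n_obs = nrow(lev),
         converged = conv, smoothed = sm$smoothed,
         excluded = fnames[degenerate]),
    class = "polychoric_result"
  )
}

#' @export
print.polychoric_result <- function(x, ...) {
  cat(sprintf("<polychoric_result: %d factors, n = %d%s>\n",
              ncol(x$corr), x$n_obs,
              if (x$smoothed) ", PSD-smoothed" else ""))
  print(round(x$corr, 3))
  invisible(x)
}
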