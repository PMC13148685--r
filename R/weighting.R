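# Per-factor weight derivation. The primary method is PCA on the polychoric
# correlation matrix; exploratory factor analysis (principal axis), the
# classical entropy weight method and equal weights are provided for
# sensitivity analysis.

#' Construct a weight vector
#'
#' @param factor_names character vector.
#' @param weights non-negative numeric vector summing to 100 (within 1e-6).
#' @param method provenance label: one of `"polychoric_pca"`, `"efa"`,
#'   `"entropy"`, `"equal"`, `"user"`.
#' @param diagnostics optional list of method-specific diagnostics.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(factor_names, weights,
                          method = c("user", "polychoric_pca", "efa",
                                     "entropy", "equal"),
                          diagnostics = list()) {
  method <- match.arg(method)
  if (length(factor_names) != length(weights))
    stop("factor_names and weights must have equal length")
  if (any(weights < -1e-9)) stop("weights must be non-negative")
  if (abs(sum(weights) - 100) > 1e-6)
    stop("weights must sum to 100, got ", sum(weights))
  structure(
    list(factor_names = as.character(factor_names),
         weights = as.numeric(weights), method = method,
         diagnostics = diagnostics),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector (%s)>\n", x$method))
  print(round(stats::setNames(x$weights, x$factor_names), 2))
  invisible(x)
}

.corr_input <- function(poly) {
  if (inherits(poly, "polychoric_result")) poly$corr else as.matrix(poly)
}

#' PCA weights from a polychoric correlation matrix
#'
#' Eigendecomposition of the (PSD) polychoric matrix; the first principal
#' component is oriented so that its loading on the first factor is
#' non-negative, and weights are its loadings normalized to sum to 100.
#' By default the absolute loadings are normalized (`transform = "abs"`),
#' which reproduces the reference weight set most closely; `"squared"`
#' normalizes squared loadings (the variance-contribution reading) instead.
#' When the leading eigenvalues are tied (no shared variance, e.g. an
#' identity matrix) the tie is broken by factor order and equal weights are
#' returned with `diagnostics$tie = TRUE`.
#'
#' @param poly a `polychoric_result` or correlation matrix.
#' @param transform `"abs"` or `"squared"` loading-to-weight transform.
#' @return A [weight_vector] with `diagnostics$explained_variance` (per
#'   component proportions) and `diagnostics$loadings`.
#' @export
#' @examples
#' pca_weights(matrix(c(1, .5, .5, 1), 2,
#'                    dimnames = list(c("a", "b"), c("a", "b"))))
pca_weights <- function(poly, transform = c("abs", "squared")) {
  transform <- match.arg(transform)
  R <- .corr_input(poly)
  fnames <- colnames(R) %||% paste0("f", seq_len(ncol(R)))
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("matrix is not positive semi-definite; smooth it first")
  k <- ncol(R)
  diag_out <- list(explained_variance = e$values / sum(e$values),
                   transform = transform)
  if (e$values[1] - e$values[2] < 1e-8) {
    diag_out$tie <- TRUE
    return(weight_vector(fnames, rep(100 / k, k), "polychoric_pca", diag_out))
  }
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v
  loading <- v * sqrt(e$values[1])
  diag_out$loadings <- stats::setNames(loading, fnames)
  w <- if (transform == "abs") abs(loading) else loading^2
  weight_vector(fnames, 100 * w / sum(w), "polychoric_pca", diag_out)
}

#' Exploratory factor analysis weights (single-factor principal axis)
#'
#' Principal-axis factoring with one factor on the polychoric matrix:
#' communalities start at the squared multiple correlations and are iterated
#' to convergence (`1e-4`, at most 100 iterations). Weights are the squared
#' factor loadings normalized to 100. A Heywood case (communality > 1) is
#' clipped to 0.999 and flagged.
#'
#' @inheritParams pca_weights
#' @return A [weight_vector] with `diagnostics$loadings`,
#'   `diagnostics$iterations`, `diagnostics$heywood`.
#' @export
efa_weights <- function(poly) {
  R <- .corr_input(poly)
  fnames <- colnames(R) %||% paste0("f", seq_len(ncol(R)))
  k <- ncol(R)
  e0 <- eigen(R, symmetric = TRUE)
  if (e0$values[1] - e0$values[2] < 1e-8) {
    return(weight_vector(fnames, rep(100 / k, k), "efa",
                         list(tie = TRUE, heywood = FALSE)))
  }
  # squared multiple correlations; fall back to max |r| if R is singular
  h <- tryCatch(1 - 1 / diag(solve(R)),
                error = function(e) {
                  Ro <- abs(R); diag(Ro) <- 0; apply(Ro, 2, max)
                })
  heywood <- FALSE
  iter <- 0L
  loading <- rep(0, k)
  for (iter in seq_len(100L)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    loading <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    if (loading[1] < 0) loading <- -loading
    h_new <- loading^2
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 0.999)
    }
    if (max(abs(h_new - h)) < 1e-4) {
      h <- h_new
      break
    }
    h <- h_new
  }
  if (sum(h) <= 0) stop("no common variance; EFA weights undefined")
  weight_vector(fnames, 100 * h / sum(h), "efa",
                list(loadings = stats::setNames(loading, fnames),
                     iterations = iter, heywood = heywood))
}

#' Entropy weights from ordinal levels
#'
#' Classical entropy weight method on the sum-normalized level matrix:
#' `p_ij = x_ij / sum_i x_ij`, entropy
#' `e_j = -(1/log n) * sum_i p_ij log p_ij` (zero terms contribute 0),
#' diversification `d_j = 1 - e_j`, weight `100 d_j / sum d`. A constant
#' column carries no information (`d_j = 0`, weight 0) and is flagged.
#'
#' @param data an [ordinal_dataset] or a numeric matrix of levels.
#' @return A [weight_vector] with `diagnostics$entropy` and
#'   `diagnostics$constant` (names of zero-information factors).
#' @export
entropy_weights <- function(data) {
  X <- if (inherits(data, "ordinal_dataset")) data$levels else as.matrix(data)
  fnames <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 countries")
  P <- sweep(X, 2, colSums(X), "/")
  plogp <- ifelse(P > 0, P * log(P), 0)
  e <- -colSums(plogp) / log(n)
  d <- 1 - e
  d[abs(d) < 1e-12] <- 0
  constant <- fnames[apply(X, 2, function(col) length(unique(col)) == 1)]
  if (sum(d) <= 0)
    stop("no information: every factor column is constant")
  weight_vector(fnames, 100 * d / sum(d), "entropy",
                list(entropy = stats::setNames(e, fnames),
                     constant = constant))
}

#' Equal weights
#'
#' @param factor_names character vector of factor names.
#' @return A [weight_vector] with `100 / k` per factor.
#' @export
equal_weights <- function(factor_names) {
  k <- length(factor_names)
  if (k < 1) stop("need at least one factor")
  weight_vector(factor_names, rep(100 / k, k), "equal")
}

#' Derive weights by a named method
#'
#' Dispatch helper used by [run_pipeline()].
#'
#' @param data an [ordinal_dataset].
#' @param method one of `"polychoric_pca"`, `"efa"`, `"entropy"`, `"equal"`.
#' @param ... passed to the method (e.g. `transform` for PCA).
#' @return A [weight_vector].
#' @export
derive_weights <- function(data, method = c("polychoric_pca", "efa",
                                            "entropy", "equal"), ...) {
  method <- match.arg(method)
  switch(method,
         polychoric_pca = pca_weights(polychoric_matrix(data), ...),
         efa = efa_weights(polychoric_matrix(data)),
         entropy = entropy_weights(data),
         equal = equal_weights(data$factor_names))
}
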