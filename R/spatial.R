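# Regression stage: predictor preparation, Gaussian GLMs with landform
# interactions, AIC stepwise selection, leave-one-out importance, k-nearest-
# neighbour spatial weights, Moran's I diagnostics, and a maximum-likelihood
# spatial error model.

#' Min-max standardization to [0, 1]
#'
#' Maps every numeric column affinely onto [0, 1] via
#' `(x - min) / (max - min)`.
#'
#' @param x Data frame or matrix of numeric columns.
#' @return Object of the same shape with all columns in [0, 1].
#' @export
minmax_standardize <- function(x) {
  df <- as.data.frame(x)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]))
      stop(sprintf("column '%s' is not numeric", nm), call. = FALSE)
    r <- range(df[[nm]], na.rm = TRUE)
    if (r[2] <= r[1])
      stop(sprintf("column '%s' is constant; cannot min-max standardize", nm),
           call. = FALSE)
    df[[nm]] <- (df[[nm]] - r[1]) / (r[2] - r[1])
  }
  if (is.matrix(x)) as.matrix(df) else df
}

#' Drop collinear columns by pairwise correlation
#'
#' Iteratively removes columns while any pair has |Pearson r| above the
#' threshold: of the offending pair, the column with the larger mean
#' absolute correlation to all remaining columns is dropped (ties: the
#' later column in input order).
#'
#' @param x Data frame or matrix of numeric columns (>= 2).
#' @param threshold Correlation threshold (default 0.95).
#' @return List with `kept` (the reduced table) and `dropped` (character
#'   vector of removed column names, in removal order).
#' @export
filter_collinear <- function(x, threshold = 0.95) {
  df <- as.data.frame(x)
  if (ncol(df) < 2) stop("need at least 2 columns", call. = FALSE)
  dropped <- character(0)
  repeat {
    if (ncol(df) < 2) break
    C <- abs(stats::cor(as.matrix(df)))
    diag(C) <- 0
    if (max(C) <= threshold) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(abs(stats::cor(as.matrix(df))) -
                           diag(ncol(df))) * ncol(df) / (ncol(df) - 1)
    i <- ij[1]; j <- ij[2]
    drop_idx <- if (mean_abs[i] > mean_abs[j]) i
                else if (mean_abs[j] > mean_abs[i]) j
                else max(i, j)
    dropped <- c(dropped, names(df)[drop_idx])
    df <- df[, -drop_idx, drop = FALSE]
  }
  list(kept = df, dropped = dropped)
}

relevel_references <- function(data, reference) {
  for (nm in names(reference)) {
    if (nm %in% names(data)) {
      data[[nm]] <- stats::relevel(factor(data[[nm]]), ref = reference[[nm]])
    }
  }
  data
}

#' Gaussian GLM with landform reference coding
#'
#' Fits a Gaussian identity-link GLM (least squares) with categorical
#' predictors dummy-coded against configurable reference levels (by
#' default landform against `Danxia` and tectonic against `craton`).
#' Interactions are expressed in the formula (e.g. `landform:TCQ`).
#' `deviance_explained` is `100 * (1 - residual / null deviance)`, which
#' equals R-squared for this family.
#'
#' @param formula Model formula.
#' @param data Data frame of response and predictors.
#' @param reference Named character vector mapping factor columns to their
#'   reference level.
#' @return Object of class `flora_glm`: list with `fit` (the `glm`),
#'   `deviance_explained` (percent), `aic`, `reference`.
#' @export
fit_glm <- function(formula, data,
                    reference = c(landform = "Danxia", tectonic = "craton")) {
  data <- relevel_references(data, reference)
  fit <- stats::glm(formula, data = data, family = stats::gaussian())
  fit$call$data <- data   # embed the data so update()/step() work anywhere
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient design: aliased coefficients dropped (NA)",
            call. = FALSE)
  structure(list(fit = fit,
                 deviance_explained = 100 * (1 - fit$deviance / fit$null.deviance),
                 aic = stats::AIC(fit),
                 reference = reference),
            class = "flora_glm")
}

#' @export
print.flora_glm <- function(x, ...) {
  cat("Gaussian GLM:", deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("  deviance explained = %.2f%%, AIC = %.2f\n",
              x$deviance_explained, x$aic))
  invisible(x)
}

#' @export
coef.flora_glm <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.flora_glm <- function(object, ...) stats::residuals(object$fit)

#' Stepwise AIC model selection
#'
#' Backward-forward stepwise selection by AIC starting from a fitted
#' [fit_glm()] model; marginality is respected (an interaction is never
#' retained without its main effects). Deterministic given the data.
#'
#' @param object A `flora_glm` fit.
#' @param scope Optional `step()` scope (defaults to the current terms).
#' @return The selected model as a `flora_glm`.
#' @export
step_aic <- function(object, scope = NULL) {
  fit <- object$fit
  selected <- if (is.null(scope)) stats::step(fit, trace = 0)
              else stats::step(fit, scope = scope, trace = 0)
  structure(list(fit = selected,
                 deviance_explained = 100 * (1 - selected$deviance / selected$null.deviance),
                 aic = stats::AIC(selected),
                 reference = object$reference),
            class = "flora_glm")
}

#' Leave-one-out term importance
#'
#' For each term group of the model (a factor such as landform counts as
#' one group of dummies; each interaction is its own group), refits the
#' model without that group — also removing any higher-order term that
#' contains it — and reports the drop in deviance explained, in percentage
#' points. Because predictors are correlated, the deltas need not sum to
#' the total deviance explained.
#'
#' @param object A `flora_glm` fit.
#' @return Data frame with `term` and `delta_deviance_explained`, sorted
#'   decreasing.
#' @export
loo_importance <- function(object) {
  fit <- object$fit
  labs <- attr(stats::terms(fit), "term.labels")
  if (length(labs) == 0) stop("model has no terms to drop", call. = FALSE)
  de_full <- 100 * (1 - fit$deviance / fit$null.deviance)
  parts <- strsplit(labs, ":", fixed = TRUE)
  delta <- vapply(seq_along(labs), function(i) {
    contains <- vapply(parts, function(p) all(parts[[i]] %in% p), logical(1))
    drop_terms <- labs[contains]
    f <- stats::as.formula(paste(". ~ . -", paste(drop_terms, collapse = " - ")))
    red <- stats::update(fit, f)
    de_full - 100 * (1 - red$deviance / red$null.deviance)
  }, numeric(1))
  out <- data.frame(term = labs, delta_deviance_explained = delta,
                    stringsAsFactors = FALSE)
  out[order(-out$delta_deviance_explained), , drop = FALSE]
}

#' k-nearest-neighbour spatial weights
#'
#' Builds row-standardized spatial weights from site coordinates: each
#' site's k nearest neighbours by great-circle distance get equal weight
#' `1/k`. Distance ties are broken by site order; a site is never its own
#' neighbour.
#'
#' @param coords Two-column matrix or data frame of longitude, latitude
#'   (degrees).
#' @param k Number of neighbours (1 <= k < n).
#' @return Object of class `spatial_weights`: list with `W` (n x n
#'   row-standardized matrix), `neighbors` (list of index vectors), `k`.
#' @export
knn_weights <- function(coords, k = 8L) {
  coords <- as.matrix(coords[, 1:2])
  n <- nrow(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (k < 1 || k >= n) stop("need 1 <= k < number of sites", call. = FALSE)
  d <- geosphere::distm(coords)
  W <- matrix(0, n, n)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    nb[[i]] <- ord[seq_len(k)]
    W[i, nb[[i]]] <- 1 / k
  }
  structure(list(W = W, neighbors = nb, k = as.integer(k), n = n),
            class = "spatial_weights")
}

weights_matrix <- function(weights) {
  if (inherits(weights, "spatial_weights")) return(weights$W)
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square", call. = FALSE)
  W
}

#' Moran's I spatial autocorrelation
#'
#' Computes Moran's I of a variable under the supplied weights, with the
#' expectation `-1/(n-1)`, and a z score and two-sided p value under the
#' normality approximation.
#'
#' @param x Numeric vector (non-constant, n >= 4).
#' @param weights A [knn_weights()] object or weight matrix.
#' @return List with `I`, `expected`, `sd`, `z`, `p`.
#' @export
morans_i <- function(x, weights) {
  W <- weights_matrix(weights)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (nrow(W) != n) stop("weights do not match `x`", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` is constant; Moran's I undefined", call. = FALSE)
  r <- ape::Moran.I(x, W, scaled = FALSE, alternative = "two.sided")
  list(I = r$observed, expected = r$expected, sd = r$sd,
       z = (r$observed - r$expected) / r$sd, p = r$p.value)
}

#' Maximum-likelihood spatial error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`
#' by maximum likelihood: the log-likelihood is concentrated in `lambda`
#' (GLS beta and sigma^2 given lambda; log-determinant of `I - lambda W`
#' via the eigenvalues of W) and maximised by bounded scalar search on
#' (-0.999, 0.999) to tolerance 1e-6. Reports AIC as
#' `-2 logL + 2 (p + 2)` (beta, lambda, sigma^2), a Cox-Snell pseudo
#' R-squared against the intercept-only model (which reduces to ordinary
#' R-squared when lambda = 0), and Moran's I of the innovations
#' `(I - lambda W)(y - X beta)`.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param weights A [knn_weights()] object (row-standardized).
#' @param reference Reference levels, as in [fit_glm()].
#' @param lambda Optional fixed value of lambda; if `NULL` (default) it is
#'   estimated.
#' @return Object of class `flora_sem`: list with `coefficients` (table of
#'   estimate, se, z, p), `lambda`, `sigma2`, `logLik`, `aic`,
#'   `deviance_explained` (pseudo R-squared, percent), `residuals` (raw,
#'   `y - X beta`), `innovations`, `moran` (Moran's I of innovations).
#' @export
fit_sem_ml <- function(formula, data, weights,
                       reference = c(landform = "Danxia", tectonic = "craton"),
                       lambda = NULL) {
  data <- relevel_references(data, reference)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  W <- weights_matrix(weights)
  n <- length(y)
  if (nrow(W) != n) stop("weights do not match the data", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  ev <- eigen(W, only.values = TRUE)$values
  cll <- function(lam) {
    A <- diag(n) - lam * W
    fit <- stats::lm.fit(A %*% X, as.vector(A %*% y))
    s2 <- sum(fit$residuals^2) / n
    ld <- Re(sum(log(1 - lam * ev)))
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) + ld
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(cll, interval = c(-0.999, 0.999),
                           maximum = TRUE, tol = 1e-6)
    lam <- opt$maximum
    ll <- opt$objective
  } else {
    assert_scalar_number(lambda, "lambda")
    if (abs(lambda) >= 1) stop("|lambda| must be < 1", call. = FALSE)
    lam <- lambda
    ll <- cll(lam)
  }
  if (!is.finite(ll))
    stop("spatial error likelihood did not evaluate finitely at lambda = ",
         signif(lam, 4), call. = FALSE)
  A <- diag(n) - lam * W
  Xs <- A %*% X
  ys <- as.vector(A %*% y)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  s2 <- sum(fit$residuals^2) / n
  XtX_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(XtX_inv) * s2)
  z <- beta / se
  coefs <- data.frame(estimate = beta, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)))
  p <- ncol(X)
  aic <- -2 * ll + 2 * (p + 2)
  ll0 <- as.numeric(stats::logLik(stats::lm(y ~ 1)))
  pseudo_r2 <- 100 * (1 - exp(-2 / n * (ll - ll0)))
  raw <- as.vector(y - X %*% beta)
  innov <- as.vector(A %*% raw)
  moran <- tryCatch(morans_i(innov, W), error = function(e) NULL)
  structure(list(coefficients = coefs, lambda = lam, sigma2 = s2,
                 logLik = ll, aic = aic, deviance_explained = pseudo_r2,
                 residuals = raw, innovations = innov, moran = moran,
                 formula = formula, n = n),
            class = "flora_sem")
}

#' @export
print.flora_sem <- function(x, ...) {
  cat("Spatial error model:", deparse(x$formula), "\n")
  cat(sprintf("  lambda = %.4f, sigma2 = %.4g, logLik = %.2f, AIC = %.2f\n",
              x$lambda, x$sigma2, x$logLik, x$aic))
  cat(sprintf("  pseudo R-squared = %.2f%%\n", x$deviance_explained))
  if (!is.null(x$moran))
    cat(sprintf("  innovation Moran's I = %.4f (p = %.3g)\n",
                x$moran$I, x$moran$p))
  invisible(x)
}

#' @export
coef.flora_sem <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}
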