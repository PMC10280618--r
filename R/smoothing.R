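#' Unit-energy normalisation of a feature column
#'
#' Scales a raw feature column by the gain `g = 1 / sqrt(sum(x^2))` so the
#' squared values sum to one. The training gain is the one reused on test
#' data; an all-zero column gets gain 1 (with a warning) so downstream fits
#' stay finite.
#'
#' @param column Numeric vector of raw feature values.
#' @return A list with `gain` and `values` (`gain * column`).
#' @examples
#' unit_energy_normalize(c(3, 4))
#' @export
unit_energy_normalize <- function(column) {
  stopifnot(is.numeric(column), length(column) > 0, all(is.finite(column)))
  energy <- sum(column^2)
  if (energy == 0) {
    warning("all-zero column: unit-energy gain set to 1")
    return(list(gain = 1, values = column))
  }
  g <- 1 / sqrt(energy)
  list(gain = g, values = g * column)
}

#' Cubic design matrix
#'
#' Builds the `N x 4` Vandermonde matrix with row i equal to
#' `[1, x_i, x_i^2, x_i^3]`.
#'
#' @param x Numeric abscissa vector.
#' @param order Polynomial order (default 3).
#' @return Numeric matrix with `length(x)` rows and `order + 1` columns.
#' @export
design_matrix <- function(x, order = 3L) {
  stopifnot(is.numeric(x), all(is.finite(x)), order >= 0)
  outer(x, 0:order, `^`)
}

# map coefficients of p(u), u = alpha*x + beta, back to coefficients in x
rescale_coefs <- function(a_u, alpha, beta) {
  order <- length(a_u) - 1L
  a <- numeric(order + 1L)
  # (alpha x + beta)^k expanded via binomial theorem
  for (k in 0:order) {
    if (a_u[k + 1L] == 0) next
    for (j in 0:k) {
      a[j + 1L] <- a[j + 1L] +
        a_u[k + 1L] * choose(k, j) * alpha^j * beta^(k - j)
    }
  }
  a
}

# internal conditioning: x mapped to [-1, 1]; returns alpha, beta with
# u = alpha * x + beta
cond_map <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("abscissa values are all identical; cannot fit a cubic")
  alpha <- 2 / (hi - lo)
  beta <- -(hi + lo) / (hi - lo)
  list(alpha = alpha, beta = beta)
}

new_poly_fit <- function(a, criterion, x, y, order = 3L) {
  X <- design_matrix(x, order)
  fitted <- drop(X %*% a)
  r <- fitted - y
  objective <- switch(criterion,
    L2 = sum(r^2),
    L1 = sum(abs(r)),
    Linf = max(abs(r))
  )
  structure(
    list(a = as.numeric(a), criterion = criterion, objective = objective,
         fitted = fitted, x = x, y = y, order = order),
    class = "poly_fit"
  )
}

#' @export
print.poly_fit <- function(x, ...) {
  cat("<poly_fit> criterion =", x$criterion,
      "| order =", x$order, "| n =", length(x$y), "\n")
  cat("  a =", paste(signif(x$a, 6), collapse = ", "), "\n")
  cat("  objective =", signif(x$objective, 6), "\n")
  invisible(x)
}

#' Tidy a polynomial fit
#'
#' @param x A `poly_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.poly_fit <- function(x, ...) {
  tibble::tibble(term = paste0("a", seq_along(x$a) - 1L), estimate = x$a)
}

#' One-row summary of a polynomial fit
#'
#' @param x A `poly_fit` object.
#' @param ... Unused.
#' @return A tibble with `criterion`, `objective`, `n.obs`.
#' @exportS3Method generics::glance
glance.poly_fit <- function(x, ...) {
  tibble::tibble(criterion = x$criterion, objective = x$objective,
                 n.obs = length(x$y))
}

#' Least-squares cubic fit
#'
#' Fits `y ~ a0 + a1 x + a2 x^2 + a3 x^3` by minimising the residual energy;
#' the solution satisfies the normal equations (residual orthogonal to the
#' design columns). The abscissa is rescaled to `[-1, 1]` internally for
#' conditioning and coefficients are mapped back exactly.
#'
#' @param x,y Numeric vectors of equal length, at least 4 points.
#' @param order Polynomial order (default 3).
#' @return A `poly_fit` object (criterion `"L2"`).
#' @export
fit_poly_l2 <- function(x, y, order = 3L) {
  check_fit_input(x, y, order)
  cm <- cond_map(x)
  u <- cm$alpha * x + cm$beta
  X <- design_matrix(u, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    a_u <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else {
    a_u <- qr.coef(qrX, y)
  }
  new_poly_fit(rescale_coefs(drop(a_u), cm$alpha, cm$beta), "L2", x, y, order)
}

# Shared LP core for the L1 and Linf criteria. Residual constraints
#   Xa - y <= s  and  -(Xa - y) <= s
# are linearised with free-sign coefficients split as a = p - m and the
# slack block s being either one variable per point (L1) or a single
# scalar (Linf). Rows are routed to the <= or >= constraint block of
# boot::simplex so every right-hand side is non-negative.
solve_poly_lp <- function(x, y, order, slack) {
  cm <- cond_map(x)
  u <- cm$alpha * x + cm$beta
  X <- design_matrix(u, order)
  n <- nrow(X); p <- ncol(X)
  n_slack <- if (slack == "per_point") n else 1L
  slack_block <- function(i) {
    e <- numeric(n_slack)
    e[if (slack == "per_point") i else 1L] <- 1
    e
  }
  nv <- 2L * p + n_slack
  obj <- c(numeric(2L * p), rep(1, n_slack))
  A1 <- NULL; b1 <- numeric(0)   # A1 %*% v <= b1
  A2 <- NULL; b2 <- numeric(0)   # A2 %*% v >= b2
  for (i in seq_len(n)) {
    xi <- X[i, ]; s <- slack_block(i)
    # X_i a - s <= y_i
    r1 <- c(xi, -xi, -s)
    # -X_i a - s <= -y_i
    r2 <- c(-xi, xi, -s)
    if (y[i] >= 0) {
      A1 <- rbind(A1, r1); b1 <- c(b1, y[i])
      A2 <- rbind(A2, -r2); b2 <- c(b2, y[i])
    } else {
      A2 <- rbind(A2, -r1); b2 <- c(b2, -y[i])
      A1 <- rbind(A1, r2); b1 <- c(b1, -y[i])
    }
  }
  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE, eps = 1e-10)
  if (sol$solved != 1) {
    stop("linear program did not converge (boot::simplex status ",
         sol$solved, ")")
  }
  v <- sol$soln
  a_u <- v[seq_len(p)] - v[p + seq_len(p)]
  rescale_coefs(a_u, cm$alpha, cm$beta)
}

#' Least-absolute-deviation cubic fit (linear program)
#'
#' Fits the cubic minimising the sum of absolute residuals. The problem is
#' posed as the standard linear program with one dummy slack variable per
#' point bounding the absolute residual from above, and solved by the
#' simplex method.
#'
#' @inheritParams fit_poly_l2
#' @return A `poly_fit` object (criterion `"L1"`).
#' @export
fit_poly_l1 <- function(x, y, order = 3L) {
  check_fit_input(x, y, order)
  a <- solve_poly_lp(x, y, order, slack = "per_point")
  new_poly_fit(a, "L1", x, y, order)
}

#' Minimax (Chebyshev) cubic fit (linear program)
#'
#' Fits the cubic minimising the maximum absolute residual. A single scalar
#' slack bounds every absolute residual and is minimised by the simplex
#' method.
#'
#' @inheritParams fit_poly_l2
#' @return A `poly_fit` object (criterion `"Linf"`).
#' @export
fit_poly_linf <- function(x, y, order = 3L) {
  check_fit_input(x, y, order)
  a <- solve_poly_lp(x, y, order, slack = "scalar")
  new_poly_fit(a, "Linf", x, y, order)
}

check_fit_input <- function(x, y, order) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  if (length(x) < order + 1L) {
    stop("need at least ", order + 1L, " points for an order-", order, " fit")
  }
  invisible(NULL)
}

#' Fit a cubic under a named criterion
#'
#' @inheritParams fit_poly_l2
#' @param criterion One of `"L1"`, `"L2"`, `"Linf"`.
#' @return A `poly_fit` object.
#' @export
fit_poly <- function(x, y, criterion = c("L2", "L1", "Linf"), order = 3L) {
  criterion <- match.arg(criterion)
  switch(criterion,
    L2 = fit_poly_l2(x, y, order),
    L1 = fit_poly_l1(x, y, order),
    Linf = fit_poly_linf(x, y, order)
  )
}

#' Smooth reference glucose values against every feature column
#'
#' Rows are sorted by ascending glucose (stable); for each feature column a
#' cubic of glucose on that column is fitted under the chosen criterion and
#' its fitted vector recorded; the smoothed glucose is the element-wise mean
#' of the per-feature fitted vectors, returned in the original row order.
#' Each feature's fit uses the original glucose vector (parallel averaging,
#' not chaining), so the result does not depend on feature order.
#'
#' @param features Numeric matrix or data frame, one row per measurement,
#'   one column per (normalised) feature.
#' @param glucose Numeric vector of reference glucose values (mmol/L).
#' @param criterion `"L1"`, `"L2"` or `"Linf"`.
#' @return Numeric vector of smoothed glucose values, same length and order
#'   as `glucose`.
#' @export
smooth_reference <- function(features, glucose, criterion = c("L2", "L1", "Linf")) {
  criterion <- match.arg(criterion)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(glucose), nrow(features) >= 4)
  ord <- order(glucose)                       # stable: ties by original index
  g_sorted <- glucose[ord]
  fitted_cols <- list()
  for (j in seq_len(ncol(features))) {
    xj <- features[ord, j]
    fit <- tryCatch(fit_poly(xj, g_sorted, criterion),
                    error = function(e) {
                      warning("skipping feature column ", j,
                              " in reference smoothing: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) fitted_cols[[length(fitted_cols) + 1L]] <- fit$fitted
  }
  if (length(fitted_cols) == 0) stop("no feature column could be fitted")
  smoothed_sorted <- rowMeans(do.call(cbind, fitted_cols))
  out <- numeric(length(glucose))
  out[ord] <- smoothed_sorted
  out
}

#' Smooth feature columns along the glucose axis
#'
#' Rows are sorted by ascending glucose; each feature column independently
#' is replaced by the fitted values of a cubic of the feature on glucose
#' under the chosen criterion; rows are returned in the original order.
#' A column whose fit fails is left unsmoothed with a warning.
#'
#' @inheritParams smooth_reference
#' @return Numeric matrix of the same shape as `features`.
#' @export
smooth_features <- function(features, glucose, criterion = c("L2", "L1", "Linf")) {
  criterion <- match.arg(criterion)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(glucose), nrow(features) >= 4)
  ord <- order(glucose)
  g_sorted <- glucose[ord]
  out <- features
  for (j in seq_len(ncol(features))) {
    yj <- features[ord, j]
    fit <- tryCatch(fit_poly(g_sorted, yj, criterion),
                    error = function(e) {
                      warning("leaving feature column ", j, " unsmoothed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) out[ord, j] <- fit$fitted
  }
  out
}
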