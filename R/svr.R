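#' Linear epsilon-insensitive support vector regression
#'
#' Solves the primal problem
#' `min 0.5 ||w||^2 + C * sum_i max(0, |y_i - w'x_i - b| - epsilon)`
#' by quasi-Newton descent from the ridge solution.  With one or two
#' predictors (the use case here: cytoarchitectonic difference and/or
#' rostrocaudal offset) the problem is tiny and the piecewise-linear loss
#' poses no practical difficulty for BFGS with the subgradient.
#'
#' Predictors are standardized internally on the supplied (training)
#' data; `epsilon = NULL` defaults to `0.1 * sd(y)`, scaling the
#' insensitive tube to the response.
#'
#' @param x numeric matrix (n x p) of predictors.
#' @param y numeric response.
#' @param C box/regularization constant (> 0), default 1.
#' @param epsilon insensitive-tube half width.
#' @return object of class `svr_fit` (weights on the original predictor
#'   scale via the stored standardization).
#' @export
svr_fit <- function(x, y, C = 1, epsilon = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), C > 0)
  if (is.null(epsilon)) epsilon <- 0.1 * sd(y)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1                        # constant column: leave as zero
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  p <- ncol(xs)

  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- y - xs %*% w - b
    0.5 * sum(w^2) + C * sum(pmax(0, abs(r) - epsilon))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    r <- as.numeric(y - xs %*% w - b)
    active <- abs(r) > epsilon
    s <- sign(r) * active
    c(w - C * as.numeric(crossprod(xs, s)), -C * sum(s))
  }
  # ridge start keeps the descent deterministic and close to the optimum
  start <- tryCatch({
    A <- crossprod(cbind(xs, 1)) + diag(1e-6, p + 1)
    as.numeric(solve(A, crossprod(cbind(xs, 1), y)))
  }, error = function(e) c(rep(0, p), mean(y)))
  fit <- optim(start, obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1],
                 center = ctr, scale = scl, C = C, epsilon = epsilon,
                 value = fit$value, kernel = "linear"),
            class = "svr_fit")
}

#' Predict from a linear SVR fit
#'
#' @param object an `svr_fit`.
#' @param newdata numeric matrix with the same columns as the training
#'   predictors.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(xs %*% object$w + object$b)
}
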