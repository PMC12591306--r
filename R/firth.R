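## Firth penalized logistic regression: Newton iteration on the Jeffreys-
## penalized likelihood l*(beta) = l(beta) + 0.5 log det I(beta), with the
## Firth-modified score, penalized likelihood-ratio p-values, and
## profile-penalized-likelihood confidence intervals. Estimates stay finite
## under complete separation, which is why sparse CH outcomes use it.

.firthParts <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  W <- mu * (1 - mu)
  XtWX <- crossprod(X * W, X)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  ## hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2
  XtWXinv <- chol2inv(ch)
  h <- rowSums((X %*% XtWXinv) * X) * W
  ## log-likelihood computed from eta, stable under mu -> 0/1 underflow
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  penll <- ll + 0.5 * logdet
  if (!is.finite(penll)) return(NULL)
  list(mu = mu, W = W, XtWX = XtWX, XtWXinv = XtWXinv, h = h,
       ll = ll, penll = penll)
}

.firthEngine <- function(X, y, start = NULL, fixed = integer(0),
                         tol = 1e-8, max_iter = 100) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  free <- setdiff(seq_len(p), fixed)
  parts <- .firthParts(X, y, beta)
  if (is.null(parts)) stop("information matrix is singular at the start")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Ustar <- drop(crossprod(X, y - parts$mu + parts$h * (0.5 - parts$mu)))
    if (max(abs(Ustar[free])) < tol) { converged <- TRUE; break }
    delta <- numeric(p)
    delta[free] <- solve(parts$XtWX[free, free, drop = FALSE], Ustar[free])
    step <- 1
    repeat {
      cand <- beta + step * delta
      candParts <- .firthParts(X, y, cand)
      if (!is.null(candParts) && candParts$penll >= parts$penll - 1e-12)
        break
      step <- step / 2
      if (step < 1e-8) { candParts <- parts; cand <- beta; break }
    }
    if (identical(cand, beta)) break
    beta <- cand
    parts <- candParts
  }
  list(beta = beta, parts = parts, iter = iter, converged = converged)
}

#' Fit a Firth penalized logistic regression
#'
#' @param X design matrix including an intercept column, or a formula.
#' @param y binary outcome vector (0/1 or logical); with a formula, a data
#'   frame must be supplied instead.
#' @param data data.frame used when `X` is a formula.
#' @param level confidence level for the profile CIs (default 0.95).
#' @param ci "profile" (default) for profile-penalized-likelihood intervals,
#'   "wald" for Wald intervals.
#' @param tol convergence tolerance on the modified score.
#' @param max_iter Newton iteration cap.
#' @return A [FirthFit-class] with coefficients, standard errors, CIs and
#'   penalized likelihood-ratio p-values.
#' @examples
#' ## sparse 2x2 data: 2/10 events vs 0/10
#' y <- c(rep(1, 2), rep(0, 8), rep(0, 10))
#' g <- c(rep(1, 10), rep(0, 10))
#' fit <- fitFirthLogistic(cbind(1, group = g), y)
#' coef(fit)["group"]  # log[(2.5 * 10.5) / (8.5 * 0.5)]
#' @export
fitFirthLogistic <- function(X, y = NULL, data = NULL, level = 0.95,
                             ci = c("profile", "wald"), tol = 1e-8,
                             max_iter = 100) {
  ci <- match.arg(ci)
  if (inherits(X, "formula")) {
    mf <- stats::model.frame(X, data)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(X, data)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- .firthEngine(X, y, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning("Firth fit did not converge in ", max_iter,
            " iterations; returning last iterate")
  beta <- stats::setNames(fit$beta, colnames(X))
  vc <- fit$parts$XtWXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  ## penalized LRT p-values: profile each coefficient at zero
  pvals <- vapply(seq_along(beta), function(j) {
    b0 <- fit$beta; b0[j] <- 0
    prof <- .firthEngine(X, y, start = b0, fixed = j,
                         tol = tol, max_iter = max_iter)
    stat <- 2 * (fit$parts$penll - prof$parts$penll)
    stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  obj <- new("FirthFit", coef = beta, se = se, vcov = vc,
             ci = matrix(NA_real_, length(beta), 2,
                         dimnames = list(names(beta), c("lower", "upper"))),
             p = stats::setNames(pvals, names(beta)), level = level,
             penloglik = fit$parts$penll, loglik = fit$parts$ll,
             iter = fit$iter, converged = fit$converged, X = X, y = y)
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald <- cbind(lower = beta - z * se, upper = beta + z * se)
  if (ci == "wald") {
    obj@ci <- wald
  } else {
    for (j in seq_along(beta))
      obj@ci[j, ] <- tryCatch(profilePenalizedCI(obj, j, level),
                              error = function(e) wald[j, ])
  }
  obj
}

#' Profile-penalized-likelihood confidence interval
#'
#' Endpoints are the values of the target coefficient where twice the drop
#' in profile penalized log-likelihood from its maximum equals the
#' chi-square(1) quantile at `level`, located by root bisection after
#' bracketing outward from the estimate in standard-error steps.
#'
#' @param fit a [FirthFit-class].
#' @param predictor coefficient name or index.
#' @param level confidence level.
#' @return numeric `(lower, upper)`, always containing the point estimate.
#' @export
profilePenalizedCI <- function(fit, predictor, level = 0.95) {
  stopifnot(is(fit, "FirthFit"))
  j <- if (is.character(predictor)) match(predictor, names(fit@coef))
       else as.integer(predictor)
  if (is.na(j)) stop("unknown predictor: ", predictor)
  X <- fit@X; y <- fit@y
  target <- stats::qchisq(level, df = 1)
  profPenll <- function(b) {
    start <- fit@coef; start[j] <- b
    .firthEngine(X, y, start = start, fixed = j)$parts$penll
  }
  f <- function(b) 2 * (fit@penloglik - profPenll(b)) - target
  hat <- fit@coef[j]
  step <- max(fit@se[j], 0.5)
  bound <- function(dir) {
    lo <- hat
    for (k in 1:30) {
      hi <- hat + dir * step * 2^(k / 2)
      if (f(hi) > 0)
        return(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-6)$root)
      lo <- hi
    }
    stop("CI endpoint not bracketed for ", names(fit@coef)[j])
  }
  c(lower = bound(-1), upper = bound(1))
}

#' Penalized likelihood-ratio statistic for one coefficient
#'
#' Used by [optimizeDoseCutoff()] as its default criterion.
#'
#' @param fit a [FirthFit-class].
#' @param predictor coefficient name or index.
#' @return twice the penalized log-likelihood drop when the coefficient is
#'   profiled at zero.
#' @export
firthLrtStat <- function(fit, predictor) {
  j <- if (is.character(predictor)) match(predictor, names(fit@coef))
       else as.integer(predictor)
  b0 <- fit@coef; b0[j] <- 0
  prof <- .firthEngine(fit@X, fit@y, start = b0, fixed = j)
  max(2 * (fit@penloglik - prof$parts$penll), 0)
}
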