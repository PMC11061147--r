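# Linear generalized estimating equations with an exchangeable working
# correlation, clustered on subject, and the cluster-robust (sandwich)
# covariance.  Classic Liang-Zeger moment estimation; with one observation
# per cluster the estimator reduces exactly to ordinary least squares.

.geeFit <- function(X, y, id, maxit = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  cl <- split(seq_len(n), id)
  beta <- qr.coef(qr(X), y)                 # OLS start
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    phi <- sum(r^2) / (n - p)
    num <- 0; den <- 0
    for (ix in cl) {
      m <- length(ix)
      if (m > 1L) {
        rr <- r[ix]
        num <- num + (sum(rr)^2 - sum(rr^2)) / 2
        den <- den + m * (m - 1) / 2
      }
    }
    alpha <- if (den > 0) num / (den * phi) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in cl) {
      m <- length(ix)
      Ri <- matrix(alpha, m, m); diag(Ri) <- 1
      Wi <- solve(Ri) / phi
      Xi <- X[ix, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      b <- b + crossprod(Xi, Wi %*% y[ix])
    }
    betaNew <- solve(A, b)
    if (max(abs(betaNew - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  converged <- it < maxit
  r <- y - drop(X %*% beta)
  phi <- sum(r^2) / (n - p)
  A <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (ix in cl) {
    m <- length(ix)
    Ri <- matrix(alpha, m, m); diag(Ri) <- 1
    Wi <- solve(Ri) / phi
    Xi <- X[ix, , drop = FALSE]
    A <- A + crossprod(Xi, Wi %*% Xi)
    u <- crossprod(Xi, Wi %*% r[ix])
    meat <- meat + tcrossprod(u)
  }
  Ainv <- solve(A)
  g <- length(cl)
  # finite-cluster correction g/(g - p) on the sandwich
  vc <- Ainv %*% meat %*% Ainv * g / max(g - p, 1L)
  list(coefficients = drop(beta), vcov = vc, alpha = alpha, phi = phi,
       nClusters = g, df = max(g - p, 1L), converged = converged)
}

#' Linear GEE for paired-eye outcomes
#'
#' Fits outcome ~ covariates with an exchangeable working correlation within
#' subject and reports cluster-robust 95% confidence intervals.  Follows the
#' univariable-then-multivariable screen: covariates with univariable
#' p < `pEnter` enter the multivariable model.
#'
#' @param records data.frame with one row per eye, a `subject_id` column,
#'   the outcome column and the candidate columns.
#' @param outcome name of the (numeric) outcome column.
#' @param candidates character vector of candidate covariate names.
#' @param pEnter univariable screening threshold (default 0.10).
#' @return list with `univariable` and `multivariable` coefficient tables
#'   (term, estimate, ci_low, ci_high, p) and the fitted `model`.
#' @export
geeLinear <- function(records, outcome, candidates, pEnter = 0.10) {
  stopifnot(outcome %in% names(records), all(candidates %in% names(records)))
  d <- records[stats::complete.cases(records[, c("subject_id", outcome,
                                                 candidates)]), ]
  oneTable <- function(vars) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(.numericCovariates(d[, vars, drop = FALSE])))
    fit <- .geeFit(X, d[[outcome]], d$subject_id)
    se <- sqrt(diag(fit$vcov))
    tq <- stats::qt(0.975, fit$df)       # cluster degrees of freedom
    z <- fit$coefficients / se
    data.frame(term = colnames(X), estimate = fit$coefficients,
               ci_low = fit$coefficients - tq * se,
               ci_high = fit$coefficients + tq * se,
               p = 2 * stats::pt(-abs(z), fit$df), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(candidates, function(v) {
    tb <- oneTable(v)
    tb[tb$term != "(Intercept)", ]
  }))
  keepTerms <- unique(uni$term[uni$p < pEnter])
  keep <- candidates[vapply(candidates, function(v)
    any(startsWith(keepTerms, v)), TRUE)]
  multi <- if (length(keep)) oneTable(keep) else NULL
  X <- cbind(`(Intercept)` = 1,
             as.matrix(.numericCovariates(d[, candidates, drop = FALSE])))
  list(univariable = uni, multivariable = multi,
       model = .geeFit(X, d[[outcome]], d$subject_id))
}

# expand factors/characters to dummy columns, keep numerics as-is
.numericCovariates <- function(d) {
  out <- lapply(names(d), function(v) {
    x <- d[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(v, levels(f)[-1])
    }
    m
  })
  do.call(cbind, out)
}
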