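# Generalized estimating equations for longitudinal binary outcomes with a
# logit link, fitted by Fisher scoring on the GEE score
#   sum_i D_i' V_i^{-1} (y_i - mu_i) = 0,
# where V_i = phi * A_i^{1/2} R(alpha) A_i^{1/2} and R is the working
# correlation. The first-order autoregressive structure exploits the
# tridiagonal inverse of an AR-1 correlation matrix, so every step is O(N p)
# and vectorised across clusters; no n_i x n_i matrix is ever formed. The
# correlation parameter is estimated by the usual moment (Pearson-residual)
# estimator, and inference uses the robust sandwich covariance
#   B^{-1} (sum_i g_i g_i') B^{-1},  g_i = D_i' V_i^{-1} (y_i - mu_i).

# Multiply R(alpha)^{-1} by the columns of M, cluster-wise, for the AR-1
# structure. `first`/`last` flag each cluster's first and last row;
# `single` flags singleton clusters (R = 1 there).
ar1_rinv_mult <- function(M, alpha, first, last, single) {
  if (alpha == 0) return(M)
  M <- as.matrix(M)
  n <- nrow(M)
  up <- rbind(M[-1, , drop = FALSE], 0)    # row j holds M[j + 1, ]
  up[last, ] <- 0
  down <- rbind(0, M[-n, , drop = FALSE])  # row j holds M[j - 1, ]
  down[first, ] <- 0
  avec <- rep(1 + alpha^2, n)
  avec[first | last] <- 1
  out <- (avec * M - alpha * (up + down)) / (1 - alpha^2)
  out[single, ] <- M[single, , drop = FALSE]
  out
}

# Multiply R(alpha)^{-1} M for the exchangeable structure:
# R^{-1} = (1/(1-a)) [I - a/(1 + (m-1)a) J] per cluster of size m.
exch_rinv_mult <- function(M, alpha, cluster, csize) {
  if (alpha == 0) return(M)
  M <- as.matrix(M)
  colsums <- rowsum(M, cluster, reorder = FALSE)
  m <- csize[match(cluster, rownames(colsums))]
  # expand cluster sums back to rows
  expand <- colsums[match(cluster, rownames(colsums)), , drop = FALSE]
  shrink <- alpha / (1 + (m - 1) * alpha)
  (M - shrink * expand) / (1 - alpha)
}

#' Fit a binary-outcome GEE with a logit link
#'
#' Matrix-interface fitter used by the analysis wrappers
#' ([fit_implementation_gee()], [fit_adherence_gee()]). Rows must be grouped
#' by cluster and time-ordered within cluster; adjacent rows of a cluster are
#' treated as lag-1 neighbours by the AR-1 working correlation.
#'
#' @param X design matrix (with intercept column).
#' @param y 0/1 response.
#' @param cluster cluster (patient) identifier, same length as `y`.
#' @param corstr working correlation: `"ar1"` (default), `"independence"` or
#'   `"exchangeable"`.
#' @param maxit,tol Fisher-scoring iteration cap and convergence tolerance on
#'   the coefficient step.
#' @return an object of class `"em_gee"`: coefficients, robust and naive
#'   covariances, the working-correlation and dispersion estimates, and a
#'   model card (`n_patients`, `n_obs`, iteration count).
#' @export
gee_binary <- function(X, y, cluster, corstr = c("ar1", "independence", "exchangeable"),
                       maxit = 100, tol = 1e-8) {
  corstr <- arg_match(corstr)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  cluster <- as.character(cluster[keep])
  N <- length(y)
  p <- ncol(X)
  if (N < 2 * p) stop_data("too few observations to fit the GEE")
  if (all(y == 1) || all(y == 0)) {
    abort(
      paste0(
        "outcome is identically ", y[1], ": no finite GEE estimate exists. ",
        "Report the implementation as the constant ", y[1],
        " instead of fitting (degenerate-case shortcut)."
      ),
      class = "emadhere_degenerate_error"
    )
  }
  # cluster bookkeeping (rows assumed cluster-contiguous and time-ordered)
  first <- !duplicated(cluster)
  last <- rev(!duplicated(rev(cluster)))
  csize_tab <- table(cluster)[unique(cluster)]
  single <- first & last
  n_clusters <- sum(first)

  beta <- tryCatch(
    suppressWarnings(
      glm.fit(X, y, family = binomial())$coefficients
    ),
    error = function(e) rep(0, p)
  )
  if (any(!is.finite(beta))) beta <- rep(0, p)

  alpha <- 0
  phi <- 1
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    e <- (y - mu) / sqrt(w)
    phi <- sum(e^2) / (N - p)

    if (corstr == "ar1") {
      e_next <- c(e[-1], 0)
      pairs <- !last
      n_pairs <- sum(pairs)
      alpha <- if (n_pairs > p) {
        sum(e[pairs] * e_next[pairs]) / ((n_pairs - p) * phi)
      } else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    } else if (corstr == "exchangeable") {
      sums <- rowsum(e, cluster, reorder = FALSE)
      sqs <- rowsum(e^2, cluster, reorder = FALSE)
      m <- as.numeric(csize_tab)
      denom <- sum(m * (m - 1)) - p
      alpha <- if (denom > 0) sum(sums^2 - sqs) / (denom * phi) else 0
      alpha <- max(min(alpha, 0.99), -1 / max(m - 1, 1) + 1e-6)
    }

    U <- sqrt(w) * X
    if (corstr == "ar1") {
      Q <- ar1_rinv_mult(U, alpha, first, last, single)
      q <- drop(ar1_rinv_mult(matrix(e), alpha, first, last, single))
    } else if (corstr == "exchangeable") {
      Q <- exch_rinv_mult(U, alpha, cluster, csize_tab)
      q <- drop(exch_rinv_mult(matrix(e), alpha, cluster, csize_tab))
    } else {
      Q <- U
      q <- e
    }
    B <- crossprod(U, Q)
    g <- drop(crossprod(U, q))
    step <- tryCatch(solve(B, g), error = function(e) {
      abort(paste0("GEE information matrix is singular: ", conditionMessage(e)),
            class = "emadhere_fit_error")
    })
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
  }
  if (!converged) {
    abort(glue::glue(
      "GEE did not converge in {maxit} iterations ",
      "(last step {signif(max(abs(step)), 3)}, alpha {signif(alpha, 3)})"
    ), class = "emadhere_fit_error")
  }

  # final quantities at the solution
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  e <- (y - mu) / sqrt(w)
  U <- sqrt(w) * X
  if (corstr == "ar1") {
    Q <- ar1_rinv_mult(U, alpha, first, last, single)
    q <- drop(ar1_rinv_mult(matrix(e), alpha, first, last, single))
  } else if (corstr == "exchangeable") {
    Q <- exch_rinv_mult(U, alpha, cluster, csize_tab)
    q <- drop(exch_rinv_mult(matrix(e), alpha, cluster, csize_tab))
  } else {
    Q <- U
    q <- e
  }
  B <- crossprod(U, Q)
  Binv <- solve(B)
  G <- rowsum(U * q, cluster, reorder = FALSE)  # per-cluster score contributions
  M <- crossprod(G)
  vrob <- Binv %*% M %*% Binv

  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(vrob) <- list(colnames(X), colnames(X))

  structure(
    list(
      coefficients = beta,
      vcov_robust = vrob,
      vcov_naive = phi * Binv,
      alpha = if (corstr == "independence") 0 else alpha,
      phi = phi,
      corstr = corstr,
      converged = converged,
      iterations = it,
      n_obs = N,
      n_patients = n_clusters
    ),
    class = "em_gee"
  )
}

#' @export
coef.em_gee <- function(object, ...) object$coefficients

#' @export
vcov.em_gee <- function(object, robust = TRUE, ...) {
  if (robust) object$vcov_robust else object$vcov_naive
}

#' @export
print.em_gee <- function(x, ...) {
  cat("Binary GEE (logit link, ", x$corstr, " working correlation)\n", sep = "")
  cat("  patients: ", x$n_patients, ", patient-days: ", x$n_obs,
      ", alpha = ", signif(x$alpha, 3), ", phi = ", signif(x$phi, 3), "\n",
      sep = "")
  print(generics::tidy(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted binary GEE
#'
#' One row per coefficient with robust (sandwich) standard errors and Wald
#' z statistics.
#'
#' @param x an `em_gee` fit.
#' @param conf.int,conf.level add Wald confidence intervals.
#' @param ... unused.
#' @export
tidy.em_gee <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_robust))
  out <- tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / se)))
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Model-level summary of a fitted binary GEE
#'
#' @param x an `em_gee` fit.
#' @param ... unused.
#' @export
glance.em_gee <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_obs = x$n_obs,
    alpha = x$alpha,
    phi = x$phi,
    corstr = x$corstr,
    iterations = x$iterations,
    converged = x$converged
  )
}
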