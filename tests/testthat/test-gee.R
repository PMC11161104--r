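# The GEE fitter: cross-checks against independent routes, degenerate
# cases, and the invariances the analysis relies on.

# Dense-matrix reference fitter: same estimating equations and moment
# estimator, built with explicit per-cluster correlation matrices and
# solve(); the independent oracle for the banded AR-1 algebra.
dense_gee <- function(X, y, cluster, corstr = "ar1", maxit = 100, tol = 1e-8) {
  ids <- unique(cluster)
  p <- ncol(X)
  N <- length(y)
  beta <- suppressWarnings(glm.fit(X, y, family = binomial())$coefficients)
  alpha <- 0
  for (it in 1:maxit) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    e <- (y - mu) / sqrt(w)
    phi <- sum(e^2) / (N - p)
    if (corstr == "ar1") {
      num <- 0; npairs <- 0
      for (id in ids) {
        ei <- e[cluster == id]
        if (length(ei) > 1) {
          num <- num + sum(ei[-length(ei)] * ei[-1])
          npairs <- npairs + length(ei) - 1
        }
      }
      alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    B <- matrix(0, p, p); g <- numeric(p)
    for (id in ids) {
      rows <- which(cluster == id)
      m <- length(rows)
      R <- if (corstr == "ar1") alpha^abs(outer(1:m, 1:m, "-")) else diag(m)
      Rinv <- solve(R)
      Ui <- sqrt(w[rows]) * X[rows, , drop = FALSE]
      B <- B + t(Ui) %*% Rinv %*% Ui
      g <- g + t(Ui) %*% Rinv %*% e[rows]
    }
    step <- solve(B, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  # sandwich
  eta <- drop(X %*% beta); mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12); e <- (y - mu) / sqrt(w)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (id in ids) {
    rows <- which(cluster == id)
    m <- length(rows)
    R <- if (corstr == "ar1") alpha^abs(outer(1:m, 1:m, "-")) else diag(m)
    Rinv <- solve(R)
    Ui <- sqrt(w[rows]) * X[rows, , drop = FALSE]
    B <- B + t(Ui) %*% Rinv %*% Ui
    gi <- t(Ui) %*% Rinv %*% e[rows]
    M <- M + gi %*% t(gi)
  }
  Binv <- solve(B)
  list(coefficients = drop(beta), vcov_robust = Binv %*% M %*% Binv,
       alpha = alpha)
}

test_that("with an independence working correlation the GEE equals ML with a clustered sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  df <- sim_panel(n = 25, days = 20, m0 = 1, m2 = 0.05, sigma = 0.8)
  df$ti <- ifelse(df$arm == "intervention", pmax(0, df$day_index - 10), 0)
  X <- cbind(1, df$day_index / 19, ti = df$ti / 19)
  colnames(X) <- c("(Intercept)", "t", "ti")
  fit <- gee_binary(X, df$value, df$patient_id, corstr = "independence")
  ref <- glm(df$value ~ X[, 2] + X[, 3], family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  vc <- sandwich::vcovCL(ref, cluster = df$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov_robust), unname(vc), tolerance = 1e-5)
})

test_that("the banded AR-1 fitter matches a dense-matrix reference implementation", {
  set.seed(12)
  df <- sim_panel(n = 15, days = 25, m0 = 1.2, m2 = 0.08, sigma = 1)
  df$ti <- ifelse(df$arm == "intervention", pmax(0, df$day_index - 10), 0)
  X <- cbind(1, df$day_index / 24, (df$day_index / 24)^2, ti = df$ti / 24)
  fit <- gee_binary(X, df$value, df$patient_id, corstr = "ar1")
  ref <- dense_gee(X, df$value, as.character(df$patient_id), corstr = "ar1")
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$alpha, ref$alpha, tolerance = 1e-6)
  expect_equal(unname(fit$vcov_robust), unname(ref$vcov_robust),
               tolerance = 1e-5)
})

test_that("an all-correct outcome triggers the degenerate-case shortcut error", {
  df <- sim_panel(n = 5, days = 10)
  df$value <- 1L
  expect_error(
    fit_implementation_gee(df),
    "degenerate|identically",
    class = "emadhere_degenerate_error"
  )
})

test_that("a zero-coefficient fit predicts 0.5 for both representatives", {
  fit <- structure(
    list(coefficients = c(0, 0, 0, 0, 0),
         vcov_robust = diag(1e-4, 5),
         time_scale = 360, degree = 3, group_effect = TRUE,
         corstr = "ar1"),
    class = "em_gee"
  )
  pred <- predict_representative(fit, day = 180, randomization_day = 21)
  expect_equal(pred$p_intervention, 0.5)
  expect_equal(pred$p_control, 0.5)
  expect_equal(pred$delta, 0)
})

test_that("predictions are invariant to affine rescaling of the day axis", {
  set.seed(13)
  df <- sim_panel(n = 30, days = 60, m0 = 1.5, m2 = 0.05, sigma = 1)
  fit1 <- fit_implementation_gee(df, degree = 3)
  df2 <- dplyr::mutate(df, day_index = day_index / 100,
                       randomization_day = randomization_day / 100)
  fit2 <- fit_implementation_gee(df2, degree = 3)
  p1 <- predict_representative(fit1, day = 50, randomization_day = 10)
  p2 <- predict_representative(fit2, day = 0.5, randomization_day = 0.1)
  expect_equal(p1$p_intervention, p2$p_intervention, tolerance = 1e-8)
  expect_equal(p1$p_control, p2$p_control, tolerance = 1e-8)
  expect_equal(p1$se, p2$se, tolerance = 1e-6)
})

test_that("the exposure-effect estimate recovers the simulated arm gap on average", {
  set.seed(14)
  m0 <- 2.2; m2 <- 0.006; rand_day <- 10; day <- 80
  deltas <- replicate(60, {
    df <- sim_panel(n = 60, days = 90, m0 = m0, m2 = m2, sigma = 1,
                    rand_day = rand_day)
    fit <- fit_implementation_gee(df, degree = 1)
    predict_representative(fit, day = day, randomization_day = rand_day)$delta
  })
  true_delta <- plogis(m0 + m2 * (day - rand_day)) - plogis(m0)
  mc_se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - true_delta), 4 * mc_se + 0.002)
})

test_that("tidy and glance summarise a fit", {
  set.seed(15)
  df <- sim_panel(n = 20, days = 30, m0 = 1, m2 = 0.05)
  fit <- fit_implementation_gee(df, degree = 2)
  td <- generics::tidy(fit, conf.int = TRUE)
  expect_equal(nrow(td), 4)  # intercept + 2 time terms + exposure
  expect_true(all(c("term", "estimate", "std.error", "conf.low") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- generics::glance(fit)
  expect_equal(gl$n_patients, 20L)
  expect_true(gl$converged)
})

test_that("subgroup refits split at the median and detect a stratum-specific effect", {
  set.seed(16)
  dfm <- sim_panel(n = 40, days = 80, m0 = 2, m2 = 0.02, sigma = 0.8)
  dff <- sim_panel(n = 40, days = 80, m0 = 2, m2 = 0, sigma = 0.8)
  dff$patient_id <- sub("P", "Q", dff$patient_id)
  dfm$gender <- "male"; dff$gender <- "female"
  df <- dplyr::bind_rows(dfm, dff)
  res <- subgroup_analysis(df, "gender", day = 70, randomization_day = 10,
                           degree = 2)
  expect_setequal(res$stratum, c("male", "female"))
  expect_true(all(res$estimable))
  expect_gt(res$delta[res$stratum == "male"],
            res$delta[res$stratum == "female"])

  # continuous covariable: dichotomized at the median with <=/>' labels
  df$age <- rep(c(45, 70), length.out = nrow(df))
  res2 <- subgroup_analysis(df, "age", day = 70, randomization_day = 10,
                            degree = 2)
  expect_setequal(res2$stratum, c("<= 57.5", "> 57.5"))

  # a stratum with < 2 patients is inestimable
  df$rare <- ifelse(df$patient_id == "P001", "yes", "no")
  res3 <- subgroup_analysis(df, "rare", day = 70, randomization_day = 10,
                            degree = 2)
  expect_false(res3$estimable[res3$stratum == "yes"])
})
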