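test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # exposed cases a=21, exposed controls b=39, unexposed cases c=13,
  # unexposed controls d=181
  a <- 21; b <- 39; c <- 13; d <- 181
  outcome <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  exposure <- c(rep(1, a + b), rep(0, c + d))
  fit <- fit_logistic(outcome, exposure)
  or_hand <- (a * d) / (b * c)
  expect_equal(fit$terms$odds_ratio[fit$terms$term == "exposure"], or_hand,
               tolerance = 1e-6)
  expect_true(all(fit$terms$ci95_low <= fit$terms$odds_ratio &
                    fit$terms$odds_ratio <= fit$terms$ci95_high))
})

test_that("logistic fit flags degenerate and separated designs", {
  expect_error(fit_logistic(rep(0, 50), rnorm(50)), "both classes")
  # quasi-complete separation
  y <- c(rep(0, 25), rep(1, 25))
  x <- c(rnorm(25, -5), rnorm(25, 5))
  expect_error(suppressWarnings(fit_logistic(y, x)), "separation")
})

test_that("logistic null rejection rate is near nominal", {
  rej <- vapply(1:300, function(s) {
    withr::with_seed(s, {
      y <- rbinom(150, 1, 0.3)
      x <- rnorm(150)
      fit <- fit_logistic(y, x)
      fit$terms$p[fit$terms$term == "exposure"] < 0.05
    })
  }, logical(1))
  expect_gt(mean(rej), 0.05 - 2.5 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 300))
})

test_that("model covariate sets match the a priori definitions", {
  co <- generate_cohort(small_config(seed = 17))
  m1 <- model_covariates(co$metadata, "model1")
  expect_setequal(names(m1), c("framingham_sd", "hiv_duration_5y", "msm",
                               "cd4_nadir_lt200", "statins", "abacavir",
                               "antibiotics", "il6_sd"))
  m2 <- model_covariates(co$metadata, "model2")
  expect_setequal(names(m2), c(names(m1), "age_10y", "sex_male"))
  expect_equal(ncol(model_covariates(co$metadata, "unadjusted")), 0L)
  expect_equal(m1$hiv_duration_5y, co$metadata$hiv_duration_y / 5)
  expect_equal(sd(m1$framingham_sd), 1, tolerance = 1e-12)
})

test_that("AUC equals Mann-Whitney concordance and handles edge cases", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # oracle equivalence on random instances (with ties)
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(20:60, 1)
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) y[1:2] <- c(0, 1)
      score <- sample(1:10, n, replace = TRUE)
      u <- unname(suppressWarnings(
        stats::wilcox.test(score[y == 1], score[y == 0])$statistic))
      expect_equal(roc_auc(score, y)$auc,
                   u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-10)
    })
  }
  # invariance to monotone transformation
  withr::with_seed(3, {
    y <- rbinom(50, 1, 0.5); sc <- rnorm(50)
    expect_equal(roc_auc(sc, y)$auc, roc_auc(exp(sc), y)$auc,
                 tolerance = 1e-12)
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    y <- rbinom(80, 1, 0.4)
    sc <- rnorm(80) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(sc, y)$auc, ref, tolerance = 1e-10)
  })
})

test_that("mediation satisfies the linear identity on every bootstrap draw", {
  withr::with_seed(5, {
    n <- 100
    x <- rnorm(n)
    m <- 0.6 * x + rnorm(n)
    y <- as.integer(plogis(0.5 * m + 0.3 * x) > runif(n))
    cov <- data.frame(z = rnorm(n))
    res <- mediate_bootstrap(x, m, y, cov, n_boot = 100, seed = 3)
    expect_true(all(abs(res$boot[, "total"] - res$boot[, "direct"] -
                          res$boot[, "indirect"]) < 1e-8))
    expect_equal(nrow(res$boot), 100L)
  })
  expect_error(mediate_bootstrap(rnorm(60), rep(1, 60),
                                 rbinom(60, 1, 0.5)), "constant")
})

test_that("full and null mediation chains are recovered", {
  # full mediation: x -> m -> y with no direct path; the proportion
  # mediated is noisy per draw, so check its median over replicates
  props <- vapply(1:20, function(s) {
    withr::with_seed(800 + s, {
      n <- 400
      x <- rnorm(n)
      m <- x + rnorm(n)
      y <- as.integer(plogis(2 * m - 1) > runif(n))
      mediate_bootstrap(x, m, y, n_boot = 50, seed = s)$proportion_mediated
    })
  }, numeric(1))
  expect_gt(median(props), 0.8)
  expect_lt(median(props), 1.2)
  withr::with_seed(8, {
    n <- 400
    x <- rnorm(n)
    m <- x + rnorm(n)
    y <- as.integer(plogis(2 * m - 1) > runif(n))
    res <- mediate_bootstrap(x, m, y, n_boot = 200, seed = 2)
    ind <- res$estimates[res$estimates$effect == "indirect", ]
    expect_lt(ind$p, 0.05)
    expect_gt(ind$ci_low, 0)
  })
  # null chain: m unrelated to x and y
  withr::with_seed(9, {
    n <- 200
    x <- rnorm(n); m <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    res0 <- mediate_bootstrap(x, m, y, n_boot = 200, seed = 4)
    ind0 <- res0$estimates[res0$estimates$effect == "indirect", ]
    expect_true(ind0$ci_low <= 0 && ind0$ci_high >= 0)
  })
})
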