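test_that("PQL with zero random variance equals the IRLS GLM oracle", {
  d <- simulate_use_availability(c(-2.675, -0.133, 2.402, -5.593),
                                 n_birds = 20, dives_per_bird = 30,
                                 sigma_bird = 0, seed = 5)
  f <- fit_binomial_glmm(d, response ~ Gdens * sex, random = NULL)
  g <- glm(response ~ Gdens * sex, family = binomial("cloglog"), data = d)
  expect_lt(max(abs(f$terms$estimate - coef(g)[f$terms$term])), 1e-4)
  # SEs are evaluated at the (slightly different) final weights
  expect_lt(max(abs(f$terms$std.error -
                      summary(g)$coefficients[f$terms$term, 2])), 1e-3)
})

test_that("intercept-only cloglog fit recovers the closed form on a 5:1 design", {
  set.seed(6)
  n <- 30000
  d <- tibble::tibble(response = rep(c(1L, rep(0L, 5)), n / 6),
                      bird_id = factor(rep(1:10, each = n / 10)))
  f <- fit_binomial_glmm(d, response ~ 1, random = NULL)
  expect_equal(f$terms$estimate, log(-log(1 - 1 / 6)), tolerance = 1e-6)
})

test_that("the PQL loop agrees with MASS::glmmPQL on a mixed-model fit", {
  d <- simulate_use_availability(c(-2.675, -0.133, 2.402, -5.593),
                                 n_birds = 40, dives_per_bird = 30,
                                 sigma_bird = 0.5, seed = 6)
  f <- fit_binomial_glmm(d, response ~ Gdens * sex)
  ref <- suppressMessages(MASS::glmmPQL(
    response ~ Gdens * sex, random = ~ 1 | bird_id,
    family = binomial("cloglog"), data = as.data.frame(d), verbose = FALSE))
  expect_lt(max(abs(f$terms$estimate - nlme::fixef(ref)[f$terms$term])), 0.02)
  expect_equal(f$sigma_bird,
               as.numeric(nlme::VarCorr(ref)["(Intercept)", "StdDev"]),
               tolerance = 0.05)
  expect_s3_class(tidy(f), "tbl_df")
  expect_true(all(c("estimate", "conf.low", "p.value") %in% names(tidy(f))))
})

test_that("LMM with no random term equals ordinary least squares", {
  set.seed(7)
  n <- 600
  d <- tibble::tibble(
    bird_id = factor(rep(1:10, each = n / 10)),
    sex = factor(sample(c("male", "female"), n, TRUE), levels = c("male", "female")),
    Fdist = runif(n, 0, 40), DecTime = runif(n))
  d$DecTime2 <- (d$DecTime - 0.5)^2
  d$duration <- 1.5 + 0.7 * (d$sex == "female") + 0.027 * d$Fdist +
    3.7 * d$DecTime - 3 * d$DecTime2 + rnorm(n, 0, 2)
  f <- fit_lmm(d, duration ~ Fdist * sex + DecTime + DecTime2, random = NULL,
               method = "ML")
  o <- lm(duration ~ Fdist * sex + DecTime + DecTime2, data = d)
  expect_lt(max(abs(f$terms$estimate - coef(o)[f$terms$term])), 1e-4)
})

test_that("LMM slope p-values are calibrated on pure noise", {
  set.seed(8)
  hits <- 0
  for (r in 1:200) {
    d <- tibble::tibble(bird_id = factor(rep(1:8, each = 25)),
                        m = runif(200), y = rnorm(200))
    f <- suppressWarnings(fit_lmm(d, y ~ m))
    hits <- hits + (f$terms$p.value[f$terms$term == "m"] < 0.05)
  }
  expect_gt(hits / 200, 0.01)
  expect_lt(hits / 200, 0.11)
})

test_that("a midday peak is recovered as negative curvature", {
  set.seed(9)
  n <- 1000
  d <- tibble::tibble(bird_id = factor(rep(1:10, each = n / 10)),
                      DecTime = runif(n))
  d$DecTime2 <- (d$DecTime - 0.5)^2
  d$y <- 5 - 8 * d$DecTime2 + rnorm(n, 0, 1) + rep(rnorm(10, 0, 0.5), each = n / 10)
  f <- fit_lmm(d, y ~ DecTime + DecTime2)
  row <- f$terms[f$terms$term == "DecTime2", ]
  expect_lt(row$estimate, 0)
  expect_gt(-8, row$conf.low)
  expect_lt(-8, row$conf.high)
})

test_that("CI-screening reduction respects hierarchy and the intercept", {
  # all terms significant: untouched
  d <- simulate_use_availability(c(-2.0, -1.0, 3.0, -6.0), n_birds = 40,
                                 dives_per_bird = 40, sigma_bird = 0.3, seed = 10)
  f <- suppressWarnings(fit_binomial_glmm(d, response ~ Gdens * sex))
  r <- suppressWarnings(reduce_glmm(f))
  expect_equal(nrow(attr(r, "drop_log")), 0)
  expect_identical(r$fixed, f$fixed)

  # pure-noise interaction on a true main effect: interaction goes first,
  # main effect survives; the intercept is never a candidate
  ok <- 0
  for (s in 1:25) {
    d2 <- simulate_use_availability(c(-2.0, 0, 2.5, 0), n_birds = 40,
                                    dives_per_bird = 30, sigma_bird = 0.3,
                                    seed = 100 + s)
    f2 <- suppressWarnings(fit_binomial_glmm(d2, response ~ Gdens * sex))
    r2 <- suppressWarnings(reduce_glmm(f2))
    kept <- attr(stats::terms(r2$fixed), "term.labels")
    dropped <- attr(r2, "drop_log")$dropped
    if ("Gdens" %in% kept && !("Gdens:sex" %in% kept)) ok <- ok + 1
    expect_false("(Intercept)" %in% dropped)
    if ("Gdens:sex" %in% dropped && "sex" %in% dropped) {
      expect_lt(which(dropped == "Gdens:sex"), which(dropped == "sex"))
    }
  }
  expect_gte(ok / 25, 0.9)
})

test_that("LMM selection keeps the true predictor and drops noise", {
  set.seed(11)
  ok <- 0
  for (s in 1:20) {
    n <- 2000
    nb <- 100 # enough birds that the between-bird (sex) LRT is calibrated
    d <- tibble::tibble(
      bird_id = factor(rep(1:nb, each = n / nb)),
      sex = factor(rep(rep(c("male", "female"), nb / 2), each = n / nb),
                   levels = c("male", "female")),
      Fdist = runif(n, 0, 40))
    d$y <- 2 + 0.1 * d$Fdist + rep(rnorm(nb, 0, 0.3), each = n / nb) + rnorm(n)
    sel <- suppressWarnings(select_lmm(d, y ~ Fdist * sex))
    kept <- attr(stats::terms(sel$fixed), "term.labels")
    if (identical(kept, "Fdist")) ok <- ok + 1
    expect_identical(sel$method, "REML")
  }
  # the property holds at ~90% over many seeds; allow Monte-Carlo slack at
  # this reduced replicate count
  expect_gte(ok / 20, 0.8)
})

test_that("AIC differences match the likelihood-ratio identity", {
  set.seed(12)
  d <- tibble::tibble(bird_id = factor(rep(1:10, each = 50)),
                      m = runif(500), y = rnorm(500))
  f1 <- fit_lmm(d, y ~ m, method = "ML")
  f0 <- fit_lmm(d, y ~ 1, method = "ML")
  daic <- AIC(f1$engine_fit) - AIC(f0$engine_fit)
  ddev <- -2 * (as.numeric(logLik(f1$engine_fit)) - as.numeric(logLik(f0$engine_fit)))
  expect_equal(daic, ddev + 2, tolerance = 1e-8) # one extra parameter
  # empty candidate set: intercept-only model comes back
  sel <- select_lmm(d, y ~ 1)
  expect_equal(length(attr(stats::terms(sel$fixed), "term.labels")), 0)
})

test_that("AUC is the pairwise concordance and is rank-invariant", {
  set.seed(13)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  y <- rbinom(2000, 1, 0.3)
  s <- runif(2000)
  expect_equal(auc_rank(s, y), 0.5, tolerance = 0.05)
  # brute-force O(n^2) oracle on a small table
  y20 <- rbinom(20, 1, 0.4)
  if (sum(y20) == 0) y20[1] <- 1
  s20 <- rnorm(20)
  pos <- s20[y20 == 1]; neg <- s20[y20 == 0]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_rank(s20, y20), brute)
  # strictly monotone transforms leave AUC unchanged
  expect_equal(auc_rank(exp(3 * s20 - 1), y20), auc_rank(s20, y20))
})

test_that("pseudo-R2 is bounded, zero for intercept-only, pi^2/6 latent", {
  d <- simulate_use_availability(c(-2.5, 0, 2, -4), n_birds = 20,
                                 dives_per_bird = 20, sigma_bird = 0.4, seed = 14)
  f0 <- suppressWarnings(fit_binomial_glmm(d, response ~ 1))
  ev0 <- evaluate_fit(f0)
  expect_equal(ev0$pseudo_r2, 0)
  f1 <- suppressWarnings(fit_binomial_glmm(d, response ~ Gdens * sex))
  ev1 <- evaluate_fit(f1)
  expect_gt(ev1$pseudo_r2, 0)
  expect_lt(ev1$pseudo_r2, 100)
  # hand computation of the marginal formula
  eta_fix <- drop(f1$X %*% f1$terms$estimate)
  by_hand <- 100 * var(eta_fix) /
    (var(eta_fix) + f1$sigma_bird^2 + pi^2 / 6)
  expect_equal(ev1$pseudo_r2, by_hand)
  expect_true(ev1$auc >= 0.5 && ev1$auc <= 1)
})

test_that("response curves are flat for null fits and bands contain them", {
  d <- simulate_use_availability(c(-2.0, 0, 0, 0), n_birds = 12,
                                 dives_per_bird = 25, sigma_bird = 0.3, seed = 15)
  f <- suppressWarnings(fit_binomial_glmm(d, response ~ Gdens))
  cv <- suppressWarnings(predict_response_curve(f, "Gdens", n_boot = 30, seed = 2))
  # slope is consistent with zero, so the curve is nearly flat
  expect_lt(diff(range(cv$fit)), 0.05)
  expect_true(all(cv$lwr <= cv$fit + 1e-12 & cv$fit <= cv$upr + 1e-12))
  expect_gt(attr(cv, "n_boot_ok"), 20)
})

test_that("vessel sensitivity removes flagged clusters and compares fits", {
  d <- simulate_use_availability(c(-2.2, -0.2, 2.0, -3.0), n_birds = 30,
                                 dives_per_bird = 30, sigma_bird = 0.3, seed = 16)
  d$vessel <- FALSE
  f <- suppressWarnings(fit_binomial_glmm(d, response ~ Gdens * sex))
  f$data <- d
  vs0 <- suppressWarnings(vessel_sensitivity(f))
  # nothing flagged: identical estimates
  expect_equal(vs0$ua_refit$terms$estimate, f$terms$estimate, tolerance = 1e-10)

  # flag dives independently of the metric: exactly whole clusters (1 dive +
  # 5 absences) drop, and metric terms agree within CIs
  set.seed(17)
  cluster <- rep(seq_len(nrow(d) / 6), each = 6)
  flagged <- cluster %in% sample(unique(cluster), 150)
  d2 <- d
  d2$vessel <- flagged
  f2 <- suppressWarnings(fit_binomial_glmm(d2, response ~ Gdens * sex))
  f2$data <- d2
  vs <- suppressWarnings(vessel_sensitivity(f2))
  expect_equal(nrow(f2$data) - vs$ua_refit$n_obs, 150 * 6)
  cmp <- vs$comparison
  g_row <- cmp[cmp$term == "Gdens", ]
  ci <- f2$terms[f2$terms$term == "Gdens", ]
  expect_gt(g_row$reanalysis, ci$conf.low)
  expect_lt(g_row$reanalysis, ci$conf.high)
})
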