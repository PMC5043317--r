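cloglog_inv <- function(eta) -expm1(-exp(pmin(eta, 30)))

# assemble the common fit container
new_fd_fit <- function(type, terms_tb, data, fixed, random, correlation,
                       link = NULL, sigma_bird = NA, sigma_resid = NA,
                       eta = NULL, converged = TRUE, method = NULL,
                       engine_fit = NULL) {
  grp <- if (is.null(random)) NULL else all.vars(random)[length(all.vars(random))]
  structure(
    list(type = type, terms = terms_tb, data = data, fixed = fixed,
         random = random, correlation = correlation, link = link,
         sigma_bird = sigma_bird, sigma_resid = sigma_resid, eta = eta,
         converged = converged, method = method, engine_fit = engine_fit,
         n_obs = nrow(data),
         n_birds = if (is.null(grp)) NA_integer_ else length(unique(data[[grp]])),
         group_var = grp),
    class = "fd_fit"
  )
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit %s> %s, n = %d obs / %s birds%s\n", x$type,
              deparse(x$fixed), x$n_obs, x$n_birds,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Tidy a fitted dive model
#'
#' @param x An `fd_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (estimate +/- 1.96 se, the reporting convention of the
#'   analysis), `p.value`.
#' @method tidy fd_fit
#' @export
tidy.fd_fit <- function(x, ...) x$terms

#' One-row summary of a fitted dive model
#'
#' @param x An `fd_fit`.
#' @param ... Unused.
#' @method glance fd_fit
#' @export
glance.fd_fit <- function(x, ...) {
  ev <- evaluate_fit(x)
  tibble::tibble(
    n_obs = x$n_obs, n_birds = x$n_birds, sigma_bird = x$sigma_bird,
    sigma_resid = x$sigma_resid, auc = ev$auc, pseudo_r2 = ev$pseudo_r2,
    converged = x$converged
  )
}

#' Fit a binomial mixed model by penalized quasi-likelihood
#'
#' Iterative working-response estimation for a binomial GLMM with a
#' complementary log-log (or logit) link: at each iteration the current
#' linear predictor defines a weighted working response, which is fitted as
#' a linear mixed model with a bird-level random intercept (and optional
#' residual correlation structure, nested in bird) via [nlme::lme()];
#' iteration stops when no fixed-effect coefficient changes by more than
#' `tol`, or after `max_iter` iterations with the fit flagged unconverged. With `random = NULL` the random variance is identically
#' zero and the loop reduces to iteratively reweighted least squares, i.e.
#' an ordinary GLM.
#'
#' @param data Data frame with the response and covariates.
#' @param fixed Fixed-effect formula, e.g. `response ~ Gdens * sex`.
#' @param random Random-effects formula `~ 1 | bird_id`, or NULL for none.
#' @param correlation Optional [nlme::corStruct] (e.g.
#'   `nlme::corExp(form = ~ x + y | bird_id)` for spatial,
#'   `nlme::corCAR1(form = ~ t | bird_id)` for temporal), nested in bird.
#' @param link `"cloglog"` (default) or `"logit"`.
#' @param tol Convergence tolerance on the fixed effects (default 1e-6).
#' @param max_iter Maximum PQL iterations (default 50).
#' @return An `fd_fit` with Wald (z) standard errors, CIs and p-values.
#' @export
fit_binomial_glmm <- function(data, fixed, random = ~ 1 | bird_id,
                              correlation = NULL, link = "cloglog",
                              tol = 1e-6, max_iter = 50) {
  fam <- binomial(link = link)
  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  stopifnot(all(y %in% c(0, 1)))
  X <- model.matrix(fixed, data)
  if (!is.null(random)) {
    grp <- all.vars(random)[length(all.vars(random))]
    if (length(unique(data[[grp]])) < 2) {
      stop("fit_binomial_glmm: need >= 2 grouping levels")
    }
  }

  mu <- (y + 0.5) / 2
  eta <- fam$linkfun(mu)
  work <- as.data.frame(data)
  converged <- FALSE
  beta <- NULL
  beta_old <- NULL
  se <- NULL
  sigma_bird <- 0
  engine <- NULL
  for (it in seq_len(max_iter)) {
    mu <- fam$linkinv(eta)
    mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    me <- fam$mu.eta(eta)
    me <- pmax(me, 1e-8)
    z <- eta + (y - mu) / me
    w <- me^2 / fam$variance(mu)
    if (is.null(random)) {
      wls <- stats::lm.wfit(X, z, w)
      beta <- wls$coefficients
      eta <- drop(X %*% beta)
      xtwx <- crossprod(X * sqrt(w))
      se <- sqrt(diag(solve(xtwx))) # binomial dispersion fixed at 1
    } else {
      work$.z <- z
      work$.invw <- 1 / w
      fixed_work <- update(fixed, .z ~ .)
      engine <- tryCatch(
        nlme::lme(fixed = fixed_work, random = random, data = work,
                  weights = nlme::varFixed(~.invw), correlation = correlation,
                  control = nlme::lmeControl(returnObject = TRUE, opt = "optim")),
        error = function(e) tryCatch(
          nlme::lme(fixed = fixed_work, random = random, data = work,
                    weights = nlme::varFixed(~.invw), correlation = correlation,
                    control = nlme::lmeControl(returnObject = TRUE)),
          error = function(e2) NULL)
      )
      if (is.null(engine)) {
        # variance component at the boundary: degenerate mixed step; fall
        # back to the weighted fixed-effects solve for this iteration
        warning("fit_binomial_glmm: random-effect variance at boundary; ",
                "mixed step degenerate")
        wls <- stats::lm.wfit(X, z, w)
        beta <- wls$coefficients
        eta <- drop(X %*% beta)
        xtwx <- crossprod(X * sqrt(w))
        se <- sqrt(diag(solve(xtwx)))
        sigma_bird <- 0
      } else {
        beta <- nlme::fixef(engine)
        eta <- as.numeric(stats::fitted(engine))
        tt <- summary(engine)$tTable
        se <- tt[, "Std.Error"]
        vc <- nlme::VarCorr(engine)
        sigma_bird <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
      }
    }
    if (!is.null(beta_old) && max(abs(beta - beta_old)) < tol) {
      converged <- TRUE
      break
    }
    beta_old <- beta
  }
  if (!converged) {
    warning("fit_binomial_glmm: PQL did not converge in ", max_iter, " iterations")
  }
  if (max(abs(eta)) > 20) {
    warning("fit_binomial_glmm: extreme linear predictor; possible separation")
  }

  zstat <- beta / se
  terms_tb <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    conf.low = unname(beta - 1.96 * se), conf.high = unname(beta + 1.96 * se),
    p.value = unname(2 * pnorm(-abs(zstat)))
  )
  fit <- new_fd_fit("glmm_pql", terms_tb, data, fixed, random, correlation,
                    link = link, sigma_bird = sigma_bird,
                    sigma_resid = pi^2 / 6, eta = eta, converged = converged,
                    engine_fit = engine)
  fit$X <- X
  fit$y <- y
  fit
}

#' Fit a linear mixed model for dive depth or duration
#'
#' Wrapper around [nlme::lme()] with a bird-level random intercept and an
#' optional continuous-time correlation structure nested in bird. REML for
#' final estimates, ML during model selection.
#'
#' @param data Data frame.
#' @param fixed Fixed-effect formula, e.g.
#'   `duration ~ Fdist * sex + DecTime + DecTime2`.
#' @param random Random-effects formula (default `~ 1 | bird_id`).
#' @param correlation Optional [nlme::corStruct].
#' @param method `"REML"` (default) or `"ML"`.
#' @return An `fd_fit` with Wald t p-values at lme's containment degrees of
#'   freedom.
#' @export
fit_lmm <- function(data, fixed, random = ~ 1 | bird_id, correlation = NULL,
                    method = "REML") {
  if (is.null(random)) {
    # random variance identically zero: generalized/ordinary least squares
    fit <- nlme::gls(model = fixed, data = as.data.frame(data),
                     correlation = correlation, method = method)
    tt <- summary(fit)$tTable
    sigma_bird <- 0
  } else {
    fit <- nlme::lme(fixed = fixed, random = random, data = as.data.frame(data),
                     correlation = correlation, method = method,
                     control = nlme::lmeControl(returnObject = TRUE))
    tt <- summary(fit)$tTable
    vc <- nlme::VarCorr(fit)
    sigma_bird <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    if (!is.na(sigma_bird) && sigma_bird < 1e-6) {
      warning("fit_lmm: random-intercept variance at boundary (~0)")
    }
  }
  sigma_resid <- fit$sigma^2
  terms_tb <- tibble::tibble(
    term = rownames(tt), estimate = tt[, "Value"], std.error = tt[, "Std.Error"],
    conf.low = tt[, "Value"] - 1.96 * tt[, "Std.Error"],
    conf.high = tt[, "Value"] + 1.96 * tt[, "Std.Error"],
    p.value = tt[, "p-value"]
  )
  out <- new_fd_fit("lmm", terms_tb, data, fixed, random, correlation,
                    sigma_bird = sigma_bird, sigma_resid = sigma_resid,
                    eta = as.numeric(stats::fitted(fit)), method = method,
                    engine_fit = fit)
  out$X <- model.matrix(fixed, data)
  out$y <- stats::model.response(stats::model.frame(fixed, data))
  out
}

# refit an fd_fit with a (possibly) new fixed formula / data / method
refit_fd <- function(fit, fixed = fit$fixed, data = fit$data,
                     method = fit$method) {
  if (fit$type == "glmm_pql") {
    fit_binomial_glmm(data, fixed, fit$random, fit$correlation, fit$link)
  } else {
    fit_lmm(data, fixed, fit$random, fit$correlation,
            method = if (is.null(method)) "REML" else method)
  }
}

# term labels droppable under marginality (no interaction containing them
# remains)
droppable_terms <- function(fixed) {
  tl <- attr(terms(fixed), "term.labels")
  ok <- vapply(tl, function(t) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) return(TRUE)
    !any(vapply(setdiff(tl, t), function(o) {
      op <- strsplit(o, ":", fixed = TRUE)[[1]]
      length(op) > 1 && t %in% op
    }, logical(1)))
  }, logical(1))
  tl[ok]
}

# map coefficient rows to term labels via the design matrix "assign"
coef_terms_map <- function(fit) {
  asn <- attr(fit$X, "assign")
  tl <- attr(terms(fit$fixed), "term.labels")
  lab <- c("(Intercept)", tl)[asn + 1]
  stats::setNames(lab, colnames(fit$X))
}

#' Reduce a PQL binomial model by confidence-interval screening
#'
#' Because PQL precludes likelihood-based selection, the fixed component is
#' reduced by iteratively removing the least-significant droppable term
#' (interactions before the main effects they contain; the intercept never
#' dropped) whose 95% confidence interval passes through zero, refitting
#' after each removal, until every remaining term has a CI excluding zero
#' or is protected by marginality.
#'
#' @param fit An `fd_fit` from [fit_binomial_glmm()].
#' @return The final `fd_fit`, with a `drop_log` attribute recording each
#'   removal (term, estimate, p at removal).
#' @export
reduce_glmm <- function(fit) {
  log <- list()
  repeat {
    tl <- attr(terms(fit$fixed), "term.labels")
    if (length(tl) == 0) break
    cand <- droppable_terms(fit$fixed)
    map <- coef_terms_map(fit)
    # a term's CI "spans zero" if all its coefficients do
    spans <- vapply(cand, function(t) {
      rows <- fit$terms[map[fit$terms$term] == t & !is.na(map[fit$terms$term]), ]
      nrow(rows) > 0 && all(rows$conf.low < 0 & rows$conf.high > 0)
    }, logical(1))
    if (!any(spans)) break
    pmaxv <- vapply(cand[spans], function(t) {
      rows <- fit$terms[map[fit$terms$term] == t, ]
      max(rows$p.value)
    }, numeric(1))
    worst <- names(pmaxv)[which.max(pmaxv)]
    log[[length(log) + 1]] <- tibble::tibble(
      dropped = worst, p_at_drop = max(pmaxv)
    )
    new_terms <- setdiff(tl, worst)
    new_fixed <- reformulate(if (length(new_terms) == 0) "1" else new_terms,
                             response = all.vars(fit$fixed)[1])
    fit <- refit_fd(fit, fixed = new_fixed)
  }
  attr(fit, "drop_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(dropped = character(), p_at_drop = numeric())
  fit
}

#' Select a linear mixed model by AIC and likelihood-ratio tests
#'
#' Backwards-then-forwards selection over the fixed terms under ML
#' estimation: at each backward step the droppable term whose removal most
#' improves AIC is removed, provided the likelihood-ratio test does not
#' contradict the drop (LRT p > `lrt_alpha`); forward steps re-add a
#' dropped term only if it improves AIC. The most parsimonious model is
#' refitted with REML.
#'
#' @param data Data frame.
#' @param fixed Full fixed-effect formula.
#' @param random,correlation As in [fit_lmm()].
#' @param lrt_alpha LRT significance level protecting against drops
#'   (default 0.05).
#' @return The final REML `fd_fit`, with a `selection_trace` attribute.
#' @export
select_lmm <- function(data, fixed, random = ~ 1 | bird_id,
                       correlation = NULL, lrt_alpha = 0.05) {
  trace <- list()
  cur <- fit_lmm(data, fixed, random, correlation, method = "ML")
  dropped <- character()
  repeat {
    improved <- FALSE
    # backward: drop the least-supported term, LRT-confirmed (p > alpha);
    # AIC of every candidate is recorded in the trace
    cand <- droppable_terms(cur$fixed)
    if (length(cand) > 0) {
      fits <- purrr::map(cand, function(t) {
        tl <- setdiff(attr(terms(cur$fixed), "term.labels"), t)
        f <- reformulate(if (length(tl) == 0) "1" else tl,
                         response = all.vars(cur$fixed)[1])
        fit_lmm(data, f, random, correlation, method = "ML")
      })
      aics <- vapply(fits, function(f) AIC(f$engine_fit), numeric(1))
      lrt_p <- vapply(fits, function(f) {
        pchisq(2 * (as.numeric(logLik(cur$engine_fit)) -
                      as.numeric(logLik(f$engine_fit))),
               df = attr(logLik(cur$engine_fit), "df") -
                 attr(logLik(f$engine_fit), "df"),
               lower.tail = FALSE)
      }, numeric(1))
      best <- which.max(lrt_p)
      if (lrt_p[best] > lrt_alpha) {
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = "drop", term = cand[best], aic = aics[best],
          lrt_p = lrt_p[best])
        dropped <- union(dropped, cand[best])
        cur <- fits[[best]]
        improved <- TRUE
      }
    }
    # forward: reconsider dropped terms
    if (!improved && length(dropped) > 0) {
      cur_aic <- AIC(cur$engine_fit)
      for (t in dropped) {
        tl <- union(attr(terms(cur$fixed), "term.labels"), t)
        # marginality: an interaction needs its mains present
        parts <- strsplit(t, ":", fixed = TRUE)[[1]]
        if (length(parts) > 1 && !all(parts %in% tl)) next
        f <- reformulate(tl, response = all.vars(cur$fixed)[1])
        cand_fit <- fit_lmm(data, f, random, correlation, method = "ML")
        add_p <- pchisq(2 * (as.numeric(logLik(cand_fit$engine_fit)) -
                               as.numeric(logLik(cur$engine_fit))),
                        df = attr(logLik(cand_fit$engine_fit), "df") -
                          attr(logLik(cur$engine_fit), "df"),
                        lower.tail = FALSE)
        # re-add only with both AIC support and LRT significance, so a
        # term dropped by the LRT cannot cycle back in
        if (AIC(cand_fit$engine_fit) < cur_aic - 1e-8 && add_p < lrt_alpha) {
          trace[[length(trace) + 1]] <- tibble::tibble(
            step = "add", term = t, aic = AIC(cand_fit$engine_fit),
            lrt_p = add_p)
          dropped <- setdiff(dropped, t)
          cur <- cand_fit
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  final <- fit_lmm(data, cur$fixed, random, correlation, method = "REML")
  attr(final, "selection_trace") <- if (length(trace)) dplyr::bind_rows(trace)
    else tibble::tibble(step = character(), term = character(),
                        aic = numeric(), lrt_p = numeric())
  final
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney rank
#' statistic of scores for positives versus negatives; invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 outcomes.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model: AUC and marginal pseudo-R2
#'
#' AUC (binomial fits only) is the rank statistic of the fitted
#' probabilities against the observed response. The marginal pseudo-R2 is
#' the variance of the fixed-effect linear predictor over the total latent
#' variance (fixed + random-intercept + residual), with the residual
#' variance of the complementary log-log link taken as pi^2/6; reported in
#' percent.
#'
#' @param fit An `fd_fit`.
#' @param data Optional data frame to evaluate on (defaults to the fitting
#'   data).
#' @return Tibble with `auc` and `pseudo_r2`.
#' @export
evaluate_fit <- function(fit, data = NULL) {
  X <- if (is.null(data)) fit$X else model.matrix(fit$fixed, data)
  beta <- fit$terms$estimate
  eta_fixed <- drop(X %*% beta)
  var_fixed <- var(eta_fixed)
  var_rand <- if (is.na(fit$sigma_bird)) 0 else fit$sigma_bird^2
  resid <- fit$sigma_resid
  pr2 <- 100 * var_fixed / (var_fixed + var_rand + resid)
  auc <- NA_real_
  if (fit$type == "glmm_pql") {
    y <- if (is.null(data)) fit$y else
      stats::model.response(stats::model.frame(fit$fixed, data))
    eta <- if (is.null(data)) fit$eta else eta_fixed
    auc <- auc_rank(cloglog_inv(eta), y)
  }
  tibble::tibble(auc = auc, pseudo_r2 = pr2)
}

#' Expected response over a metric gradient, with bootstrap CI
#'
#' Expected response for an "average" bird (random effect zero) over a grid
#' of metric values, with a 95% band from a nonparametric bootstrap that
#' resamples birds with replacement and refits the model.
#'
#' @param fit An `fd_fit`.
#' @param metric Name of the metric column to vary.
#' @param metric_grid Numeric vector of metric values (default: 50 points
#'   over the observed range).
#' @param sex Sex level held fixed (default the base level, `"male"`).
#' @param dectime Decimal time held fixed when the model includes it
#'   (default 0.5, midday).
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return Tibble `metric`, `fit`, `lwr`, `upr` (response scale); attribute
#'   `n_boot_ok` counts replicates that refitted successfully.
#' @export
predict_response_curve <- function(fit, metric, metric_grid = NULL,
                                   sex = "male", dectime = 0.5, n_boot = 500,
                                   seed = 1) {
  data <- fit$data
  if (is.null(metric_grid)) {
    metric_grid <- seq(min(data[[metric]], na.rm = TRUE),
                       max(data[[metric]], na.rm = TRUE), length.out = 50)
  }
  newdata <- data[rep(1, length(metric_grid)), , drop = FALSE]
  newdata[[metric]] <- metric_grid
  if ("sex" %in% names(data)) {
    newdata$sex <- factor(sex, levels = levels(data$sex))
  }
  if ("DecTime" %in% names(data)) {
    newdata$DecTime <- dectime
    if ("DecTime2" %in% names(data)) newdata$DecTime2 <- (dectime - 0.5)^2
  }
  resp_fun <- if (fit$type == "glmm_pql") cloglog_inv else identity
  point <- resp_fun(drop(model.matrix(fit$fixed, newdata) %*% fit$terms$estimate))

  grp <- fit$group_var
  birds <- unique(data[[grp]])
  boot <- matrix(NA_real_, n_boot, length(metric_grid))
  with_seed(fd_substream(seed, 707), {
    for (b in seq_len(n_boot)) {
      pick <- sample(birds, length(birds), replace = TRUE)
      bd <- purrr::imap_dfr(pick, function(bird, i) {
        d <- data[data[[grp]] == bird, , drop = FALSE]
        d[[grp]] <- paste0("copy", i)
        d
      })
      bd[[grp]] <- factor(bd[[grp]])
      bf <- tryCatch(suppressWarnings(refit_fd(fit, data = bd)),
                     error = function(e) NULL)
      if (is.null(bf)) next
      boot[b, ] <- resp_fun(drop(model.matrix(fit$fixed, newdata) %*%
                                   bf$terms$estimate))
    }
  })
  ok <- stats::complete.cases(boot)
  band <- apply(boot[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
  out <- tibble::tibble(metric = metric_grid, fit = point,
                        lwr = band[1, ], upr = band[2, ])
  attr(out, "n_boot_ok") <- sum(ok)
  out
}

#' Plot a response curve with its bootstrap band
#'
#' @param curve Output of [predict_response_curve()].
#' @param metric_name Axis label.
#' @return A ggplot.
#' @export
plot_response_curve <- function(curve, metric_name = "metric") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$metric, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = metric_name, y = "expected response")
}

#' Vessel-association sensitivity re-analysis
#'
#' Re-runs (i) the use-availability model on the table with vessel-
#' associated dives and their pseudo-absences removed, and (ii) the
#' dive-characteristic model with a two-level vessel factor added, and
#' reports sign and significance agreement with the primary fits.
#'
#' @param ua_fit Primary use-availability `fd_fit` (its data must carry a
#'   logical `vessel` column, inherited by absences from their parent
#'   dives).
#' @param dive_fit Optional primary dive-characteristic `fd_fit` (data must
#'   carry `vessel`).
#' @return List with `ua_refit`, `dive_refit` (NULL if not requested) and a
#'   `comparison` tibble (term, primary and re-analysis estimates,
#'   `same_sign`, `signif_agrees`).
#' @export
vessel_sensitivity <- function(ua_fit, dive_fit = NULL) {
  stopifnot("vessel" %in% names(ua_fit$data))
  sub <- ua_fit$data[!ua_fit$data$vessel, , drop = FALSE]
  ua_refit <- refit_fd(ua_fit, data = sub)

  dive_refit <- NULL
  if (!is.null(dive_fit)) {
    stopifnot("vessel" %in% names(dive_fit$data))
    tl <- union(attr(terms(dive_fit$fixed), "term.labels"), "vessel")
    f <- reformulate(tl, response = all.vars(dive_fit$fixed)[1])
    dive_refit <- refit_fd(dive_fit, fixed = f)
  }

  cmp <- dplyr::inner_join(
    dplyr::select(ua_fit$terms, "term", primary = "estimate",
                  primary_p = "p.value"),
    dplyr::select(ua_refit$terms, "term", reanalysis = "estimate",
                  reanalysis_p = "p.value"),
    by = "term"
  ) |>
    dplyr::mutate(
      same_sign = sign(.data$primary) == sign(.data$reanalysis),
      signif_agrees = (.data$primary_p < 0.05) == (.data$reanalysis_p < 0.05)
    )
  list(ua_refit = ua_refit, dive_refit = dive_refit, comparison = cmp)
}
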