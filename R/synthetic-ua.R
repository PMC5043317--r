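#' Simulate a use-availability table from known coefficients
#'
#' Draws binary outcomes directly from the complementary log-log model used
#' in the habitat use-availability analysis:
#' `p = 1 - exp(-exp(eta))`, `eta = b0 + b_sexF * I(female) + b_m * metric +
#' b_int * I(female) * metric + b_bird`, with `b_bird ~ N(0, sigma_bird^2)`.
#' Each bird contributes `dives_per_bird` clusters of `1 + n_absence`
#' candidate rows (mirroring the 1 presence : 5 pseudo-absence design of the
#' real table); outcomes are then drawn stochastically from the model, which
#' is what the fitted GLMM assumes.
#'
#' @param true_betas Numeric length 4: intercept, sex (female), metric,
#'   sex:metric, on the cloglog scale.
#' @param n_birds Number of birds (>= 2; sexes balanced).
#' @param dives_per_bird Clusters per bird; rows per bird =
#'   `dives_per_bird * (1 + n_absence)`.
#' @param metric_field Source of covariate values: an [fd_raster()] (sampled
#'   at uniform random pixels), a numeric vector (resampled), or a function
#'   `f(n)` returning `n` draws.
#' @param sigma_bird SD of the bird-level random intercept.
#' @param seed Integer seed.
#' @param n_absence Pseudo-absence rows per cluster (default 5).
#' @param metric_name Column name for the covariate (default `"Gdens"`).
#' @return Tibble with `bird_id` (factor), `sex` (factor, male = base
#'   level), the metric column, `response` (0/1), and attribute `truth`
#'   (betas, sigma_bird, per-bird intercepts).
#' @export
simulate_use_availability <- function(true_betas, n_birds = 50,
                                      dives_per_bird = 40, metric_field = NULL,
                                      sigma_bird = 0.5, seed = 1,
                                      n_absence = 5, metric_name = "Gdens") {
  if (length(true_betas) != 4 || any(!is.finite(true_betas))) {
    stop("simulate_use_availability: true_betas must be 4 finite numbers")
  }
  stopifnot(n_birds >= 2, dives_per_bird >= 1, sigma_bird >= 0)

  rows_per_bird <- dives_per_bird * (1 + n_absence)
  n <- n_birds * rows_per_bird
  draw_metric <- function(n) {
    if (is.null(metric_field)) {
      # default: mostly-zero field with occasional frontal values, the shape
      # a smoothed gradient-density raster takes
      v <- numeric(n)
      hot <- runif(n) < 0.3
      v[hot] <- rgamma(sum(hot), shape = 2, scale = 0.08)
      v
    } else if (inherits(metric_field, "fd_raster")) {
      g <- metric_field$grid
      vals <- rep(NA_real_, n)
      need <- seq_len(n)
      while (length(need) > 0) { # resample pixels under cloud
        rr <- sample.int(g$ny, length(need), replace = TRUE)
        cc <- sample.int(g$nx, length(need), replace = TRUE)
        vals[need] <- metric_field$values[cbind(rr, cc)]
        need <- which(is.na(vals))
      }
      vals
    } else if (is.function(metric_field)) {
      metric_field(n)
    } else {
      sample(as.numeric(metric_field), n, replace = TRUE)
    }
  }

  with_seed(fd_substream(seed, 505), {
    sex_by_bird <- rep(c("male", "female"), length.out = n_birds)
    b_bird <- rnorm(n_birds, 0, sigma_bird)
    bird <- rep(seq_len(n_birds), each = rows_per_bird)
    m <- draw_metric(n)
    is_f <- as.numeric(sex_by_bird[bird] == "female")
    eta <- true_betas[1] + true_betas[2] * is_f + true_betas[3] * m +
      true_betas[4] * is_f * m + b_bird[bird]
    p <- -expm1(-exp(eta))
    y <- rbinom(n, 1, p)
  })

  out <- tibble::tibble(
    bird_id = factor(sprintf("bird%03d", bird)),
    sex = factor(sex_by_bird[bird], levels = c("male", "female")),
    metric = m,
    response = y
  )
  names(out)[names(out) == "metric"] <- metric_name
  attr(out, "truth") <- list(betas = true_betas, sigma_bird = sigma_bird,
                             b_bird = b_bird, metric_name = metric_name)
  out
}
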