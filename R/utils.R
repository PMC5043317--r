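#' @importFrom generics tidy glance augment
#' @importFrom rlang .data
#' @importFrom stats AIC aggregate anova approx as.formula binomial coef dnorm
#'   glm lm logLik median model.matrix pchisq plogis pnorm predict pt qchisq
#'   qnorm quantile rbinom reformulate rgamma rnorm runif sd setNames spline
#'   terms update var vcov
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# One global seed fans out to independent substreams, one per component, so
# that e.g. regenerating the depth traces does not perturb the SST scenes.
fd_substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 31 + k) %% 2147483647L
}

# run expr under a temporary RNG state seeded by `seed`; restores the caller's
# RNG afterwards so generators do not disturb ambient randomness
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

mean_se <- function(x) {
  x <- x[!is.na(x)]
  tibble::tibble(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}
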