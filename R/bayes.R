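#' Variational Gaussian over a set of weights
#'
#' Mean-field Gaussian posterior for a block of convolution weights: each
#' weight has posterior N(mean, sd^2) with sd stored on the log scale, and
#' an isotropic Gaussian prior N(prior_mean, prior_sd^2). The five default
#' segmentation levels use prior SDs 0.5, 1.0, 1.5, 2.0, 2.5.
#'
#' @param mean Numeric array/vector of posterior means.
#' @param log_sd Posterior log-SDs, same shape as `mean` (scalar recycled).
#' @param prior_mean,prior_sd Prior parameters (scalars).
#' @return An object of class `variational_gaussian`.
#' @export
variational_gaussian <- function(mean, log_sd = log(0.05), prior_mean = 0,
                                 prior_sd = 1) {
  if (length(log_sd) == 1L) log_sd <- array(log_sd, dim = dim(mean) %||%
                                              length(mean))
  stopifnot(length(log_sd) == length(mean), prior_sd > 0)
  structure(list(mean = mean, log_sd = log_sd, prior_mean = prior_mean,
                 prior_sd = prior_sd),
            class = "variational_gaussian")
}

#' Sample concrete weights by the reparameterization trick
#'
#' Draws `weights = mean + exp(log_sd) * eps` with `eps` standard normal,
#' so the draw is differentiable in the variational parameters. The draw
#' `eps` is attached as an attribute for gradient propagation.
#'
#' @param vg A [variational_gaussian()].
#' @param seed Optional integer seed for a reproducible draw.
#' @return Array of sampled weights with attribute `eps`.
#' @export
sample_weights <- function(vg, seed = NULL) {
  n <- length(vg$mean)
  eps <- if (is.null(seed)) rnorm(n) else with_seed(seed, rnorm(n))
  w <- vg$mean + exp(vg$log_sd) * eps
  attr(w, "eps") <- eps
  w
}

#' Kullback-Leibler divergence between diagonal Gaussians
#'
#' Closed form, summed over weights:
#' \deqn{KL = \sum_i \log(p_{sd}/q_{sd,i}) +
#'   (q_{sd,i}^2 + (q_{\mu,i}-p_\mu)^2)/(2 p_{sd}^2) - 1/2}
#'
#' @param q_mean,q_sd Posterior means and SDs (vectors/arrays).
#' @param p_mean,p_sd Prior mean and SD (scalars or same shape).
#' @return Nonnegative scalar; zero iff q equals p.
#' @export
kl_gaussian <- function(q_mean, q_sd, p_mean = 0, p_sd = 1) {
  stopifnot(all(q_sd > 0), all(p_sd > 0))
  sum(log(p_sd / q_sd) + (q_sd^2 + (q_mean - p_mean)^2) / (2 * p_sd^2) - 0.5)
}

# KL of a variational_gaussian against its own prior, plus gradients
kl_vg <- function(vg) {
  sd <- exp(vg$log_sd)
  kl <- kl_gaussian(vg$mean, sd, vg$prior_mean, vg$prior_sd)
  list(kl = kl,
       d_mean = (vg$mean - vg$prior_mean) / vg$prior_sd^2,
       d_log_sd = sd^2 / vg$prior_sd^2 - 1)
}
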