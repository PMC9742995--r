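## Metropolis-Hastings engine and the two fitting pipelines.  Both fits
## sample on the log scale (positivity without informative priors) with a
## Gaussian iid likelihood on growth rates; the point estimate is the chain
## state attaining the maximum recorded log-posterior.

#' Gaussian log-likelihood of predicted growth rates
#'
#' Independent homoscedastic Gaussian errors on growth rate:
#' \eqn{\sum_i \log N(\mu_i^{obs} \mid \mu_i^{pred}, \sigma^2)}.
#' Maximized exactly when all residuals vanish.
#'
#' @param predicted,observed equal-length growth-rate vectors (day^-1).
#' @param sigma observation noise standard deviation (day^-1), > 0.
#' @return the summed log-density.
#' @export
gaussianLogLikelihood <- function(predicted, observed, sigma) {
  if (length(predicted) != length(observed) || length(observed) < 1L)
    stop("predicted and observed must have equal length >= 1", call. = FALSE)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single number > 0", call. = FALSE)
  sum(stats::dnorm(observed, mean = predicted, sd = sigma, log = TRUE))
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Gaussian random-walk proposals with independent per-parameter scales;
#' a proposal is accepted with probability
#' \eqn{\min(1, e^{\Delta \log \mathrm{posterior}})}.  The chain is fully
#' reproducible given \code{seed}.
#'
#' @param logpost function taking a parameter vector and returning the
#'   (unnormalized) log-posterior; \code{-Inf} encodes zero prior support.
#' @param init parameter vector with finite \code{logpost(init)};
#'   names are carried into the sample matrix.
#' @param proposalScales positive per-parameter proposal standard
#'   deviations (recycled to the parameter length).
#' @param nIter number of iterations, >= 1.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param burnIn iterations to mark as burn-in; default 20 percent.
#' @param progress optional \code{function(iteration, logPost,
#'   acceptanceRate)} invoked every 1000 iterations.
#' @return an [McmcChain-class] object.
#' @export
metropolisHastings <- function(logpost, init, proposalScales, nIter,
                               seed = NULL, burnIn = NULL,
                               progress = NULL) {
  if (nIter < 1L) stop("nIter must be >= 1", call. = FALSE)
  p <- length(init)
  scales <- rep_len(proposalScales, p)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("proposalScales must be positive and finite", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cur <- init
  lp_cur <- logpost(cur)
  if (!is.finite(lp_cur))
    stop("log-posterior is not finite at the initial value; ",
         "re-initialize the chain from a supported point", call. = FALSE)
  samples <- matrix(NA_real_, nrow = nIter, ncol = p,
                    dimnames = list(NULL, names(init)))
  lp_trace <- numeric(nIter)
  acc <- logical(nIter)
  for (it in seq_len(nIter)) {
    prop <- cur + stats::rnorm(p, 0, scales)
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop
      lp_cur <- lp_prop
      acc[it] <- TRUE
    }
    samples[it, ] <- cur
    lp_trace[it] <- lp_cur
    if (!is.null(progress) && it %% 1000L == 0L)
      progress(it, lp_cur, mean(acc[seq_len(it)]))
  }
  if (is.null(burnIn)) burnIn <- floor(0.2 * nIter)
  new("McmcChain", samples = samples, logPost = lp_trace, accepted = acc,
      acceptanceRate = mean(acc), seed = if (is.null(seed)) NA_real_
      else as.numeric(seed), burnIn = as.integer(burnIn))
}

# Short adaptive pre-run: multiplicatively rescales the proposal widths
# toward ~30% acceptance over blocks of 100 iterations.  The pre-run draws
# are discarded; only the tuned scales and last state are kept, so the main
# chain remains a fixed-scale Metropolis-Hastings sampler.
.tune_scales <- function(logpost, init, scales, nBlocks = 10L) {
  cur <- init
  for (b in seq_len(nBlocks)) {
    nacc <- 0L
    for (it in 1:100) {
      prop <- cur + stats::rnorm(length(cur), 0, scales)
      lp_prop <- logpost(prop)
      lp_cur <- logpost(cur)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        cur <- prop
        nacc <- nacc + 1L
      }
    }
    rate <- nacc / 100
    scales <- scales * exp(rate - 0.3)
  }
  list(state = cur, scales = scales)
}

# Shared machinery: sample a 2-parameter model on the log scale with flat
# priors inside broad positive bounds, then summarize on the natural scale.
.fit_two_par <- function(model, predictFun, data, initNat, parNames,
                         iterations, seed, sigma, logBounds, adapt,
                         proposalScales, burnInFrac, progress) {
  obs <- data@mu_obs
  logpost <- function(theta) {
    if (any(theta < logBounds[, 1L]) || any(theta > logBounds[, 2L]))
      return(-Inf)
    pred <- tryCatch(predictFun(exp(theta)), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(-Inf)
    gaussianLogLikelihood(pred, obs, sigma)
  }
  theta0 <- log(initNat)
  if (!is.finite(logpost(theta0)))
    stop("log-posterior not finite at the initial estimates; ",
         "re-initialize (adjust starting values or bounds)", call. = FALSE)
  scales <- rep_len(proposalScales, 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (adapt) {
    tuned <- .tune_scales(logpost, theta0, scales)
    theta0 <- tuned$state
    scales <- tuned$scales
  }
  chain <- metropolisHastings(logpost, stats::setNames(theta0, parNames),
                              scales, iterations, seed = NULL,
                              burnIn = floor(burnInFrac * iterations),
                              progress = progress)
  # natural-scale samples for reporting
  nat <- exp(chain@samples)
  chain@samples <- nat
  best <- which.max(chain@logPost)
  est <- stats::setNames(nat[best, ], parNames)
  keep <- nat[(chain@burnIn + 1L):nrow(nat), , drop = FALSE]
  ci <- t(apply(keep, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  dimnames(ci) <- list(parNames, c("lo95", "hi95"))
  rss <- sum((predictFun(est) - obs)^2)
  new("FitResult", model = model, estimate = est,
      postMean = colMeans(keep), ci = ci, rss = rss, sigma = sigma,
      chain = chain)
}

#' Fit Monod kinetics to a growth dataset
#'
#' Metropolis-Hastings estimation of \eqn{(\mu_{max}, K_s)} from
#' growth-versus-nitrate points, sampling on the log scale (flat prior
#' within broad positive bounds).  Starting values default to simple
#' data-driven guesses: \eqn{\mu_{max}} slightly above the largest observed
#' rate and \eqn{K_s} from where the data cross half of it.
#'
#' @param data a [GrowthDataset-class] with at least 3 points.
#' @param iterations chain length (default 20000).
#' @param seed integer seed for reproducibility.
#' @param sigma likelihood noise scale (day^-1), default 0.05.
#' @param init optional named starting values \code{c(mu_max=, Ks=)}.
#' @param logBounds 2 x 2 matrix of log-scale prior bounds
#'   (rows: mu_max, Ks).
#' @param adapt run a short discarded proposal-tuning phase (default TRUE).
#' @param proposalScales initial log-scale proposal sd(s), default 0.1.
#' @param burnInFrac fraction of the chain marked burn-in, default 0.2.
#' @param progress optional progress callback, see [metropolisHastings()].
#' @return a [FitResult-class] over \code{mu_max} and \code{Ks}.
#' @export
fitMonod <- function(data, iterations = 20000L, seed = 1L, sigma = 0.05,
                     init = NULL,
                     logBounds = rbind(mu_max = log(c(1e-3, 1e3)),
                                       Ks = log(c(1e-4, 1e5))),
                     adapt = TRUE, proposalScales = 0.1,
                     burnInFrac = 0.2, progress = NULL) {
  stopifnot(is(data, "GrowthDataset"))
  if (length(data@no3) < 3L)
    stop("need at least 3 data points to fit Monod kinetics", call. = FALSE)
  if (all(data@mu_obs <= 0))
    stop("all observed growth rates are <= 0; nothing to fit", call. = FALSE)
  if (is.null(init)) {
    mu_max0 <- max(data@mu_obs) * 1.05
    half <- mu_max0 / 2
    above <- data@no3[data@mu_obs >= half & data@no3 > 0]
    Ks0 <- if (length(above)) min(above) else
      max(stats::median(data@no3[data@no3 > 0]), 1e-3)
    init <- c(mu_max = mu_max0, Ks = Ks0)
  }
  predictFun <- function(par) monodGrowth(data@no3,
                                          monodParams(par[1L], par[2L]))
  .fit_two_par("monod", predictFun, data, init, c("mu_max", "Ks"),
               iterations, seed, sigma, logBounds, adapt, proposalScales,
               burnInFrac, progress)
}

#' Fit the allocation model to a growth dataset
#'
#' Metropolis-Hastings estimation of the photosynthetic-protein-to-
#' chlorophyll ratio \eqn{A_{pho}} and the nitrate uptake affinity
#' \eqn{A_N} from growth-versus-nitrate points.  The base parameter set
#' carries the experiment's irradiance; \code{k_bio} is slaved to
#' \eqn{A_{pho}} through the fixed ratio \code{r_bio_pho} so that only two
#' parameters are free.  The model curve is the realized (min of C- and
#' N-limited) growth rate at each nitrate concentration; parameter
#' proposals that make the carbon budget infeasible receive zero posterior
#' support.
#'
#' @param data a [GrowthDataset-class] with at least 3 points.
#' @param base a [CfmParams-class] parameterized with the experiment's
#'   irradiance; its \code{A_pho} and \code{A_N} seed the chain unless
#'   \code{init} is given.
#' @param init optional named starting values \code{c(A_pho=, A_N=)}.
#' @param logBounds 2 x 2 matrix of log-scale prior bounds
#'   (rows: A_pho, A_N).
#' @inheritParams fitMonod
#' @return a [FitResult-class] over \code{A_pho} and \code{A_N}.
#' @export
fitCfm <- function(data, base, iterations = 20000L, seed = 1L,
                   sigma = 0.05, init = NULL,
                   logBounds = rbind(A_pho = log(c(1e-2, 1e3)),
                                     A_N = log(c(1e-6, 1e3))),
                   adapt = TRUE, proposalScales = 0.1,
                   burnInFrac = 0.2, progress = NULL) {
  stopifnot(is(data, "GrowthDataset"), is(base, "CfmParams"))
  if (length(data@no3) < 3L)
    stop("need at least 3 data points to fit the allocation model",
         call. = FALSE)
  if (all(data@mu_obs <= 0))
    stop("all observed growth rates are <= 0; nothing to fit", call. = FALSE)
  .assert_feasible(base)
  if (is.null(init)) init <- c(A_pho = base@A_pho, A_N = base@A_N)
  predictFun <- function(par) {
    pp <- setFittedParams(base, A_pho = par[1L], A_N = par[2L])
    .realized_mu(pp, data@no3)
  }
  .fit_two_par("cfm", predictFun, data, init, c("A_pho", "A_N"),
               iterations, seed, sigma, logBounds, adapt, proposalScales,
               burnInFrac, progress)
}
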