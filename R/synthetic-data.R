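## Seeded generators for growth-versus-nitrate datasets with the
## statistical structure the fitting pipeline assumes: a known mean curve
## (Monod or allocation model) plus additive homoscedastic Gaussian noise,
## truncated at zero growth.  Default grids mimic typical culture designs:
## 6-12 concentrations spanning zero to about four times the saturation
## scale of the curve (Ks for Monod, the limitation crossover for the
## allocation model).

#' Construct a growth dataset directly
#'
#' @param no3 nitrate concentrations (uM), >= 0.
#' @param mu_obs observed growth rates (day^-1).
#' @param species species label.
#' @param irradiance experiment irradiance (umol photons m^-2 s^-1).
#' @param provenance \code{"synthetic"} or \code{"file"}.
#' @return a [GrowthDataset-class] object.
#' @export
growthDataset <- function(no3, mu_obs, species = "unnamed",
                          irradiance = 200, provenance = "synthetic") {
  new("GrowthDataset", species = species, irradiance = irradiance,
      no3 = as.numeric(no3), mu_obs = as.numeric(mu_obs),
      provenance = provenance)
}

.noisy_points <- function(mean_mu, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pmax(mean_mu + stats::rnorm(length(mean_mu), 0, noise_sd), 0)
}

#' Generate a synthetic Monod dataset
#'
#' Observed rates are \code{monodGrowth(no3)} plus Gaussian noise of sd
#' \code{noise_sd}, truncated at zero; deterministic under \code{seed}.
#'
#' @param true a [MonodParams-class]: the generating curve.
#' @param no3_grid nitrate grid (uM); default 10 concentrations spanning
#'   0 to 4 Ks.
#' @param noise_sd observation noise sd (day^-1), >= 0.
#' @param seed integer seed.
#' @param species species label for the dataset.
#' @param irradiance irradiance recorded with the dataset.
#' @return a [GrowthDataset-class] with provenance \code{"synthetic"}.
#' @export
generateMonodDataset <- function(true, no3_grid = NULL, noise_sd = 0.05,
                                 seed = 1L, species = "synthetic Monod",
                                 irradiance = 200) {
  stopifnot(is(true, "MonodParams"))
  if (is.null(no3_grid)) no3_grid <- seq(0, 4 * true@Ks, length.out = 10L)
  if (!length(no3_grid)) stop("no3_grid must be non-empty", call. = FALSE)
  mu <- monodGrowth(no3_grid, true)
  growthDataset(no3_grid, .noisy_points(mu, noise_sd, seed),
                species = species, irradiance = irradiance)
}

#' Generate a synthetic allocation-model dataset
#'
#' Observed rates follow the realized (min of C- and N-limited) growth
#' curve of \code{true} plus truncated Gaussian noise; the default grid
#' spans 0 to 4 times the limitation crossover so both regimes are
#' represented.
#'
#' @param true a [CfmParams-class]: the generating parameter set.
#' @param no3_grid nitrate grid (uM); default 10 concentrations spanning
#'   0 to 4 times [crossoverNo3()].
#' @param noise_sd observation noise sd (day^-1), >= 0.
#' @param seed integer seed.
#' @param species species label for the dataset.
#' @return a [GrowthDataset-class] with provenance \code{"synthetic"} and
#'   the irradiance of \code{true}.
#' @export
generateCfmDataset <- function(true, no3_grid = NULL, noise_sd = 0.05,
                               seed = 1L, species = "synthetic CFM") {
  stopifnot(is(true, "CfmParams"))
  if (is.null(no3_grid))
    no3_grid <- seq(0, 4 * crossoverNo3(true), length.out = 10L)
  if (!length(no3_grid)) stop("no3_grid must be non-empty", call. = FALSE)
  mu <- .realized_mu(true, no3_grid)
  growthDataset(no3_grid, .noisy_points(mu, noise_sd, seed),
                species = species, irradiance = true@I)
}
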