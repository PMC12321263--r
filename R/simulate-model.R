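## Synthetic datasets for the linear GRN->PER model and for the
## Scheirer-Ray-Hare size/power studies.

#' Generate a per-odor dataset for the linear PER model
#'
#' Draws positive per-odor GRN predictor responses and builds the outcome
#' as `w1 * gr5a + w2 * gr66a + intercept + Gaussian noise`. Default
#' predictor scales put the weight magnitudes in the regime of the
#' sweet/bitter pathway model (weights of order `5e-4` and `-2e-5` with
#' PER magnitudes of order 1 s).
#'
#' @param weights length-2 numeric `c(w_gr5a, w_gr66a)`.
#' @param intercept intercept (default 0.2).
#' @param noise_sd outcome noise SD (default 0.1).
#' @param n_odors number of odors (default 9, minimum 3).
#' @param gr5a_mean,gr5a_sd,gr66a_mean,gr66a_sd predictor gamma-moment
#'   parameters (positive responses).
#' @param seed integer seed.
#' @return data.frame: `odor`, `gr5a`, `gr66a`, `per_magnitude`,
#'   `per_expected` (noiseless outcome).
#' @export
generateModelDataset <- function(weights = c(5.0e-4, -2.3e-5),
                                 intercept = 0.2, noise_sd = 0.1,
                                 n_odors = 9,
                                 gr5a_mean = 1500, gr5a_sd = 800,
                                 gr66a_mean = 3000, gr66a_sd = 1800,
                                 seed = 1L) {
  if (n_odors < 3L) stop("need at least 3 odors")
  withSeed(seed, {
    rgam <- function(n, m, s) {
      shape <- (m / s)^2
      rgamma(n, shape = shape, rate = shape / m)
    }
    gr5a <- rgam(n_odors, gr5a_mean, gr5a_sd)
    gr66a <- rgam(n_odors, gr66a_mean, gr66a_sd)
    mu <- weights[1] * gr5a + weights[2] * gr66a + intercept
    y <- mu + rnorm(n_odors, 0, noise_sd)
    data.frame(odor = paste0("odor", seq_len(n_odors)),
               gr5a = gr5a, gr66a = gr66a,
               per_magnitude = y, per_expected = mu,
               stringsAsFactors = FALSE)
  })
}

#' Generate a factorial dataset for rank-test size/power studies
#'
#' Continuous observations on a crossed genotype x odor layout with
#' planted additive main effects and interaction (in units of the residual
#' SD), for checking the Scheirer-Ray-Hare test's type-I error and power.
#'
#' @param a_levels,b_levels numbers of factor levels (default 3 genotypes
#'   x 9 odors).
#' @param n_per_cell observations per cell (default 5).
#' @param effect_a,effect_b planted main-effect sizes in SD units: level
#'   `i` of A shifts the mean by `effect_a * (i - 1) / (a_levels - 1)`,
#'   likewise for B (0 = null).
#' @param effect_ab planted interaction size in SD units (0 = null).
#' @param sd residual SD (default 1).
#' @param seed integer seed.
#' @return data.frame: `value`, `A`, `B`.
#' @export
generateFactorialDataset <- function(a_levels = 3, b_levels = 9,
                                     n_per_cell = 5, effect_a = 0,
                                     effect_b = 0, effect_ab = 0, sd = 1,
                                     seed = 1L) {
  withSeed(seed, {
    g <- expand.grid(A = seq_len(a_levels), B = seq_len(b_levels),
                     rep = seq_len(n_per_cell))
    mu <- effect_a * (g$A - 1) / max(1, a_levels - 1) +
      effect_b * (g$B - 1) / max(1, b_levels - 1) +
      effect_ab * ((g$A - 1) / max(1, a_levels - 1)) *
        ((g$B - 1) / max(1, b_levels - 1))
    data.frame(value = rnorm(nrow(g), mu * sd, sd),
               A = factor(paste0("a", g$A)),
               B = factor(paste0("b", g$B)))
  })
}
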