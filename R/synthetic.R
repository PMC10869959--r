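#' Specification of a synthetic IVF/ICSI-like cohort
#'
#' Describes the simulated study conditions: about 1000 treatment cycles,
#' 38 candidate predictors, a clinical-pregnancy prevalence of 31.7%, and
#' seven informative predictors (day-3 FSH dose, female age, oocytes
#' retrieved, day-3/4 embryo-cell counts, transferred-embryo quality grade,
#' and the number of previous unsuccessful cycles) carrying planted
#' class-conditional mean shifts; all remaining predictors are outcome-
#' independent noise.
#'
#' Default effect sizes are standardized mean differences (Cohen's d)
#' between 0.4 and 0.8, the moderate range typical of the clinical
#' predictors this generator emulates. All planted effects point the same
#' way as the clinical literature on these factors: larger values
#' (older age, higher FSH dose, more prior failures, ...) accompany a
#' lower success probability.
#'
#' @param n number of cycles (default 1000).
#' @param p number of predictors (default 38; at least 7).
#' @param prevalence expected positive-class fraction (default 0.317,
#'   the clinical-pregnancy rate; use 0.258 for the ongoing-pregnancy
#'   outcome definition).
#' @param informative_names names of the 7 informative predictors.
#' @param effect_sizes named numeric vector of |Cohen's d| per informative
#'   predictor.
#' @param noise_correlation pairwise correlation among noise predictors
#'   (compound symmetry, default 0).
#' @param seed integer seed.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n = 1000L, p = 38L, prevalence = 0.317,
                        informative_names = c("FSH", "FAge", "oocytes",
                                              "unsuccessful", "16Cells",
                                              "compact", "GIII"),
                        effect_sizes = c(FSH = 0.8, FAge = 0.6,
                                         oocytes = 0.55, unsuccessful = 0.45,
                                         `16Cells` = 0.5, compact = 0.45,
                                         GIII = 0.4),
                        noise_correlation = 0, seed = 1L) {
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must lie in (0,1)")
  if (length(informative_names) > p)
    stop("more informative names than predictors")
  if (anyDuplicated(informative_names))
    stop("informative names must be unique")
  effect_sizes <- effect_sizes[informative_names]
  if (anyNA(effect_sizes) || any(!is.finite(effect_sizes)))
    stop("effect_sizes must give a finite value for every informative name")
  if (n < 1 || p < 1) stop("n and p must be positive")
  if (noise_correlation < 0 || noise_correlation >= 1)
    stop("noise_correlation must lie in [0,1)")
  structure(list(n = as.integer(n), p = as.integer(p),
                 prevalence = prevalence,
                 informative_names = informative_names,
                 effect_sizes = effect_sizes,
                 noise_correlation = noise_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# baseline (unsuccessful-class) marginals for the informative predictors;
# count-like predictors are Poisson, continuous ones normal
.informative_marginals <- list(
  FSH          = list(kind = "normal",  mean = 11.5, sd = 2.5),
  FAge         = list(kind = "normal",  mean = 30.9, sd = 4.6),
  oocytes      = list(kind = "poisson", lambda = 9),
  unsuccessful = list(kind = "poisson", lambda = 0.6),
  `16Cells`    = list(kind = "poisson", lambda = 2.2),
  compact      = list(kind = "poisson", lambda = 2.0),
  GIII         = list(kind = "poisson", lambda = 1.2)
)

#' Generate a synthetic cohort with planted signal
#'
#' Draws the outcome first (Bernoulli at the specified prevalence) and the
#' predictors conditional on outcome class, so the planted standardized
#' mean differences hold by construction. Informative predictors follow
#' the clinically plausible marginals of the factors they are named after
#' (e.g. female age with mean ~30.9 years; nonnegative integer counts for
#' oocytes, embryo-cell counts, embryo grade and prior failures); noise
#' predictors are standard normal and independent of the outcome. Effects
#' are planted with a negative sign: the positive (successful) class has
#' the lower mean.
#'
#' Unknown informative names fall back to a standard-normal marginal, so
#' custom signal layouts remain possible.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A list with elements \code{table} (a
#'   \code{\link{feature_table}}) and \code{truth} (list with
#'   \code{informative_indices}, 1-based column positions, and
#'   \code{directions}, the signed effect per informative predictor).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, p = 10, seed = 42))
#' cohort$table
#' cohort$truth$informative_indices
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$informative_names)
  # fixed layout: informative predictors at the positions the cohort's
  # record format uses (2, 4, 7, 9, 12, 15, 18) when room allows,
  # otherwise the first k columns
  pos <- c(2L, 4L, 7L, 9L, 12L, 15L, 18L)[seq_len(min(k, 7L))]
  if (k > 7L || spec$p < max(pos)) pos <- seq_len(k)
  with_seed(spec$seed, {
    y <- stats::rbinom(spec$n, 1L, spec$prevalence)
    v <- matrix(0, spec$n, spec$p)
    nm <- paste0("x", sprintf("%02d", seq_len(spec$p)))
    dirs <- rep(-1, k)
    names(dirs) <- spec$informative_names
    for (i in seq_len(k)) {
      name <- spec$informative_names[i]
      d <- spec$effect_sizes[[name]] * dirs[i]
      marg <- .informative_marginals[[name]]
      if (is.null(marg)) marg <- list(kind = "normal", mean = 0, sd = 1)
      v[, pos[i]] <- if (marg$kind == "poisson") {
        lam0 <- marg$lambda
        lam1 <- max(0.05, lam0 + d * sqrt(lam0))
        stats::rpois(spec$n, ifelse(y == 1, lam1, lam0))
      } else {
        mu <- marg$mean + ifelse(y == 1, d * marg$sd, 0)
        stats::rnorm(spec$n, mu, marg$sd)
      }
      nm[pos[i]] <- name
    }
    noise <- setdiff(seq_len(spec$p), pos)
    if (length(noise)) {
      z <- matrix(stats::rnorm(spec$n * length(noise)), spec$n)
      if (spec$noise_correlation > 0) {
        shared <- stats::rnorm(spec$n)
        z <- sqrt(spec$noise_correlation) * shared +
          sqrt(1 - spec$noise_correlation) * z
      }
      v[, noise] <- z
    }
    list(table = feature_table(v, y, nm),
         truth = list(informative_indices = pos,
                      directions = dirs * spec$effect_sizes))
  })
}
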