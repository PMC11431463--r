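#' Parameters of the profile quality metric
#'
#' The metric scores a single-source profile as a weighted sum of four
#' nonpositive components: a Normal log-density penalty on the mean observed
#' peak height (ideal `mu_a`, tolerated spread `sigma_a`), an exponential
#' log-density penalty on the coefficient of variation of peak heights
#' (rate `lambda_cov`), a linear artefact penalty and a linear duration
#' penalty. Each log-density component is offset by its own maximum so an
#' ideal profile scores exactly 0; with `k0 = k1 = 1` the two offsets sum to
#' the single constant `C = log10 p(mu_a | mu_a, sigma_a) + log10 lambda`.
#'
#' None of the constants are canonical: they must be balanced against each
#' other for the profiling kit in use. The defaults put the ideal mean height
#' at 5000 RFU (high enough to avoid dropout, below pull-up/saturation
#' territory) with a tolerated spread of 1000 RFU, a COV rate of 2, unit
#' weight on both density components, one score unit per artefact peak, and
#' 0.05 score units per minute of cycling.
#'
#' @param mu_a Ideal mean peak height (RFU), > 0.
#' @param sigma_a Tolerated spread around the ideal (RFU), > 0.
#' @param lambda_cov Rate of the exponential COV penalty, > 0.
#' @param k0,k1 Nonnegative weights on the height and COV components.
#' @param k2,k3 Nonpositive weights on the artefact count (or summed RFU)
#'   and the cycling duration in minutes.
#' @param cov_power Exponent applied to the mean before dividing the standard
#'   deviation (1 = plain COV; 0.8 removes the empirical correlation between
#'   COV and mean height in low-template profiles).
#' @param artefact_mode `"count"` (penalise the number of artefact peaks) or
#'   `"summed_rfu"` (penalise their total height).
#' @return A list of class `score_params`.
#' @export
score_params <- function(mu_a = 5000, sigma_a = 1000, lambda_cov = 2,
                         k0 = 1, k1 = 1, k2 = -1, k3 = -0.05,
                         cov_power = 1,
                         artefact_mode = c("count", "summed_rfu")) {
  artefact_mode <- match.arg(artefact_mode)
  stopifnot(mu_a > 0, sigma_a > 0, lambda_cov > 0,
            k0 >= 0, k1 >= 0, k2 <= 0, k3 <= 0, cov_power > 0)
  structure(
    list(mu_a = mu_a, sigma_a = sigma_a, lambda_cov = lambda_cov,
         k0 = k0, k1 = k1, k2 = k2, k3 = k3, cov_power = cov_power,
         artefact_mode = artefact_mode),
    class = "score_params"
  )
}

#' Peak-height component of the quality score
#'
#' log10 of the Normal density at the observed mean, offset by the log10
#' density at the ideal, so the maximum is 0 at `x_bar = mu_a`. Equal to
#' `-(x_bar - mu_a)^2 / (2 sigma_a^2) * log10(e)`.
#'
#' @param x_bar Mean of the observed (called) peak heights.
#' @param mu_a,sigma_a Ideal mean and tolerated spread (RFU).
#' @return Nonpositive penalty (vectorised over `x_bar`).
#' @export
height_score <- function(x_bar, mu_a, sigma_a) {
  stopifnot(sigma_a > 0)
  dnorm(x_bar, mu_a, sigma_a, log = TRUE) / log(10) -
    dnorm(mu_a, mu_a, sigma_a, log = TRUE) / log(10)
}

#' Coefficient of variation of peak heights
#'
#' Population (divide-by-N) standard deviation over the mean raised to
#' `cov_power`. The vector is expected to contain a 0 entry for every missing
#' expected allele, so dropout, within-locus imbalance and between-locus
#' imbalance all inflate the statistic.
#'
#' @param heights Numeric vector of peak heights (zeros allowed).
#' @param cov_power Exponent on the mean (1 = plain COV, 0.8 = adjusted).
#' @return Nonnegative scalar.
#' @export
peak_cov <- function(heights, cov_power = 1) {
  stopifnot(length(heights) > 0, all(heights >= 0))
  m <- mean(heights)
  if (m <= 0) {
    abort("coefficient of variation undefined: mean height is zero",
          class = "smartpcr_domain_error")
  }
  sqrt(mean((heights - m)^2)) / m^cov_power
}

#' Coefficient of variation from reported moments
#'
#' @param mean_rfu Mean peak height, > 0.
#' @param sd_rfu Standard deviation of peak heights, >= 0.
#' @return `sd_rfu / mean_rfu`.
#' @examples
#' cov_from_moments(687, 631) # 0.92
#' @export
cov_from_moments <- function(mean_rfu, sd_rfu) {
  if (any(mean_rfu <= 0)) {
    abort("mean_rfu must be positive", class = "smartpcr_domain_error")
  }
  stopifnot(all(sd_rfu >= 0))
  sd_rfu / mean_rfu
}

#' Peak-balance component of the quality score
#'
#' log10 of the exponential density at the observed COV, offset by its
#' maximum (log10 lambda), i.e. `-lambda * cv * log10(e)`; 0 when the peaks
#' are perfectly balanced.
#'
#' @param cv Coefficient of variation, >= 0.
#' @param lambda_cov Exponential rate, > 0.
#' @return Nonpositive penalty (vectorised over `cv`).
#' @export
cov_score <- function(cv, lambda_cov) {
  stopifnot(lambda_cov > 0, all(cv >= 0))
  (log(lambda_cov) - lambda_cov * cv) / log(10) - log(lambda_cov) / log(10)
}

#' Summarise a called profile for scoring
#'
#' Builds the two height views the metric needs: the mean of the observed
#' (called, non-artefact, donor-position) peaks, and the expected-length
#' height vector with missing donor positions set to 0 from which the COV is
#' computed. Artefact peaks are counted (and summed) separately.
#'
#' @param profile An [str_profile()] after [call_alleles()].
#' @param reference A [reference_genotype()]; defaults to the profile's own.
#' @param t_minutes Denature + anneal cycling time of the program that
#'   produced the profile (see [cycling_time_minutes()]); holds excluded.
#' @param cov_power Exponent on the mean in the COV (see [peak_cov()]).
#' @return One-row tibble: `sample`, `x_bar_observed`, `cv`, `n_observed`,
#'   `n_expected`, `n_artefacts`, `artefact_rfu_sum`, `t_minutes`, plus the
#'   full height vector in the list-column `heights`.
#' @export
profile_summary <- function(profile, reference = profile$reference,
                            t_minutes = 0, cov_power = 1) {
  stopifnot(inherits(profile, "str_profile"), t_minutes >= 0)
  if (is.null(reference)) {
    abort("a reference genotype is required", class = "smartpcr_domain_error")
  }
  donor <- dplyr::filter(profile$peaks, !.data$artefact)
  matched <- dplyr::left_join(
    tibble::as_tibble(reference)[c("locus", "allele")],
    donor[c("locus", "allele", "height_rfu")],
    by = c("locus", "allele")
  )
  heights <- dplyr::coalesce(matched$height_rfu, 0)
  observed <- heights[heights > 0]
  artefacts <- dplyr::filter(profile$peaks, .data$artefact)
  tibble::tibble(
    sample = profile$sample,
    x_bar_observed = if (length(observed) > 0) mean(observed) else 0,
    cv = peak_cov(heights, cov_power = cov_power),
    n_observed = length(observed),
    n_expected = length(heights),
    n_artefacts = nrow(artefacts),
    artefact_rfu_sum = sum(artefacts$height_rfu),
    t_minutes = t_minutes,
    heights = list(heights)
  )
}

#' Score a DNA profile
#'
#' Computes the total quality score and its per-component decomposition:
#' `total = k0 * height_score + k1 * cov_score + k2 * artefacts + k3 * t`.
#' Every component is nonpositive, so 0 is the ideal and more negative is
#' worse; the total is 0 exactly when every component is 0.
#'
#' @inheritParams profile_summary
#' @param params A [score_params()].
#' @return One-row tibble of class `score_breakdown`: the summary columns
#'   plus `height_component`, `cov_component`, `artefact_component`,
#'   `duration_component`, `offset_constant` and `total`.
#' @examples
#' ref <- example_reference_genotype()
#' ideal <- str_profile("ideal", dplyr::mutate(ref, height_rfu = 5000), ref)
#' score_profile(ideal, t_minutes = 0,
#'               params = score_params(mu_a = 5000, k3 = 0))$total # 0
#' @export
score_profile <- function(profile, t_minutes, params = score_params(),
                          reference = profile$reference) {
  stopifnot(inherits(params, "score_params"))
  s <- profile_summary(profile, reference = reference,
                       t_minutes = t_minutes, cov_power = params$cov_power)
  artefact_size <- switch(params$artefact_mode,
    count = s$n_artefacts,
    summed_rfu = s$artefact_rfu_sum
  )
  out <- dplyr::mutate(
    s,
    height_component = params$k0 *
      height_score(.data$x_bar_observed, params$mu_a, params$sigma_a),
    cov_component = params$k1 * cov_score(.data$cv, params$lambda_cov),
    artefact_component = params$k2 * artefact_size,
    duration_component = params$k3 * .data$t_minutes,
    offset_constant =
      dnorm(params$mu_a, params$mu_a, params$sigma_a, log = TRUE) / log(10) +
      log(params$lambda_cov) / log(10),
    total = .data$height_component + .data$cov_component +
      .data$artefact_component + .data$duration_component
  )
  class(out) <- c("score_breakdown", class(out))
  out
}

#' @export
tidy.score_breakdown <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[c("sample", "height_component", "cov_component",
                           "artefact_component", "duration_component")],
    -"sample", names_to = "component", values_to = "penalty",
    names_pattern = "(.*)_component"
  )
}

#' @export
glance.score_breakdown <- function(x, ...) {
  tibble::as_tibble(x)[c("sample", "x_bar_observed", "cv", "n_artefacts",
                         "t_minutes", "total")]
}

#' Plot the penalty decomposition of one or more scored profiles
#' @param object A `score_breakdown` (rows may cover several profiles).
#' @param ... Unused.
#' @return A ggplot bar chart of penalties by component.
#' @export
autoplot.score_breakdown <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$component, y = .data$penalty,
                               fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "penalty (log10 score units)")
}
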