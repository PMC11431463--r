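#' Parameters of the phenomenological PCR simulator
#'
#' The simulator stands in for a real open qPCR instrument so that scoring,
#' curve fitting, optimization and closed-loop control can be exercised
#' end-to-end. It is deliberately phenomenological: per-cycle efficiency is
#' unimodal in annealing time and Gaussian in annealing temperature,
#' fluorescence follows noisy logistic growth towards an
#' efficiency-dependent carrying capacity, and end-point STR peak heights
#' share the curve's plateau with height-dependent lognormal variability and
#' a hard dropout floor.
#'
#' Default calibration (see the methods vignette): a 30 pg input amplified
#' with the standard 30-cycle endpoint program yields a mean peak height of
#' roughly 660 RFU with COV near 0.9 (the trace-DNA regime reported for that
#' protocol), and shortening the annealing/extension step from 70 s to 10 s
#' drops the qPCR plateau from about 5500 to about 3000 RFU.
#'
#' @param template_pg Starting DNA mass in picograms.
#' @param e_max Maximum per-cycle amplification efficiency, in (0, 1].
#' @param t_opt_seconds Annealing/extension time of peak efficiency.
#' @param temp_opt_c,temp_width_c Centre and width of the Gaussian
#'   temperature response of the annealing step.
#' @param f_sat Fluorescence saturation ceiling (RFU).
#' @param f0_per_pg Initial fluorescence-equivalent per pg of template.
#' @param noise_sd Multiplicative (lognormal) per-cycle noise scale on the
#'   fluorescence update.
#' @param height_noise_sd Baseline lognormal log-sd of simulated peak
#'   heights at one template copy per allele; the effective log-sd scales as
#'   `copies^-0.2`, so linear height spread grows like mean^0.8.
#' @param h_cap Peak-height scale (RFU): the asymptotic mean height at
#'   saturating template under a full-efficiency program.
#' @param template_half_pg Template mass at which mean peak height reaches
#'   half of `h_cap`.
#' @param degradation_k Per-bp exponential decay of peak height with
#'   fragment size (0 = no degradation slope).
#' @param size_ref_bp Fragment size at which the degradation factor is 1.
#' @param dropout_floor_rfu Simulated peaks below this height drop out.
#' @param seed Default RNG seed used when no seed is passed to the
#'   simulation functions.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(template_pg = 30, e_max = 0.95, t_opt_seconds = 70,
                       temp_opt_c = 60, temp_width_c = 5,
                       f_sat = 5500, f0_per_pg = 2e-5,
                       noise_sd = 0.02, height_noise_sd = 1.0,
                       h_cap = 46000, template_half_pg = 2000,
                       degradation_k = 0.001, size_ref_bp = 150,
                       dropout_floor_rfu = 30, seed = NULL) {
  stopifnot(template_pg >= 0, e_max > 0, e_max <= 1, t_opt_seconds > 0,
            temp_width_c > 0, f_sat > 0, f0_per_pg > 0, noise_sd >= 0,
            height_noise_sd >= 0, h_cap > 0, template_half_pg > 0,
            degradation_k >= 0, dropout_floor_rfu >= 0)
  structure(
    list(template_pg = template_pg, e_max = e_max,
         t_opt_seconds = t_opt_seconds, temp_opt_c = temp_opt_c,
         temp_width_c = temp_width_c, f_sat = f_sat, f0_per_pg = f0_per_pg,
         noise_sd = noise_sd, height_noise_sd = height_noise_sd,
         h_cap = h_cap, template_half_pg = template_half_pg,
         degradation_k = degradation_k, size_ref_bp = size_ref_bp,
         dropout_floor_rfu = dropout_floor_rfu, seed = seed),
    class = "sim_params"
  )
}

.efficiency_num <- function(params, anneal_seconds, temperature_c) {
  tt <- anneal_seconds / params$t_opt_seconds
  time_factor <- ifelse(anneal_seconds <= 0, 0, tt * exp(1 - tt))
  temp_factor <- exp(-(temperature_c - params$temp_opt_c)^2 /
                       (2 * params$temp_width_c^2))
  pmin(pmax(params$e_max * time_factor * temp_factor, 0), 1)
}

#' Per-cycle amplification efficiency
#'
#' Unimodal in annealing time (maximum `e_max` at `t_opt_seconds`, zero at
#' zero annealing time, declining for over-long steps) and Gaussian in
#' annealing temperature, clipped to `[0, 1]`:
#' `e_max * (t/t_opt) * exp(1 - t/t_opt) * exp(-(T - T_opt)^2 / (2 w^2))`.
#'
#' @param params A [sim_params()].
#' @param step An anneal/extend [cycling_step()].
#' @param cycle_index Cycle at which to resolve a ramped duration.
#' @return Efficiency in `[0, 1]`.
#' @export
per_cycle_efficiency <- function(params, step, cycle_index = 1) {
  stopifnot(inherits(params, "sim_params"), inherits(step, "cycling_step"))
  .efficiency_num(params, step_duration_at_cycle(step, cycle_index),
                  step$temperature_c)
}

# One logistic growth cycle: carrying capacity scales with efficiency so
# short anneal steps plateau lower, as observed when anneal time is varied.
.qpcr_advance <- function(f, eff, params, z) {
  k <- params$f_sat * (0.4 + 0.6 * eff / params$e_max)
  eps <- exp(params$noise_sd * z - params$noise_sd^2 / 2)
  f_new <- f * (1 + eff * (1 - f / k)) * eps
  min(max(f_new, 0), params$f_sat * (1 + 5 * params$noise_sd))
}

# anneal schedule (seconds, temperature) per global cycle of a program
.anneal_schedule <- function(program) {
  sched <- program_schedule(program)
  anneal <- sched[sched$label == "anneal_extend", ]
  denat <- sched[sched$label == "denature", ]
  cycles <- sort(unique(sched$cycle))
  tibble::tibble(
    cycle = cycles,
    anneal_seconds = anneal$seconds[match(cycles, anneal$cycle)],
    anneal_temp_c = anneal$temperature_c[match(cycles, anneal$cycle)],
    cycle_seconds = dplyr::coalesce(anneal$seconds[match(cycles, anneal$cycle)], 0) +
      dplyr::coalesce(denat$seconds[match(cycles, denat$cycle)], 0)
  )
}

#' Simulate a qPCR amplification curve
#'
#' Runs the logistic-growth kinetics over every cycled stage of `program`:
#' `F_{c+1} = F_c * (1 + E_c * (1 - F_c / K_c)) * eps_c` with lognormal
#' multiplicative noise `eps_c`, per-cycle efficiency `E_c` from
#' [per_cycle_efficiency()], and carrying capacity `K_c` increasing with
#' efficiency. Cycles without an anneal/extend step contribute no growth.
#' Fully deterministic under a fixed seed.
#'
#' @param params A [sim_params()].
#' @param program A [pcr_program()].
#' @param seed RNG seed (defaults to `params$seed`; `NULL` uses the current
#'   RNG state).
#' @param well,channel Identifiers stamped on the returned curve.
#' @return An [amp_curve()] on the cycle axis with an extra
#'   `elapsed_minutes` column (cumulative denature + anneal time).
#' @export
simulate_qpcr <- function(params, program, seed = params$seed,
                          well = "A1", channel = 1L) {
  stopifnot(inherits(params, "sim_params"), inherits(program, "pcr_program"))
  if (!is.null(seed)) set.seed(seed)
  sched <- .anneal_schedule(program)
  n <- nrow(sched)
  f <- params$f0_per_pg * params$template_pg
  fl <- numeric(n)
  for (i in seq_len(n)) {
    eff <- if (is.na(sched$anneal_seconds[i])) 0 else
      .efficiency_num(params, sched$anneal_seconds[i], sched$anneal_temp_c[i])
    z <- rnorm(1)
    f <- .qpcr_advance(f, eff, params, z)
    fl[i] <- f
  }
  out <- amp_curve(sched$cycle, fl, well = well, channel = channel,
                   x_axis = "cycle")
  out$elapsed_minutes <- cumsum(sched$cycle_seconds) / 60
  .as_amp_curve(out, out)
}

# deterministic plateau of a program, used to couple peak heights to the
# cycling conditions
.deterministic_plateau <- function(params, program) {
  quiet <- params
  quiet$noise_sd <- 0
  quiet$template_pg <- max(params$template_pg, 1e-12)
  curve <- simulate_qpcr(quiet, program, seed = NULL)
  max(curve$fluorescence)
}

#' Simulate an end-point STR profile
#'
#' Generates per-allele peak heights for the donor's reference genotype
#' under the given cycling program. The mean height couples the program's
#' deterministic qPCR plateau share with a saturating response to template
#' mass; each allele is attenuated exponentially with fragment size
#' (degradation) and perturbed by lognormal noise whose log-sd scales as
#' `copies^-0.2`, so low-template profiles are both lower and relatively
#' more variable (the classic height/imbalance relationship). Heights below
#' the dropout floor are removed.
#'
#' @inheritParams simulate_qpcr
#' @param reference A [reference_genotype()] with a `size_bp` column.
#' @param sample Sample id for the returned profile.
#' @return An [str_profile()] carrying the reference genotype.
#' @export
simulate_profile <- function(params, program, reference,
                             seed = params$seed, sample = "sim") {
  stopifnot(inherits(params, "sim_params"), inherits(program, "pcr_program"))
  if (!inherits(reference, "reference_genotype")) {
    reference <- reference_genotype(reference)
  }
  if (!"size_bp" %in% names(reference)) {
    abort("reference genotype needs a size_bp column for simulation",
          class = "smartpcr_format_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(reference)
  plateau_share <- .deterministic_plateau(params, program) / params$f_sat
  copies <- params$template_pg / 6.6 # one homolog per allele position
  mean_height <- params$h_cap * plateau_share *
    params$template_pg / (params$template_pg + params$template_half_pg)
  s <- if (params$height_noise_sd == 0 || copies <= 0) 0 else
    params$height_noise_sd * copies^(-0.2)
  size_factor <- exp(-params$degradation_k *
                       (reference$size_bp - params$size_ref_bp))
  noise <- if (s == 0) rep(1, n) else rlnorm(n, -s^2 / 2, s)
  heights <- mean_height * size_factor * noise
  keep <- heights >= params$dropout_floor_rfu & heights > 0
  peaks <- tibble::tibble(
    locus = reference$locus[keep],
    allele = reference$allele[keep],
    size_bp = reference$size_bp[keep],
    height_rfu = heights[keep],
    dye = if ("dye" %in% names(reference)) reference$dye[keep]
          else NA_character_,
    artefact = FALSE
  )
  str_profile(sample, peaks, reference = reference)
}
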