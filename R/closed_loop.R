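#' Device contract for cycle-by-cycle PCR control
#'
#' A controllable thermocycler backend is any object of class `pcr_device`
#' implementing the five generics below. The contract mirrors the control
#' surface of an open qPCR instrument driven over its API: a program must be
#' defined before starting, cycles are run in short segments (the workaround
#' for instruments that cannot edit a running program), and fetching after
#' cycle k returns the readings for all cycles up to k. The built-in
#' simulator backend is [sim_device()]; an HTTP instrument adapter would
#' implement the same five methods.
#'
#' @param device A `pcr_device`.
#' @param program A [pcr_program()] (or segment thereof) whose first cycled
#'   stage supplies the step parameters for subsequently run cycles.
#' @param n Number of cycles to run before returning.
#' @return `device_fetch()` returns a tibble (`cycle`, `fluorescence`,
#'   `anneal_seconds`, `anneal_temp_c`); the others return the device,
#'   invisibly.
#' @name pcr_device
NULL

#' @rdname pcr_device
#' @export
device_define_program <- function(device, program) {
  UseMethod("device_define_program")
}

#' @rdname pcr_device
#' @export
device_start <- function(device) UseMethod("device_start")

#' @rdname pcr_device
#' @export
device_run_cycles <- function(device, n = 1) UseMethod("device_run_cycles")

#' @rdname pcr_device
#' @export
device_fetch <- function(device) UseMethod("device_fetch")

#' @rdname pcr_device
#' @export
device_stop <- function(device) UseMethod("device_stop")

#' Simulated qPCR device backend
#'
#' Wraps the kinetics of [simulate_qpcr()] behind the [pcr_device] contract
#' so the closed-loop controller can be exercised without hardware. The
#' device keeps its own RNG stream, so a closed-loop run under a fixed seed
#' reproduces the open-loop [simulate_qpcr()] trajectory exactly when the
#' per-cycle parameters match.
#'
#' @param params A [sim_params()].
#' @param seed RNG seed for the device's private stream.
#' @param fail_after_cycle Optional cycle index after which the device
#'   raises an error (for testing fault handling).
#' @return An environment of class `c("sim_device", "pcr_device")`.
#' @export
sim_device <- function(params, seed = params$seed, fail_after_cycle = Inf) {
  stopifnot(inherits(params, "sim_params"))
  dev <- new.env(parent = emptyenv())
  dev$params <- params
  dev$fail_after_cycle <- fail_after_cycle
  dev$steps <- NULL
  dev$started <- FALSE
  dev$cycle <- 0L
  dev$f <- params$f0_per_pg * params$template_pg
  dev$readings <- tibble::tibble(cycle = integer(), fluorescence = numeric(),
                                 anneal_seconds = numeric(),
                                 anneal_temp_c = numeric())
  # private RNG stream, isolated from the session RNG
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed) else set.seed(sample.int(.Machine$integer.max, 1))
  dev$rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(dev) <- c("sim_device", "pcr_device")
  dev
}

#' @export
device_define_program.sim_device <- function(device, program) {
  stopifnot(inherits(program, "pcr_program"))
  device$steps <- program$stages[[1]]$steps
  invisible(device)
}

#' @export
device_start.sim_device <- function(device) {
  if (is.null(device$steps)) {
    abort("define a program before starting the device",
          class = "smartpcr_device_error")
  }
  device$started <- TRUE
  invisible(device)
}

#' @export
device_run_cycles.sim_device <- function(device, n = 1) {
  if (!isTRUE(device$started)) {
    abort("device not started", class = "smartpcr_device_error")
  }
  params <- device$params
  anneal <- purrr::detect(device$steps, ~ .x$label == "anneal_extend")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", device$rng, globalenv())
  on.exit({
    device$rng <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  for (k in seq_len(n)) {
    device$cycle <- device$cycle + 1L
    if (device$cycle > device$fail_after_cycle) {
      abort("device fault: lost contact with instrument",
            class = "smartpcr_device_error")
    }
    if (is.null(anneal)) {
      secs <- NA_real_; temp <- NA_real_; eff <- 0
    } else {
      secs <- step_duration_at_cycle(anneal, device$cycle)
      temp <- anneal$temperature_c
      eff <- .efficiency_num(params, secs, temp)
    }
    z <- rnorm(1)
    device$f <- .qpcr_advance(device$f, eff, params, z)
    device$readings <- dplyr::bind_rows(
      device$readings,
      tibble::tibble(cycle = device$cycle, fluorescence = device$f,
                     anneal_seconds = secs, anneal_temp_c = temp)
    )
  }
  invisible(device)
}

#' @export
device_fetch.sim_device <- function(device) device$readings

#' @export
device_stop.sim_device <- function(device) {
  device$started <- FALSE
  invisible(device)
}

#' Early-termination criteria for a closed-loop run
#'
#' Three mutually exclusive reasons to stop before the cycle budget:
#' sufficiency (the signal already exceeds `max_amount_rfu`; checked first),
#' undetectability (still below `detect_threshold_rfu` at or after
#' `min_detect_cycle`), and low rate (detected, but the per-cycle increase
#' has fallen below `min_rate`). Use [no_termination()] to run a fixed
#' number of cycles open-loop style.
#'
#' @param min_detect_cycle Cycle by which the signal must be detectable.
#' @param detect_threshold_rfu Detection threshold (RFU).
#' @param min_rate Minimum per-cycle fluorescence increase once detected
#'   (0 disables the low-rate rule).
#' @param max_amount_rfu Sufficiency ceiling (RFU).
#' @param max_cycles Cycle budget, >= 1.
#' @param rate_window Number of trailing readings in the least-squares rate
#'   estimate.
#' @return A list of class `termination_criteria`.
#' @export
termination_criteria <- function(min_detect_cycle = 16,
                                 detect_threshold_rfu = 500,
                                 min_rate = 0,
                                 max_amount_rfu = 5000,
                                 max_cycles = 40,
                                 rate_window = 3) {
  stopifnot(min_detect_cycle >= 1, detect_threshold_rfu >= 0, min_rate >= 0,
            max_amount_rfu >= 0, max_cycles >= 1, rate_window >= 2)
  structure(
    list(min_detect_cycle = min_detect_cycle,
         detect_threshold_rfu = detect_threshold_rfu,
         min_rate = min_rate, max_amount_rfu = max_amount_rfu,
         max_cycles = max_cycles, rate_window = rate_window),
    class = "termination_criteria"
  )
}

#' @rdname termination_criteria
#' @export
no_termination <- function(max_cycles = 40) {
  termination_criteria(min_detect_cycle = Inf, detect_threshold_rfu = 0,
                       min_rate = 0, max_amount_rfu = Inf,
                       max_cycles = max_cycles)
}

#' Termination decision for the current loop state
#'
#' @param state List with `cycle` (index of the last completed cycle),
#'   `fluorescence` (latest reading) and `rate` (trailing per-cycle
#'   increase).
#' @param criteria A [termination_criteria()].
#' @return One of `"continue"`, `"terminated_sufficient"`,
#'   `"terminated_undetectable"`, `"terminated_low_rate"`.
#' @export
check_termination <- function(state, criteria) {
  stopifnot(inherits(criteria, "termination_criteria"))
  f <- state$fluorescence
  if (f > criteria$max_amount_rfu) return("terminated_sufficient")
  detected <- f >= criteria$detect_threshold_rfu
  if (!detected && state$cycle >= criteria$min_detect_cycle) {
    return("terminated_undetectable")
  }
  if (detected && criteria$min_rate > 0 &&
      is.finite(state$rate) && state$rate < criteria$min_rate) {
    return("terminated_low_rate")
  }
  "continue"
}

#' Rule bank of open-loop experience
#'
#' The closed-loop policy consults a bank of `(condition, parameters,
#' metric-increase-rate)` entries recorded during open-loop optimisation:
#' the fluorescence level at which a condition was observed, the cycling
#' parameters that were used, and the per-cycle rate of increase of the
#' quality metric they produced.
#'
#' @param condition_rfu Fluorescence level of each recorded condition.
#' @param metric_rate Observed per-cycle increase of the scoring metric.
#' @param ... Parameter columns (e.g. `anneal_seconds = c(...)`).
#' @return A tibble of class `rule_bank`.
#' @export
rule_bank <- function(condition_rfu, metric_rate, ...) {
  out <- tibble::tibble(condition_rfu = condition_rfu, ...,
                        metric_rate = metric_rate)
  stopifnot(all(is.finite(out$metric_rate)), all(out$condition_rfu >= 0))
  class(out) <- c("rule_bank", class(out))
  out
}

#' Nearest-condition parameter policy
#'
#' Among the bank entries whose condition is closest to the observed
#' fluorescence (absolute difference on the log10 scale, since amplification
#' spans orders of magnitude; ties all retained), returns the parameters of
#' the entry with the highest metric-increase rate, breaking remaining ties
#' by entry order.
#'
#' @param bank A [rule_bank()].
#' @param observed_rfu Observed fluorescence level.
#' @return One-row tibble of the winning entry's parameter columns.
#' @export
nearest_condition_policy <- function(bank, observed_rfu) {
  if (!inherits(bank, "rule_bank")) bank <- rule_bank_from_df(bank)
  if (nrow(bank) == 0) {
    abort("rule bank is empty", class = "smartpcr_domain_error")
  }
  lg <- function(x) log10(pmax(x, 1)) # flatten sub-RFU noise to one point
  d <- abs(lg(bank$condition_rfu) - lg(observed_rfu))
  nearest <- which(d <= min(d) + 1e-12)
  winner <- nearest[which.max(bank$metric_rate[nearest])]
  bank[winner, setdiff(names(bank), c("condition_rfu", "metric_rate")),
       drop = FALSE]
}

rule_bank_from_df <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("condition_rfu", "metric_rate") %in% names(df)))
  class(df) <- c("rule_bank", class(df))
  df
}

# least-squares slope of the last `window` readings
.trailing_rate <- function(fluor, window) {
  n <- length(fluor)
  if (n < 2) return(Inf)
  k <- min(window, n)
  y <- fluor[(n - k + 1):n]
  x <- seq_len(k)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Run the closed-loop controller
#'
#' Implements the segment-wise control sequence: define the program, run an
#' initial uninterrupted block of cycles (instruments cannot detect anything
#' useful before the signal clears the noise floor), then alternate short
#' segments with feedback: fetch the amplification data, check the
#' termination criteria, consult the policy for the next segment's
#' parameters (clipped to the declared bounds), redefine and continue. Ends
#' when a termination rule fires or `max_cycles` is reached, and returns the
#' full per-cycle log. A device fault mid-run aborts with the partial record
#' preserved and status `"device_fault"`.
#'
#' @param device A [pcr_device] backend, e.g. [sim_device()].
#' @param program_template A [pcr_program()] supplying the default step
#'   parameters; the policy overrides the anneal/extend duration per
#'   segment.
#' @param criteria A [termination_criteria()].
#' @param bank Optional [rule_bank()] driving the default
#'   [nearest_condition_policy()].
#' @param policy Optional function `(state, bank)` returning a one-row data
#'   frame with an `anneal_seconds` column (or `NULL` to keep the template
#'   parameters). Defaults to the nearest-condition policy when `bank` is
#'   given, otherwise to fixed template parameters.
#' @param initial_block_cycles Cycles run before the first intervention.
#' @param segment_cycles Cycles per feedback segment (1 or 2 on real
#'   instruments).
#' @param param_bounds Optional tibble (`parameter`, `lower`, `upper`)
#'   used to clip policy outputs; the controller never issues parameters
#'   outside these bounds.
#' @return A list of class `loop_record`: `record` (tibble with one row per
#'   executed cycle: `cycle`, `anneal_seconds`, `anneal_temp_c`,
#'   `fluorescence`, `decision`), `status`, and `criteria`.
#' @export
run_closed_loop <- function(device, program_template, criteria,
                            bank = NULL, policy = NULL,
                            initial_block_cycles = 16, segment_cycles = 1,
                            param_bounds = NULL) {
  stopifnot(inherits(device, "pcr_device"),
            inherits(program_template, "pcr_program"),
            inherits(criteria, "termination_criteria"),
            initial_block_cycles >= 1, segment_cycles >= 1)
  if (is.null(policy) && !is.null(bank)) {
    policy <- function(state, bank) nearest_condition_policy(bank, state$fluorescence)
  }
  template_anneal <- purrr::detect(program_template$stages[[1]]$steps,
                                   ~ .x$label == "anneal_extend")
  clip <- function(value, parameter) {
    if (is.null(param_bounds)) return(value)
    b <- param_bounds[param_bounds$parameter == parameter, ]
    if (nrow(b) == 0) return(value)
    min(max(value, b$lower[1]), b$upper[1])
  }
  segment_program <- function(anneal_seconds) {
    steps <- purrr::map(program_template$stages[[1]]$steps, function(s) {
      if (s$label == "anneal_extend") {
        cycling_step("anneal_extend", s$temperature_c,
                     clip(anneal_seconds, "anneal_seconds"),
                     s$increment_seconds_per_cycle)
      } else s
    })
    pcr_program(list(list(cycles = 1, steps = steps)),
                name = program_template$name)
  }

  device_define_program(device, program_template)
  device_start(device)
  decisions <- character(0)
  status <- NULL

  fetch_state <- function() {
    readings <- device_fetch(device)
    list(cycle = nrow(readings),
         fluorescence = readings$fluorescence[nrow(readings)],
         rate = .trailing_rate(readings$fluorescence, criteria$rate_window),
         readings = readings)
  }

  result <- tryCatch({
    block <- min(initial_block_cycles, criteria$max_cycles)
    device_run_cycles(device, block)
    state <- fetch_state()
    decision <- check_termination(state, criteria)
    decisions <- c(rep("continue", state$cycle - 1L), decision)
    while (decision == "continue" && state$cycle < criteria$max_cycles) {
      if (!is.null(policy)) {
        next_params <- policy(state, bank)
        if (!is.null(next_params) && "anneal_seconds" %in% names(next_params)) {
          device_define_program(device,
                                segment_program(next_params$anneal_seconds[1]))
        }
      }
      n_run <- min(segment_cycles, criteria$max_cycles - state$cycle)
      device_run_cycles(device, n_run)
      state <- fetch_state()
      decision <- check_termination(state, criteria)
      decisions <- c(decisions, rep("continue", n_run - 1L), decision)
    }
    status <- if (decision == "continue") "completed" else decision
    list(readings = state$readings, status = status)
  }, smartpcr_device_error = function(e) {
    list(readings = device_fetch(device), status = "device_fault",
         fault = conditionMessage(e))
  })

  device_stop(device)
  readings <- result$readings
  n <- nrow(readings)
  decisions <- c(decisions, rep("continue", max(0, n - length(decisions))))
  record <- dplyr::mutate(readings[seq_len(n), ],
                          decision = decisions[seq_len(n)])
  structure(
    list(record = record, status = result$status,
         fault = result$fault %||% NA_character_, criteria = criteria),
    class = "loop_record"
  )
}

#' @export
print.loop_record <- function(x, ...) {
  cat("<loop_record>", nrow(x$record), "cycles, status:", x$status, "\n")
  print(x$record, ...)
  invisible(x)
}

#' @export
tidy.loop_record <- function(x, ...) x$record

#' @export
glance.loop_record <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    cycles = nrow(x$record),
    final_fluorescence = if (nrow(x$record) > 0)
      x$record$fluorescence[nrow(x$record)] else NA_real_
  )
}

#' Write a loop record as CSV plus a JSON-ready summary
#' @param x A `loop_record`.
#' @param file CSV path for the per-cycle record.
#' @return The summary list (status, cycles, final fluorescence), invisibly.
#' @export
write_loop_record <- function(x, file) {
  stopifnot(inherits(x, "loop_record"))
  readr::write_csv(x$record, file)
  invisible(as.list(glance(x)))
}

#' Plot a closed-loop run
#' @param object A `loop_record`.
#' @param ... Unused.
#' @return A ggplot of the fluorescence trajectory, coloured by the
#'   controller's decision, with the anneal schedule beneath.
#' @export
autoplot.loop_record <- function(object, ...) {
  ggplot2::ggplot(object$record,
                  ggplot2::aes(x = .data$cycle, y = .data$fluorescence,
                               colour = .data$decision)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "fluorescence (RFU)",
                  title = paste("closed-loop run:", object$status))
}
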