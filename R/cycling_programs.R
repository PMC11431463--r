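#' A single thermocycler step
#'
#' A cycled step with a temperature, a base duration at cycle 1 and an
#' optional additive per-cycle ramp (e.g. the modified GlobalFiler anneal
#' step: 60 s + 1.56 s per cycle). The ramp applies from cycle 2: the base
#' duration is the printed cycle-1 value.
#'
#' @param label One of `"denature"`, `"anneal_extend"`, `"other"`. Only
#'   denature and anneal/extend steps count towards [cycling_time_minutes()].
#' @param temperature_c Step temperature in degrees Celsius.
#' @param base_seconds Duration at cycle 1, >= 0.
#' @param increment_seconds_per_cycle Additive ramp per cycle (0 = fixed).
#' @param temp_range Allowed instrument temperature range.
#' @return A list of class `cycling_step`.
#' @export
cycling_step <- function(label = c("denature", "anneal_extend", "other"),
                         temperature_c, base_seconds,
                         increment_seconds_per_cycle = 0,
                         temp_range = c(4, 100)) {
  label <- match.arg(label)
  stopifnot(base_seconds >= 0, length(temperature_c) == 1L)
  if (temperature_c < temp_range[1] || temperature_c > temp_range[2]) {
    abort(sprintf("temperature %.1f C outside instrument range [%g, %g]",
                  temperature_c, temp_range[1], temp_range[2]),
          class = "smartpcr_domain_error")
  }
  structure(
    list(label = label, temperature_c = temperature_c,
         base_seconds = base_seconds,
         increment_seconds_per_cycle = increment_seconds_per_cycle),
    class = "cycling_step"
  )
}

#' Duration of a cycled step at a given cycle
#'
#' `base_seconds + increment_seconds_per_cycle * (cycle_index - 1)`.
#'
#' @param step A [cycling_step()].
#' @param cycle_index Cycle number within the stage, >= 1.
#' @return Duration in seconds.
#' @examples
#' ramp <- cycling_step("anneal_extend", 59, 60, 1.56)
#' step_duration_at_cycle(ramp, 1)  # 60
#' step_duration_at_cycle(ramp, 30) # 105.24
#' @export
step_duration_at_cycle <- function(step, cycle_index) {
  stopifnot(inherits(step, "cycling_step"), all(cycle_index >= 1))
  d <- step$base_seconds +
    step$increment_seconds_per_cycle * (cycle_index - 1)
  if (any(d < 0)) {
    abort("step duration is negative at the requested cycle",
          class = "smartpcr_domain_error")
  }
  d
}

#' A complete PCR program
#'
#' Initial holds, one or more cycled stages (each an ordered step list run
#' for a fixed number of cycles) and final holds. Stage cycle indices are
#' local to the stage, so a ramped step restarts from its base duration in a
#' new stage.
#'
#' @param stages List of stages; each stage is `list(cycles = n, steps =
#'   list(<cycling_step>, ...))` with `cycles >= 1`.
#' @param initial_holds,final_holds Optional data frames (or lists coercible
#'   to them) with columns `temperature_c`, `seconds`.
#' @param name Optional program name.
#' @return A list of class `pcr_program`.
#' @export
pcr_program <- function(stages, initial_holds = NULL, final_holds = NULL,
                        name = NULL) {
  as_holds <- function(h) {
    if (is.null(h)) return(tibble::tibble(temperature_c = numeric(),
                                          seconds = numeric()))
    tibble::as_tibble(h)[c("temperature_c", "seconds")]
  }
  stopifnot(is.list(stages), length(stages) >= 1)
  for (st in stages) {
    stopifnot(is.numeric(st$cycles), st$cycles >= 1,
              length(st$steps) >= 1)
    for (s in st$steps) stopifnot(inherits(s, "cycling_step"))
  }
  structure(
    list(name = name, initial_holds = as_holds(initial_holds),
         stages = stages, final_holds = as_holds(final_holds)),
    class = "pcr_program"
  )
}

#' @export
print.pcr_program <- function(x, ...) {
  cat("<pcr_program>", x$name %||% "", "\n")
  for (i in seq_len(nrow(x$initial_holds))) {
    cat(sprintf("  hold: %g C, %g s\n", x$initial_holds$temperature_c[i],
                x$initial_holds$seconds[i]))
  }
  for (st in x$stages) {
    cat(sprintf("  stage x%d cycles:\n", st$cycles))
    for (s in st$steps) {
      cat(sprintf("    %s: %g C, %g s%s\n", s$label, s$temperature_c,
                  s$base_seconds,
                  if (s$increment_seconds_per_cycle != 0)
                    sprintf(" (%+g s per cycle)",
                            s$increment_seconds_per_cycle) else ""))
    }
  }
  for (i in seq_len(nrow(x$final_holds))) {
    cat(sprintf("  hold: %g C, %g s\n", x$final_holds$temperature_c[i],
                x$final_holds$seconds[i]))
  }
  invisible(x)
}

#' Per-cycle step schedule of a program
#'
#' Expands the cycled stages into one row per (global cycle, step) with the
#' ramped duration resolved, the view both the simulator and the duration
#' accounting consume.
#'
#' @param program A [pcr_program()].
#' @return Tibble: `cycle` (global index), `stage`, `label`,
#'   `temperature_c`, `seconds`.
#' @export
program_schedule <- function(program) {
  stopifnot(inherits(program, "pcr_program"))
  offset <- 0L
  rows <- purrr::imap(program$stages, function(st, i) {
    local_cycles <- seq_len(st$cycles)
    out <- purrr::map(st$steps, function(s) {
      tibble::tibble(
        cycle = offset + local_cycles,
        stage = i,
        label = s$label,
        temperature_c = s$temperature_c,
        seconds = step_duration_at_cycle(s, local_cycles)
      )
    }) |> dplyr::bind_rows()
    offset <<- offset + as.integer(st$cycles)
    out
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$cycle, .data$stage)
}

#' Total denature + anneal cycling time
#'
#' The duration term of the quality metric: the summed durations of the
#' denature and anneal/extend steps over every cycle of every stage, in
#' minutes. Holds (and `"other"` steps) are excluded, as are between-step
#' temperature transitions.
#'
#' @param program A [pcr_program()].
#' @return Minutes (numeric scalar).
#' @examples
#' std <- load_program_fixture("globalfiler_standard")
#' cycling_time_minutes(std) # 30 * (10 + 90) / 60 = 50
#' @export
cycling_time_minutes <- function(program) {
  sched <- program_schedule(program)
  sum(sched$seconds[sched$label %in% c("denature", "anneal_extend")]) / 60
}

#' Build a program from a configuration mapping
#'
#' The config mirrors the YAML layout of the packaged fixtures:
#' `name`, `initial_holds`/`final_holds` (lists of `{temperature_c,
#' seconds}`), and `stages` (lists of `{cycles, steps: [{label,
#' temperature_c, base_seconds, increment_seconds_per_cycle}]}`).
#'
#' @param config A named list (e.g. from [yaml::read_yaml()]).
#' @return A [pcr_program()].
#' @export
build_program <- function(config) {
  holds <- function(h) {
    if (is.null(h) || length(h) == 0) return(NULL)
    dplyr::bind_rows(purrr::map(h, tibble::as_tibble))
  }
  known <- c("denature", "anneal_extend", "other")
  stages <- purrr::map(config$stages, function(st) {
    steps <- purrr::map(st$steps, function(s) {
      if (is.null(s$label) || !s$label %in% known) {
        abort(paste0("unknown step label: ",
                     s$label %||% "<missing>"),
              class = "smartpcr_format_error")
      }
      cycling_step(s$label, s$temperature_c, s$base_seconds,
                   s$increment_seconds_per_cycle %||% 0)
    })
    list(cycles = st$cycles, steps = steps)
  })
  pcr_program(stages, initial_holds = holds(config$initial_holds),
              final_holds = holds(config$final_holds),
              name = config$name)
}

#' Serialize a program back to a configuration mapping
#'
#' Inverse of [build_program()]: `build_program(serialize_program(p))` is
#' identical to `p`.
#'
#' @param program A [pcr_program()].
#' @return A named list suitable for [yaml::write_yaml()].
#' @export
serialize_program <- function(program) {
  stopifnot(inherits(program, "pcr_program"))
  holds <- function(h) {
    if (nrow(h) == 0) return(NULL)
    purrr::pmap(h, function(temperature_c, seconds) {
      list(temperature_c = temperature_c, seconds = seconds)
    })
  }
  out <- list(
    name = program$name,
    initial_holds = holds(program$initial_holds),
    stages = purrr::map(program$stages, function(st) {
      list(cycles = st$cycles, steps = purrr::map(st$steps, function(s) {
        list(label = s$label, temperature_c = s$temperature_c,
             base_seconds = s$base_seconds,
             increment_seconds_per_cycle = s$increment_seconds_per_cycle)
      }))
    }),
    final_holds = holds(program$final_holds)
  )
  out[!purrr::map_lgl(out, is.null)]
}

#' Read / write program YAML files
#' @param file Path to a YAML program config.
#' @return [read_program()]: a [pcr_program()].
#' @export
read_program <- function(file) build_program(yaml::read_yaml(file))

#' @rdname read_program
#' @param program A [pcr_program()].
#' @export
write_program <- function(program, file) {
  yaml::write_yaml(serialize_program(program), file)
  invisible(file)
}

#' Packaged cycling-program fixtures
#'
#' YAML configs for the endpoint-PCR and qPCR programs the framework was
#' exercised with: the standard 30-cycle GlobalFiler protocol and its
#' ramped-anneal modification, their 16-cycle qPCR-primed variants, and the
#' Quantiplex Pro qPCR series with annealing/extension times of 10 (standard),
#' 30, 50, 70 and 90 s in the final 24 of 40 cycles.
#'
#' @param name Fixture name; see [list_program_fixtures()].
#' @return A [pcr_program()].
#' @export
load_program_fixture <- function(name) {
  path <- system.file("extdata", "programs", paste0(name, ".yaml"),
                      package = "smartpcr")
  if (path == "") {
    abort(paste0("no packaged program named '", name, "'; see ",
                 "list_program_fixtures()"),
          class = "smartpcr_format_error")
  }
  read_program(path)
}

#' @rdname load_program_fixture
#' @export
list_program_fixtures <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "programs", package = "smartpcr"),
                 pattern = "\\.yaml$"))
}
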