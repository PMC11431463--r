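#' Construct a per-cycle amplification curve
#'
#' A tidy container for real-time fluorescence data from one well and
#' channel: one row per reading, with `x` either the cycle index or elapsed
#' minutes (`x_axis` records which).
#'
#' @param x Strictly increasing cycle indices or elapsed minutes.
#' @param fluorescence Fluorescence readings (RFU), same length as `x`.
#' @param well,channel Well and channel identifiers.
#' @param x_axis `"cycle"` or `"minutes"`.
#' @return A tibble of class `amp_curve` with columns `well`, `channel`,
#'   `x`, `fluorescence` and attributes `x_axis`, `baselined`.
#' @export
amp_curve <- function(x, fluorescence, well = "A1", channel = 1L,
                      x_axis = c("cycle", "minutes")) {
  x_axis <- match.arg(x_axis)
  stopifnot(length(x) == length(fluorescence), length(x) > 0)
  if (any(diff(x) <= 0)) {
    abort("x must be strictly increasing", class = "smartpcr_domain_error")
  }
  out <- tibble::tibble(well = well, channel = channel, x = as.numeric(x),
                        fluorescence = as.numeric(fluorescence))
  attr(out, "x_axis") <- x_axis
  attr(out, "baselined") <- FALSE
  class(out) <- c("amp_curve", class(out))
  out
}

.as_amp_curve <- function(df, template) {
  attr(df, "x_axis") <- attr(template, "x_axis")
  attr(df, "baselined") <- attr(template, "baselined")
  if (!inherits(df, "amp_curve")) class(df) <- c("amp_curve", class(df))
  df
}

#' Baseline subtraction
#'
#' Subtracts the median fluorescence of the first `n_baseline_cycles`
#' readings from every reading, the standard pre-processing before sigmoid
#' fitting. Idempotent: the median of the corrected baseline window is 0.
#'
#' @param curve An [amp_curve()].
#' @param n_baseline_cycles Number of leading readings defining the baseline
#'   (default 16).
#' @return The baseline-corrected curve (`baselined` attribute set).
#' @export
baseline_subtract <- function(curve, n_baseline_cycles = 16) {
  stopifnot(inherits(curve, "amp_curve"), n_baseline_cycles >= 1)
  if (nrow(curve) < n_baseline_cycles) {
    abort(sprintf("curve has %d readings, fewer than the %d baseline cycles",
                  nrow(curve), n_baseline_cycles),
          class = "smartpcr_domain_error")
  }
  base <- median(curve$fluorescence[seq_len(n_baseline_cycles)])
  out <- dplyr::mutate(curve, fluorescence = .data$fluorescence - base)
  out <- .as_amp_curve(out, curve)
  attr(out, "baselined") <- TRUE
  out
}

#' Evaluate the tanh sigmoid model
#'
#' `y = A * (1 + tanh(B * (x - C_mid))) / 2`: a logistic-type amplification
#' curve with plateau amplitude `A`, gradient `B` and midpoint `C_mid` (the x
#' at which the fluorescence reaches A/2).
#'
#' @param A Plateau amplitude (RFU).
#' @param B Gradient of the response.
#' @param C_mid Midpoint, in the same units as `x`.
#' @param x Cycle indices or elapsed minutes (vectorised).
#' @return Modelled fluorescence.
#' @export
eval_tanh <- function(A, B, C_mid, x) {
  A * (1 + tanh(B * (x - C_mid))) / 2
}

#' Fit the tanh sigmoid to a baseline-subtracted curve
#'
#' Least-squares estimation of `(A, B, C_mid)` with data-derived starting
#' values (`A` from the maximum reading, `C_mid` from the half-maximum
#' crossing, `B` from the 10--90% rise width). Fitting uses
#' Levenberg--Marquardt ([minpack.lm::nlsLM()]); if that fails, a
#' Nelder--Mead polish of the residual sum of squares is attempted and the
#' `converged` flag reports the outcome honestly. A flat curve returns
#' `A = 0` with `converged = FALSE` rather than an error.
#'
#' @param curve An [amp_curve()], normally after [baseline_subtract()], with
#'   at least 4 readings.
#' @return A list of class `tanh_fit`: `A`, `B`, `C_mid`, `rss`,
#'   `converged`, `n`, and the fitted data in `$data`.
#' @export
fit_tanh <- function(curve) {
  stopifnot(inherits(curve, "amp_curve"))
  x <- curve$x
  y <- curve$fluorescence
  if (length(x) < 4) {
    abort("at least 4 readings are required to fit the sigmoid",
          class = "smartpcr_domain_error")
  }
  out <- list(A = NA_real_, B = NA_real_, C_mid = NA_real_,
              rss = NA_real_, converged = FALSE, n = length(x),
              x_axis = attr(curve, "x_axis"), data = curve)
  class(out) <- "tanh_fit"

  a0 <- max(y)
  if (a0 <= 0 || (max(y) - min(y)) < .Machine$double.eps^0.5 * max(abs(y), 1)) {
    out$A <- max(0, a0)
    out$B <- 0
    out$rss <- sum((y - mean(y))^2)
    return(out)
  }
  cross_x <- function(level) {
    i <- which(y >= level)[1]
    if (is.na(i)) return(max(x))
    if (i == 1L) return(x[1])
    x[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
  }
  c0 <- cross_x(a0 / 2)
  width <- max(cross_x(0.9 * a0) - cross_x(0.1 * a0), diff(range(x)) / 50)
  b0 <- 4.4 / width # tanh rises 10-90% over ~4.4/B in x

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 + tanh(B * (x - C))) / 2,
      start = list(A = a0, B = b0, C = c0),
      data = data.frame(x = x, y = y),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    out$A <- unname(cf["A"])
    out$B <- unname(cf["B"])
    out$C_mid <- unname(cf["C"])
    out$rss <- sum(residuals(fit)^2)
    out$converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(cf))
    return(out)
  }
  rss_fn <- function(p) sum((y - eval_tanh(p[1], p[2], p[3], x))^2)
  opt <- optim(c(a0, b0, c0), rss_fn, method = "Nelder-Mead",
               control = list(maxit = 2000))
  out$A <- opt$par[1]
  out$B <- opt$par[2]
  out$C_mid <- opt$par[3]
  out$rss <- opt$value
  out$converged <- opt$convergence == 0
  out
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat(sprintf(
    "<tanh_fit> A = %.4g RFU, B = %.4g, C_mid = %.4g (%s), rss = %.4g, %s\n",
    x$A, x$B, x$C_mid, x$x_axis %||% "cycle", x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.tanh_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C_mid"),
                 estimate = c(x$A, x$B, x$C_mid))
}

#' @export
glance.tanh_fit <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, C_mid = x$C_mid, rss = x$rss,
                 converged = x$converged, n = x$n)
}

#' Threshold-crossing point (Ct)
#'
#' First `x` at which the (baseline-subtracted) fluorescence reaches the
#' detection threshold, linearly interpolated between the bracketing
#' readings. If the first reading already meets the threshold its `x` is
#' returned; if the curve never reaches it, `NA`.
#'
#' @param curve An [amp_curve()].
#' @param threshold_rfu Detection threshold (default 500 RFU).
#' @return The crossing point (cycle or minutes), or `NA_real_`.
#' @export
ct_cycle <- function(curve, threshold_rfu = 500) {
  stopifnot(inherits(curve, "amp_curve"))
  y <- curve$fluorescence
  x <- curve$x
  i <- which(y >= threshold_rfu)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(x[1])
  x[i - 1] + (threshold_rfu - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

#' Pointwise average of replicate curves
#'
#' @param curves List of [amp_curve()] objects sharing the same x grid.
#' @return An [amp_curve()] whose fluorescence is the arithmetic mean of the
#'   replicates at each x.
#' @export
average_replicates <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  x0 <- curves[[1]]$x
  for (cv in curves) {
    stopifnot(inherits(cv, "amp_curve"))
    if (length(cv$x) != length(x0) || any(cv$x != x0)) {
      abort("replicate curves must share an identical x grid",
            class = "smartpcr_domain_error")
    }
  }
  y <- rowMeans(do.call(cbind, purrr::map(curves, "fluorescence")))
  out <- amp_curve(x0, y, well = "avg", channel = curves[[1]]$channel[1],
                   x_axis = attr(curves[[1]], "x_axis"))
  attr(out, "baselined") <- attr(curves[[1]], "baselined")
  out
}

#' Read / write long-format amplification tables
#'
#' CSV with columns `well`, `channel`, `cycle` (or `minutes`) and
#' `fluorescence`; one [amp_curve()] per well x channel.
#'
#' @param file CSV path.
#' @return [read_amp_table()]: a list of [amp_curve()] objects.
#' @export
read_amp_table <- function(file) {
  d <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  x_axis <- if ("minutes" %in% names(d)) "minutes" else "cycle"
  xcol <- if (x_axis == "minutes") "minutes" else "cycle"
  stopifnot(all(c("well", "channel", xcol, "fluorescence") %in% names(d)))
  d |>
    dplyr::group_by(.data$well, .data$channel) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      g <- dplyr::arrange(g, .data[[xcol]])
      amp_curve(g[[xcol]], g$fluorescence, well = g$well[1],
                channel = g$channel[1], x_axis = x_axis)
    })
}

#' @rdname read_amp_table
#' @param curves A list of [amp_curve()] objects (or a single one).
#' @export
write_amp_table <- function(curves, file) {
  if (inherits(curves, "amp_curve")) curves <- list(curves)
  x_axis <- attr(curves[[1]], "x_axis")
  tab <- dplyr::bind_rows(purrr::map(curves, tibble::as_tibble))
  names(tab)[names(tab) == "x"] <- if (x_axis == "minutes") "minutes" else "cycle"
  readr::write_csv(tab, file)
  invisible(file)
}

#' Plot an amplification curve, optionally with its fitted sigmoid
#' @param object An [amp_curve()].
#' @param fit Optional `tanh_fit` overlaid as a smooth line.
#' @param threshold_rfu Optional detection threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amp_curve <- function(object, fit = NULL, threshold_rfu = NULL,
                               ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x,
                                            y = .data$fluorescence)) +
    ggplot2::geom_point(shape = 4) +
    ggplot2::labs(
      x = if (identical(attr(object, "x_axis"), "minutes"))
        "run time (min)" else "cycle",
      y = "fluorescence (RFU)")
  if (!is.null(fit)) {
    grid <- tibble::tibble(x = seq(min(object$x), max(object$x),
                                   length.out = 200))
    grid$fluorescence <- eval_tanh(fit$A, fit$B, fit$C_mid, grid$x)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  if (!is.null(threshold_rfu)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_rfu,
                                 linetype = "dashed")
  }
  p
}
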