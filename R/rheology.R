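#' Temperature-sweep gelation curve
#'
#' A thermoreversible polymer sweep: response (storage modulus G', or a
#' pre-normalized gelation fraction) versus temperature. The sol-gel
#' transition appears as a sigmoidal rise; the half-gelation temperature is
#' the midpoint of that rise.
#'
#' @param temperature_c strictly increasing temperatures in degrees C
#'   (at least 6 points).
#' @param response non-negative responses, same length.
#' @return object of class `gelation_curve`.
#' @export
gelation_curve <- function(temperature_c, response) {
  if (length(temperature_c) < 6 || length(response) != length(temperature_c)) {
    stop_mucoscape("mucoscape_validation_error",
                   "need >= 6 (temperature, response) pairs of equal length")
  }
  if (any(diff(temperature_c) <= 0)) {
    stop_mucoscape("mucoscape_validation_error",
                   "temperatures must be strictly increasing")
  }
  if (any(!is.finite(temperature_c)) || any(!is.finite(response)) || any(response < 0)) {
    stop_mucoscape("mucoscape_validation_error",
                   "responses must be finite and non-negative")
  }
  structure(list(temperature_c = as.numeric(temperature_c),
                 response = as.numeric(response)),
            class = "gelation_curve")
}

#' Min-max normalization of a gelation curve
#' @param curve a [gelation_curve()].
#' @return a [gelation_curve()] with response scaled to `[0, 1]`.
#' @export
normalize_gelation <- function(curve) {
  stopifnot(inherits(curve, "gelation_curve"))
  r <- curve$response
  rng <- range(r)
  if (diff(rng) == 0) {
    stop_mucoscape("mucoscape_degenerate_data_error",
                   "constant response cannot be normalized")
  }
  gelation_curve(curve$temperature_c, (r - rng[1]) / diff(rng))
}

gelation_model <- function(T, bottom, top, hill_slope, t_half) {
  bottom + (top - bottom) / (1 + 10^(hill_slope * (t_half - T)))
}

gelation_sse <- function(par, T, y) {
  sum((y - gelation_model(T, par[1], par[2], par[3], par[4]))^2)
}

#' Fit the half-gelation temperature with a dose-response sigmoid
#'
#' Least-squares fit of the four-parameter log-logistic ("dose response")
#' model with temperature as the dose axis:
#' `response(T) = bottom + (top - bottom) / (1 + 10^(hill_slope * (t_half - T)))`.
#' Initialization: bottom/top from the data range, `t_half` at the
#' temperature nearest the half-range crossing, slope 1; on non-convergence
#' up to 5 jittered restarts (fixed internal seed) followed by a
#' Nelder-Mead fallback on the SSE. Deterministic for given data.
#'
#' @param curve a [gelation_curve()].
#' @return object of class `gelation_fit`: `t_half_c`, `hill_slope`,
#'   `bottom`, `top`, `residual_sse`, `converged`.
#' @export
fit_gelation <- function(curve) {
  stopifnot(inherits(curve, "gelation_curve"))
  T <- curve$temperature_c
  y <- curve$response
  if (diff(range(y)) == 0) {
    stop_mucoscape("mucoscape_degenerate_data_error",
                   "constant response: half-gelation temperature undefined")
  }
  bottom0 <- min(y); top0 <- max(y)
  half <- (bottom0 + top0) / 2
  t0 <- T[which.min(abs(y - half))]
  span <- diff(range(T))
  lower <- c(bottom = min(y) - diff(range(y)), top = min(y),
             hill_slope = 1e-4, t_half = min(T))
  upper <- c(bottom = max(y), top = max(y) + diff(range(y)),
             hill_slope = 100, t_half = max(T))
  starts <- list(c(bottom0, top0, 1, t0))
  jit <- with_seed(20231207, lapply(seq_len(5), function(i) {
    c(bottom0, top0,
      exp(runif(1, log(0.05), log(5))),
      min(max(t0 + runif(1, -span / 4, span / 4), min(T)), max(T)))
  }))
  starts <- c(starts, jit)
  best <- NULL
  converged <- FALSE
  df <- data.frame(T = T, y = y)
  for (st in starts) {
    fit <- try(suppressWarnings(nls(
      y ~ gelation_model(T, bottom, top, hill_slope, t_half),
      data = df,
      start = list(bottom = st[1], top = st[2], hill_slope = st[3], t_half = st[4]),
      lower = lower, upper = upper, algorithm = "port",
      control = list(maxiter = 200, warnOnly = FALSE)
    )), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      sse <- sum(residuals(fit)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(par = coef(fit), sse = sse)
        converged <- TRUE
      }
    }
  }
  if (is.null(best)) {
    opt <- optim(starts[[1]], gelation_sse, T = T, y = y,
                 method = "Nelder-Mead", control = list(maxit = 2000))
    best <- list(par = setNames(opt$par, c("bottom", "top", "hill_slope", "t_half")),
                 sse = opt$value)
    converged <- FALSE
  }
  p <- best$par
  if (p[["bottom"]] > p[["top"]]) {  # enforce bottom <= top orientation
    tmp <- p[["bottom"]]; p[["bottom"]] <- p[["top"]]; p[["top"]] <- tmp
  }
  structure(list(
    t_half_c = unname(p[["t_half"]]),
    hill_slope = unname(p[["hill_slope"]]),
    bottom = unname(p[["bottom"]]),
    top = unname(p[["top"]]),
    residual_sse = best$sse,
    converged = converged
  ), class = "gelation_fit")
}

#' @export
print.gelation_fit <- function(x, ...) {
  cat(sprintf("<gelation_fit> t_half = %.2f C, slope %.3g, range [%.3g, %.3g], SSE %.3g%s\n",
              x$t_half_c, x$hill_slope, x$bottom, x$top, x$residual_sse,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Half-gelation temperature shift between two formulations
#'
#' Fits both sweeps and returns `t_half(a) - t_half(b)` in degrees C; a
#' negative value means formulation `a` gels at a lower temperature.
#'
#' @param curve_a,curve_b [gelation_curve()]s.
#' @return signed temperature difference in degrees C.
#' @export
compare_formulations <- function(curve_a, curve_b) {
  fa <- fit_gelation(curve_a)
  fb <- fit_gelation(curve_b)
  if (!fa$converged || !fb$converged) {
    stop_mucoscape("mucoscape_fit_error",
                   "gelation fit did not converge for one of the formulations")
  }
  fa$t_half_c - fb$t_half_c
}

#' Read a rheology sweep CSV
#'
#' Expects columns `temperature_c`, `response` and an optional `series`
#' label; returns one [gelation_curve()] per series.
#'
#' @param path CSV file path.
#' @return named list of [gelation_curve()]s.
#' @export
read_gelation_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("temperature_c", "response") %in% names(df))) {
    stop_mucoscape("mucoscape_io_error",
                   "CSV must have columns temperature_c, response")
  }
  if (!"series" %in% names(df)) df$series <- "sweep"
  lapply(split(df, df$series), function(d) {
    d <- d[order(d$temperature_c), ]
    gelation_curve(d$temperature_c, d$response)
  })
}
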