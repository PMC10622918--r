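#' Model II (and ordinary) regression with permutation significance
#'
#' Fits a bivariate regression treating both variables as subject to
#' error, as is appropriate when neither axis is experimentally
#' controlled (rates against measured primary production). Methods:
#' `"OLS"` ordinary least squares (slope = cov(x,y)/var(x)); `"SMA"`
#' standardized major axis (slope = sign(r) sd(y)/sd(x)); `"MA"` major
#' axis (slope of the leading eigenvector of the sample covariance
#' matrix). The intercept is always `mean(y) - slope * mean(x)`.
#'
#' Significance is assessed by a two-sided permutation test: `y` is
#' permuted against `x` `n_perm` times and the p-value is
#' `(1 + #{|r*| >= |r|}) / (n_perm + 1)`. The permutation stream is
#' governed by `seed` when given, making the p-value reproducible.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite, each with
#'   positive spread. Any transformation (e.g. log10) is applied by the
#'   caller; record it via `x_transform` / `y_transform`.
#' @param method `"SMA"` (default), `"MA"`, or `"OLS"`.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional integer seed for the permutation stream.
#' @param x_transform,y_transform Labels (`"linear"` or `"log10"`)
#'   recording how the caller transformed the inputs; bookkeeping only.
#' @param segment Optional label of the gradient segment fitted.
#' @return An object of class `model2_fit`; see [tidy()] and [glance()]
#'   methods, and [autoplot.model2_fit()].
#' @export
#' @examples
#' set.seed(7)
#' x <- rnorm(30); y <- 2 * x + rnorm(30, sd = 0.5)
#' fit <- model2_fit(x, y, method = "SMA", seed = 1)
#' glance(fit)
model2_fit <- function(x, y, method = c("SMA", "MA", "OLS"),
                       n_perm = 999, seed = NULL,
                       x_transform = "linear", y_transform = "linear",
                       segment = NA_character_) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "picograze_fit_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite", class = "picograze_fit_error")
  }
  n <- length(x)
  if (n < 3) abort("need at least 3 points", class = "picograze_fit_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input", class = "picograze_fit_error")
  }

  r <- cor(x, y)
  slope <- model2_slope(x, y, method)
  intercept <- mean(y) - slope * mean(x)

  perm_r <- function() {
    abs_r <- abs(r)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(cor(x, sample(y))) >= abs_r - 1e-15) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  p_perm <- if (is.null(seed)) perm_r() else {
    withr::with_seed(as.integer(seed), perm_r())
  }

  structure(
    list(method = method, slope = slope, intercept = intercept, r = r,
         p_perm = p_perm, n = n, n_perm = n_perm,
         x_transform = x_transform, y_transform = y_transform,
         segment = segment, data = tibble::tibble(x = x, y = y)),
    class = "model2_fit"
  )
}

model2_slope <- function(x, y, method) {
  sxy <- stats::cov(x, y)
  switch(method,
    OLS = sxy / var(x),
    SMA = {
      r <- cor(x, y)
      s <- if (r == 0) 1 else sign(r)
      s * sd(y) / sd(x)
    },
    MA = {
      sxx <- var(x)
      syy <- var(y)
      if (sxy == 0) {
        if (syy <= sxx) 0 else Inf
      } else {
        disc <- sqrt((syy - sxx)^2 + 4 * sxy^2)
        # pick the algebraically equivalent branch without cancellation
        if (syy >= sxx) {
          (syy - sxx + disc) / (2 * sxy)
        } else {
          2 * sxy / (sxx - syy + disc)
        }
      }
    }
  )
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("<model2_fit> %s: y = %.4g + %.4g x  (n = %d%s)\n",
              x$method, x$intercept, x$slope, x$n,
              if (is.na(x$segment)) "" else paste0(", segment ", x$segment)))
  cat(sprintf("  r = %.3f, permutation p = %.4g (%d permutations)\n",
              x$r, x$p_perm, x$n_perm))
  cat(sprintf("  transforms: x %s, y %s\n", x$x_transform, x$y_transform))
  invisible(x)
}

#' Tidy a Model II fit
#'
#' @param x A [model2_fit()] object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.model2_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a Model II fit
#'
#' @param x A [model2_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `segment`, `n`, `slope`,
#'   `intercept`, `r`, `p_perm`, `x_transform`, `y_transform`.
#' @export
glance.model2_fit <- function(x, ...) {
  tibble::tibble(method = x$method, segment = x$segment, n = x$n,
                 slope = x$slope, intercept = x$intercept, r = x$r,
                 p_perm = x$p_perm, x_transform = x$x_transform,
                 y_transform = x$y_transform)
}

#' Floor nonpositive rates before log transformation
#'
#' Rate estimates from noisy two-bottle experiments can be negative;
#' before a log-scale regression every value <= 0 is replaced by a low
#' positive floor (0.01 d-1 by default). Positive values are untouched,
#' so the ordering of positive values is preserved. A message reports
#' how many values were floored.
#'
#' @param values Numeric vector of rates (d-1).
#' @param floor Replacement value for nonpositive entries.
#' @return `values` with every nonpositive entry replaced by `floor`.
#' @export
#' @examples
#' floor_for_log(c(-0.05, 0, 0.3))
floor_for_log <- function(values, floor = 0.01) {
  nonpos <- is.finite(values) & values <= 0
  if (any(nonpos)) {
    inform(sprintf("floored %d nonpositive value(s) to %g for log scale",
                   sum(nonpos), floor))
    values[nonpos] <- floor
  }
  values
}

#' Default overlapping productivity segments
#'
#' The gradient analysis fits trends over overlapping windows of primary
#' production rather than a single global line: the low-to-medium window
#' (PP < 100 mg C m-3 d-1) and the medium-to-high window (PP > 10)
#' overlap in 10--100, where picophytoplankton abundance peaks, and the
#' extreme windows (PP < 10, PP > 100) and the full range are also
#' available.
#'
#' @return A tibble: `label`, `pp_min`, `pp_max` (open intervals; `0` and
#'   `Inf` mark unbounded ends).
#' @export
default_segments <- function() {
  tibble::tribble(
    ~label,    ~pp_min, ~pp_max,
    "PP<100",  0,       100,
    "PP>10",   10,      Inf,
    "PP>100",  100,     Inf,
    "PP<10",   0,       10,
    "all",     0,       Inf
  )
}

#' Segmented Model II regressions of station rates against production
#'
#' Regresses a station-level response (abundance, rate, or mortality
#' ratio) on mean primary production over each requested gradient
#' segment. Stations whose `pp_mean` falls inside a window enter that
#' window's fit, so overlapping windows share stations. Undefined
#' responses (absent populations) are dropped with a message; segments
#' with fewer than 3 stations are skipped with a warning.
#'
#' Axis transforms follow the field's plotting conventions: by default
#' both production and the response are log10-transformed, and
#' nonpositive responses are floored via [floor_for_log()] before the
#' log (the floor is not applied on linear-scale fits).
#'
#' @param stations Station-level table ([aggregate_stations()], or any
#'   tibble with `pp_mean` and the response column; a `population`
#'   column is filtered when `population` is given).
#' @param response Name of the response column (string), e.g. `"m_mean"`.
#' @param population Optional population label to filter on.
#' @param segments Segment windows, as from [default_segments()].
#' @param method,n_perm Passed to [model2_fit()].
#' @param log_x,log_y Apply log10 to production / response.
#' @param floor Floor for nonpositive responses when `log_y = TRUE`.
#' @param seed Optional integer; segment fits use `seed`, `seed + 1`, ...
#'   so the whole table is reproducible.
#' @return A tibble with one row per fitted segment: `population`,
#'   `response`, `segment`, `pp_min`, `pp_max`, `method`, `n`, `slope`,
#'   `intercept`, `r`, `p_perm`, `x_transform`, `y_transform`.
#' @export
segment_regressions <- function(stations, response, population = NULL,
                                segments = default_segments(),
                                method = "SMA", log_x = TRUE, log_y = TRUE,
                                n_perm = 999, floor = 0.01, seed = NULL) {
  if (!response %in% names(stations)) {
    abort(sprintf("response column `%s` not found", response),
          class = "picograze_schema_error")
  }
  data <- stations
  if (!is.null(population)) {
    data <- dplyr::filter(data, .data$population == !!population)
  }
  y_raw <- data[[response]]
  drop <- !is.finite(y_raw) | !is.finite(data$pp_mean)
  if (any(drop)) {
    inform(sprintf("dropping %d station(s) with undefined %s",
                   sum(drop), response))
    data <- data[!drop, ]
    y_raw <- y_raw[!drop]
  }
  x <- data$pp_mean
  y <- y_raw
  if (log_y) y <- log10(floor_for_log(y, floor))
  if (log_x) x <- log10(x)

  fits <- purrr::imap(split(segments, seq_len(nrow(segments))), function(seg, i) {
    inside <- data$pp_mean > seg$pp_min & data$pp_mean < seg$pp_max
    if (sum(inside) < 3) {
      warn(sprintf("segment %s has %d station(s) (< 3); fit skipped",
                   seg$label, sum(inside)))
      return(NULL)
    }
    fit <- model2_fit(
      x[inside], y[inside], method = method, n_perm = n_perm,
      seed = if (is.null(seed)) NULL else as.integer(seed) + as.integer(i) - 1L,
      x_transform = if (log_x) "log10" else "linear",
      y_transform = if (log_y) "log10" else "linear",
      segment = seg$label
    )
    dplyr::mutate(glance(fit), pp_min = seg$pp_min, pp_max = seg$pp_max)
  })
  fits <- dplyr::bind_rows(fits)
  if (nrow(fits) == 0) return(fits)
  dplyr::mutate(fits,
    population = if (is.null(population)) NA_character_ else population,
    response = response,
    .before = 1
  ) |>
    dplyr::relocate("segment", "pp_min", "pp_max", .after = "response")
}
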