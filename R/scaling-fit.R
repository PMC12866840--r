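# log-log least squares core; both residual-space conventions for R^2
fit_loglog <- function(x, y, residual_space = c("log10", "cartesian")) {
  residual_space <- match.arg(residual_space)
  usable <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_excluded <- sum(!usable)
  x <- x[usable]; y <- y[usable]
  if (length(x) < 3) abort("fewer than 3 usable (positive, finite) points")
  lx <- log10(x); ly <- log10(y)
  fit <- lm(ly ~ lx)
  exponent <- unname(coef(fit)[2])
  prefactor <- 10^unname(coef(fit)[1])
  if (residual_space == "log10") {
    ss_res <- sum(residuals(fit)^2)
    ss_tot <- sum((ly - mean(ly))^2)
  } else {
    yhat <- prefactor * x^exponent
    ss_res <- sum((y - yhat)^2)
    ss_tot <- sum((y - mean(y))^2)
  }
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else -Inf
  } else {
    1 - ss_res / ss_tot
  }
  list(
    exponent = exponent, prefactor = prefactor, r_squared = r2,
    residual_space = residual_space, n_points = length(x),
    n_excluded = n_excluded, model = fit, x = x, y = y
  )
}

#' Fit a power law y = a * x^b by log-log least squares
#'
#' Ordinary least squares on `(log10 x, log10 y)`; the exponent is the slope
#' and the prefactor `10^intercept`. `R^2` is computed in the requested
#' residual space: `"log10"` uses the log-residuals of the line,
#' `"cartesian"` measures residuals of `y` against the back-transformed model
#' on the natural scale. Non-positive or non-finite records are excluded and
#' counted.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the positive predictor and response.
#' @param residual_space `"log10"` (default) or `"cartesian"`.
#' @return An object of class `power_fit` with fields `exponent`,
#'   `prefactor`, `r_squared`, `residual_space`, `n_points`, `n_excluded`.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' d <- tibble::tibble(x = 10^seq(1, 5, length.out = 50))
#' d$y <- 2 * d$x^2.5
#' fit_power_law(d, x, y)
#' @export
fit_power_law <- function(data, x, y, residual_space = c("log10", "cartesian")) {
  xv <- pull(data, {{ x }})
  yv <- pull(data, {{ y }})
  out <- fit_loglog(xv, yv, residual_space)
  structure(out, class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf(
    "<power_fit> y = %.4g * x^%.4g  (R^2 [%s] = %.4f, n = %d, excluded = %d)\n",
    x$prefactor, x$exponent, x$residual_space, x$r_squared,
    x$n_points, x$n_excluded
  ))
  invisible(x)
}

#' @export
tidy.power_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("prefactor", "exponent"),
    estimate = c(x$prefactor, x$exponent),
    std.error = c(NA_real_, s[2, 2]),
    p.value = c(NA_real_, s[2, 4])
  )
}

#' @export
glance.power_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared, residual_space = x$residual_space,
    n_points = x$n_points, n_excluded = x$n_excluded
  )
}

#' @export
autoplot.power_fit <- function(object, ...) {
  d <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_function(
      fun = function(x) object$prefactor * x^object$exponent,
      colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "x", y = "y",
      subtitle = sprintf("exponent %.3f, prefactor %.3g, R²(%s) %.3f",
                         object$exponent, object$prefactor,
                         object$residual_space, object$r_squared)
    )
}

#' Fit the exon/intron ratio vs gene length law E/I = p / L^n
#'
#' Fits `log10(E/I) = log10(p) - n log10(L)` over gene metrics, so the
#' reported `n_hat` is minus the log-log slope and `p_hat = 10^intercept`
#' (bp). With `fixed_n` set (the convention `n = 1`), only `p` is estimated,
#' as the geometric mean of `(E/I) * L^n`. Genes with `I = 0` or `E = 0` are
#' excluded and counted.
#'
#' @param metrics Tibble from [gene_metrics()] (columns `exon_bp`,
#'   `intron_bp`, `length`).
#' @param fixed_n Optional fixed length exponent.
#' @param residual_space Residual convention for `R^2`.
#' @return An `ei_fit` object with `n_hat`, `p_hat`, `r_squared`,
#'   `n_points`, `n_excluded`.
#' @export
fit_ei_vs_length <- function(metrics, fixed_n = NULL,
                             residual_space = c("log10", "cartesian")) {
  residual_space <- match.arg(residual_space)
  ei <- metrics$exon_bp / metrics$intron_bp
  L <- metrics$length
  usable <- is.finite(ei) & ei > 0 & L > 0
  if (!is.null(fixed_n)) {
    if (sum(usable) < 1) abort("no usable genes")
    lp <- log10(ei[usable]) + fixed_n * log10(L[usable])
    p_hat <- 10^mean(lp)
    res <- lp - mean(lp)
    ss_tot <- sum((log10(ei[usable]) - mean(log10(ei[usable])))^2)
    r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
    out <- list(
      n_hat = fixed_n, p_hat = p_hat, fixed_n = TRUE, r_squared = r2,
      residual_space = "log10", n_points = sum(usable),
      n_excluded = sum(!usable)
    )
  } else {
    f <- fit_loglog(L[usable], ei[usable], residual_space)
    out <- list(
      n_hat = -f$exponent, p_hat = f$prefactor, fixed_n = FALSE,
      r_squared = f$r_squared, residual_space = residual_space,
      n_points = f$n_points, n_excluded = sum(!usable) + f$n_excluded,
      model = f$model
    )
  }
  structure(out, class = "ei_fit")
}

#' @export
print.ei_fit <- function(x, ...) {
  cat(sprintf(
    "<ei_fit> E/I = %.4g / L^%.4g  (R^2 [%s] = %.4f, n = %d, excluded = %d%s)\n",
    x$p_hat, x$n_hat, x$residual_space, x$r_squared, x$n_points,
    x$n_excluded, if (x$fixed_n) ", n fixed" else ""
  ))
  invisible(x)
}

#' @export
glance.ei_fit <- function(x, ...) {
  tibble(
    n_hat = x$n_hat, p_hat = x$p_hat, fixed_n = x$fixed_n,
    r_squared = x$r_squared, residual_space = x$residual_space,
    n_points = x$n_points, n_excluded = x$n_excluded
  )
}

#' R^2 of gene metrics against a fixed E/I = p / L^n curve
#'
#' Companion to [fit_ei_vs_length()]: evaluates a user-supplied `(p, n)`
#' instead of the free fit, in either residual convention.
#'
#' @inheritParams fit_ei_vs_length
#' @param p,n Fixed scalar parameters of the curve.
#' @return A single `R^2` value (may be negative when the curve fits worse
#'   than the mean).
#' @export
ei_r_squared <- function(metrics, p, n, residual_space = c("log10", "cartesian")) {
  residual_space <- match.arg(residual_space)
  ei <- metrics$exon_bp / metrics$intron_bp
  L <- metrics$length
  usable <- is.finite(ei) & ei > 0 & L > 0
  ei <- ei[usable]; L <- L[usable]
  if (residual_space == "log10") {
    obs <- log10(ei); pred <- log10(p) - n * log10(L)
  } else {
    obs <- ei; pred <- p / L^n
  }
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Classify records as linear vs power-law geometry
#'
#' Records with exon content exceeding NE content (`E/I > 1`) are labelled
#' `"linear"` (beads-on-a-string-like, exon-dominated); all others
#' `"power_law"` (volumetric, NE-dominated).
#'
#' @param data Gene metrics (`exon_bp`, `intron_bp`) or segments (`exon_bp`,
#'   `ne_bp`).
#' @return `data` with a `geometry` column; class counts in
#'   `attr(, "summary")`.
#' @export
classify_geometry <- function(data) {
  ne <- if ("intron_bp" %in% names(data)) data$intron_bp else data$ne_bp
  if (is.null(ne)) abort("`data` needs an `intron_bp` or `ne_bp` column")
  out <- mutate(data,
    geometry = if_else(.data$exon_bp / ne > 1, "linear", "power_law")
  )
  attr(out, "summary") <- count(out, .data$geometry)
  out
}

#' Compare observed scaling against a null by log10 residuals
#'
#' Fits the observed data in log10 space, measures log10 residuals of both
#' the observed and the null data from that fitted model, and compares the
#' two residual distributions with a Welch two-sample t-test. Also reports
#' the `R^2` of each data set against the observed model.
#'
#' @param obs,null Data frames holding the observed and null records.
#' @param x,y Unquoted column names (shared by both frames).
#' @return A tibble with `statistic`, `p_value`, `r2_obs`, `r2_null`,
#'   `n_obs`, `n_null`, `degenerate` (TRUE when both residual sets have zero
#'   variance, in which case the test is skipped and the p-value is `NA`).
#' @export
compare_to_null <- function(obs, null, x, y) {
  fo <- fit_loglog(pull(obs, {{ x }}), pull(obs, {{ y }}), "log10")
  res_of <- function(xv, yv) {
    usable <- is.finite(xv) & is.finite(yv) & xv > 0 & yv > 0
    lx <- log10(xv[usable]); ly <- log10(yv[usable])
    list(res = ly - (log10(fo$prefactor) + fo$exponent * lx), ly = ly)
  }
  ro <- res_of(pull(obs, {{ x }}), pull(obs, {{ y }}))
  rn <- res_of(pull(null, {{ x }}), pull(null, {{ y }}))
  r2 <- function(r) {
    ss_tot <- sum((r$ly - mean(r$ly))^2)
    if (ss_tot == 0) NA_real_ else 1 - sum(r$res^2) / ss_tot
  }
  degenerate <- stats::sd(ro$res) < 1e-12 && stats::sd(rn$res) < 1e-12
  if (degenerate) {
    warn("both residual distributions are degenerate; test skipped")
    stat <- NA_real_; pval <- NA_real_
  } else {
    tt <- t.test(ro$res, rn$res, var.equal = FALSE)
    stat <- unname(tt$statistic); pval <- tt$p.value
  }
  tibble(
    statistic = stat, p_value = pval,
    r2_obs = r2(ro), r2_null = r2(rn),
    n_obs = length(ro$res), n_null = length(rn$res),
    degenerate = degenerate
  )
}
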