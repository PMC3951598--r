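#' Fit the quadratic browning response surface
#'
#' Ordinary least squares of mean browning scores on the 6-term quadratic
#' basis in baking time `x1` (min) and oven temperature `x2` (°C):
#' `S = b0 + b1 x1 + b2 x2 + b11 x1^2 + b22 x2^2 + b12 x1 x2`.
#' Cookies baked 20 min or longer are excluded as extreme cases before
#' fitting. The surface is only considered valid inside the fitted design
#' box; evaluation outside it triggers a warning.
#'
#' @param scores Mean browning scores, one per cookie.
#' @param times Baking times (min).
#' @param temps Oven temperatures (°C).
#' @param max_time_min Exclusion threshold for extreme baking times.
#' @return Object of class `response_surface`: coefficients `b0, b1, b2,
#'   b11, b22, b12`, validity ranges, `residuals` and `r_squared`.
#' @export
fit_surface <- function(scores, times, temps, max_time_min = 20) {
  stopifnot(length(scores) == length(times), length(times) == length(temps))
  keep <- times < max_time_min
  scores <- scores[keep]; times <- times[keep]; temps <- temps[keep]
  if (length(unique(paste(times, temps))) < 6) {
    stop("need at least 6 distinct (time, temperature) design points")
  }
  df <- data.frame(s = scores, x1 = times, x2 = temps)
  fit <- stats::lm(s ~ x1 + x2 + I(x1^2) + I(x2^2) + x1:x2, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  cf <- stats::coef(fit)
  structure(list(
    b0 = unname(cf["(Intercept)"]), b1 = unname(cf["x1"]),
    b2 = unname(cf["x2"]), b11 = unname(cf["I(x1^2)"]),
    b22 = unname(cf["I(x2^2)"]), b12 = unname(cf["x1:x2"]),
    time_range = range(times), temp_range = range(temps),
    residuals = unname(stats::residuals(fit)),
    # computed directly (not via summary.lm, which warns on perfect fits)
    r_squared = if (stats::var(scores) > 0) {
      1 - sum(stats::residuals(fit)^2) / sum((scores - mean(scores))^2)
    } else 1
  ), class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "<response_surface> S = %.3g + %.3g t + %.3g T + %.3g t^2 + %.3g T^2 + %.3g tT\n",
    x$b0, x$b1, x$b2, x$b11, x$b22, x$b12
  ))
  cat(sprintf("  valid for t in [%g, %g] min, T in [%g, %g] degC; R^2 = %.3f\n",
              x$time_range[1], x$time_range[2],
              x$temp_range[1], x$temp_range[2], x$r_squared))
  invisible(x)
}

#' Evaluate the response surface
#'
#' @param surface A [fit_surface()] object.
#' @param time_min,temp_c Evaluation point(s); recycled.
#' @param warn_outside Warn when the point lies outside the validity box.
#' @return Predicted browning score(s).
#' @export
eval_surface <- function(surface, time_min, temp_c, warn_outside = TRUE) {
  if (warn_outside &&
      (any(time_min < surface$time_range[1] | time_min > surface$time_range[2]) ||
       any(temp_c < surface$temp_range[1] | temp_c > surface$temp_range[2]))) {
    warning("evaluating response surface outside its validity ranges")
  }
  with(surface, b0 + b1 * time_min + b2 * temp_c + b11 * time_min^2 +
         b22 * temp_c^2 + b12 * time_min * temp_c)
}

#' Time-temperature sensitivity ratio
#'
#' Ratio of the surface's partial derivative with respect to time to its
#' partial derivative with respect to temperature,
#' `(dS/dt) / (dS/dT) = (b1 + 2 b11 t + b12 T) / (b2 + 2 b22 T + b12 t)`,
#' in °C per minute: how many degrees of extra oven temperature produce the
#' same browning change as one extra minute.
#'
#' @param surface A [fit_surface()] object.
#' @param at_time,at_temp Evaluation point (defaults: design box center).
#' @return Sensitivity in °C per minute.
#' @export
sensitivity_ratio <- function(surface,
                              at_time = mean(surface$time_range),
                              at_temp = mean(surface$temp_range)) {
  if (at_time < surface$time_range[1] || at_time > surface$time_range[2] ||
      at_temp < surface$temp_range[1] || at_temp > surface$temp_range[2]) {
    stop("evaluation point outside the surface's validity box")
  }
  ds_dt <- surface$b1 + 2 * surface$b11 * at_time + surface$b12 * at_temp
  ds_dT <- surface$b2 + 2 * surface$b22 * at_temp + surface$b12 * at_time
  if (abs(ds_dT) < 1e-12) stop("temperature sensitivity is zero at this point")
  ds_dt / ds_dT
}

#' Browning zone map over the process window
#'
#' Evaluates the response surface on a time x temperature grid and labels
#' each cell with the sensory zone obtained by thresholding the surface
#' value with the browning-score class limits.
#'
#' @param surface A [fit_surface()] object.
#' @param limits Class limits (vector from [compute_class_limits()] or an
#'   `fda_model` carrying them).
#' @param time_grid,temp_grid Grid vectors; default 81 points across the
#'   validity ranges.
#' @return List with `zones` (character matrix, times x temps), `scores`
#'   (numeric matrix), `time_grid`, `temp_grid`.
#' @export
zone_map <- function(surface, limits,
                     time_grid = seq(surface$time_range[1],
                                     surface$time_range[2], length.out = 81),
                     temp_grid = seq(surface$temp_range[1],
                                     surface$temp_range[2], length.out = 81)) {
  if (any(time_grid < surface$time_range[1]) ||
      any(time_grid > surface$time_range[2]) ||
      any(temp_grid < surface$temp_range[1]) ||
      any(temp_grid > surface$temp_range[2])) {
    warning("zone map grid extends outside the surface validity box")
  }
  sc <- outer(time_grid, temp_grid,
              function(t, T) eval_surface(surface, t, T, warn_outside = FALSE))
  zones <- matrix(classify_cookie(as.vector(sc), limits),
                  nrow = length(time_grid),
                  dimnames = list(time_min = time_grid, temp_c = temp_grid))
  list(zones = zones, scores = sc, time_grid = time_grid, temp_grid = temp_grid)
}
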