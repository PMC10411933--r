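#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Fitts-law fit
#'
#' @param x An `aimkin_fitts` object.
#' @param ... Unused.
#' @return One row per model term (`(Intercept)` in ms, `id_e` in ms/bit)
#'   with estimate, standard error, t statistic and p value.
#' @export
tidy.aimkin_fitts <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' Glance at a Fitts-law fit
#'
#' @param x An `aimkin_fitts` object.
#' @param ... Unused.
#' @return A one-row tibble: `intercept` (ms), `slope` (ms/bit),
#'   `throughput` (bits/s, `1000 / slope`), `r.squared`, `sigma`, `nobs`.
#' @export
glance.aimkin_fitts <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    intercept = x$intercept, slope = x$slope,
    throughput = 1000 / x$slope,
    r.squared = sm$r.squared, sigma = sm$sigma,
    nobs = stats::nobs(x$fit)
  )
}

#' Tidy an error ellipse
#'
#' @param x An `aimkin_ellipse` object.
#' @param ... Unused.
#' @return A one-row tibble with the centre, semi-axes, orientation and
#'   aspect ratio.
#' @export
tidy.aimkin_ellipse <- function(x, ...) {
  tibble(
    center_x = x$center[1], center_y = x$center[2],
    semi_major = x$semi_axes[1], semi_minor = x$semi_axes[2],
    orientation = x$orientation, aspect_ratio = x$aspect_ratio,
    coverage = x$coverage, n = x$n
  )
}

# points on the ellipse outline, for plotting
ellipse_outline <- function(ell, n = 181) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- deg2rad(ell$orientation)
  ex <- ell$semi_axes[1] * cos(th)
  ey <- ell$semi_axes[2] * sin(th)
  tibble(
    x = ell$center[1] + cos(a) * ex - sin(a) * ey,
    y = ell$center[2] + sin(a) * ex + cos(a) * ey
  )
}
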