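#' Fraction of RNA bound from membrane intensities
#'
#' `fraction_bound = nitro / (nitro + nylon)`: the nitrocellulose membrane
#' retains protein-bound RNA, the nylon membrane the free RNA.
#'
#' @param nitro,nylon Nonnegative intensities (vectorized).
#' @return Fractions in `[0, 1]`.
#' @export
fraction_bound <- function(nitro, nylon) {
  stopifnot(all(nitro >= 0), all(nylon >= 0))
  tot <- nitro + nylon
  if (any(tot == 0)) {
    stop("undefined observation: both membrane intensities are zero",
         call. = FALSE)
  }
  nitro / tot
}

#' Fit the single-site hyperbolic binding equation
#'
#' Nonlinear least squares of
#' \deqn{f(c) = f_{max} \, c / (c + K_d)}
#' to a concentration series, with multi-start initialization (`kd` started
#' at the minimum, geometric mean, and maximum of the concentrations) via
#' Levenberg-Marquardt. `f_max` is free within `(0, 1.2]` to tolerate
#' normalization noise.
#'
#' @param observations data.frame with `protein_conc_nM` and either
#'   `fraction_bound` or both `intensity_nitro` and `intensity_nylon`
#'   columns.
#' @return Object of class `"binding_fit"` with components `kd` (nM),
#'   `f_max`, `rss`, `n_points`, `data`, and the underlying `nls` fit.
#' @export
fit_binding <- function(observations) {
  obs <- observations
  if (!"fraction_bound" %in% names(obs)) {
    obs$fraction_bound <- fraction_bound(obs$intensity_nitro,
                                         obs$intensity_nylon)
  }
  conc <- obs$protein_conc_nM
  frac <- obs$fraction_bound
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  if (stats::sd(frac) == 0) {
    stop("degenerate binding data: fraction bound constant at all ",
         "concentrations (no curvature to fit)", call. = FALSE)
  }
  gm <- exp(mean(log(conc[conc > 0])))
  starts <- list(
    c(kd = min(conc[conc > 0]), f_max = min(max(frac), 1.2)),
    c(kd = gm, f_max = min(max(frac), 1.2)),
    c(kd = max(conc), f_max = min(max(frac), 1.2))
  )
  df <- data.frame(c = conc, f = frac)
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ f_max * c / (c + kd), data = df,
                        start = as.list(st),
                        lower = c(kd = 1e-9, f_max = 1e-6),
                        upper = c(kd = Inf, f_max = 1.2),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) {
    stop("binding fit failed to converge from all starting points",
         call. = FALSE)
  }
  cf <- stats::coef(best)
  structure(
    list(kd = unname(cf["kd"]), f_max = unname(cf["f_max"]),
         rss = best_rss, n_points = nrow(df), data = df, fit = best),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Hyperbolic binding fit: f(c) = f_max * c / (c + Kd)\n")
  cat(sprintf("  Kd:    %.4g nM\n", x$kd))
  cat(sprintf("  f_max: %.4f\n", x$f_max))
  cat(sprintf("  rss:   %.3g over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, f_max = object$f_max)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$c else {
    if (is.data.frame(newdata)) {
      newdata$protein_conc_nM %||% newdata$c
    } else {
      newdata
    }
  }
  object$f_max * conc / (conc + object$kd)
}

#' @export
fitted.binding_fit <- function(object, ...) predict(object)

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$f - fitted(object)
}

#' @export
summary.binding_fit <- function(object, ...) {
  s <- summary(object$fit)
  cat("Hyperbolic binding fit\n")
  print(s$coefficients)
  invisible(s)
}

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$data$c, x$data$f, log = "x",
                 xlab = "protein concentration (nM)",
                 ylab = "fraction bound",
                 main = sprintf("Kd = %.3g nM, f_max = %.3f", x$kd, x$f_max),
                 ...)
  cc <- exp(seq(log(min(x$data$c[x$data$c > 0])), log(max(x$data$c)),
                length.out = 200))
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}
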