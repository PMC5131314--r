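# Developmental staging and cohort-level statistics.

#' Stage thresholds on the equivalent diameter
#'
#' Antral follicles typically measure between 100 um (early antral) and
#' 700 um in diameter; beyond that a follicle is Graafian. The interval is
#' closed on both ends (100 um and 700 um both class as antral); the
#' convention is fixed here because the boundary behaviour matters for
#' automated staging.
#'
#' @param primary_max upper diameter bound (um) for primary follicles.
#' @param antral_max upper diameter bound (um) for antral follicles.
#' @export
stage_thresholds <- function(primary_max = 100, antral_max = 700) {
  if (!(primary_max > 0 && primary_max < antral_max)) {
    stop("need 0 < primary_max < antral_max")
  }
  structure(list(primary_max = primary_max, antral_max = antral_max),
            class = "stage_thresholds")
}

#' Classify developmental stage from the equivalent diameter
#'
#' @param diameter_um equivalent diameter(s), micrometres.
#' @param thresholds a [stage_thresholds()].
#' @return factor with levels primary, antral, Graafian.
#' @export
classify_stage <- function(diameter_um, thresholds = stage_thresholds()) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("diameters must be positive")
  }
  lab <- ifelse(diameter_um < thresholds$primary_max, "primary",
                ifelse(diameter_um <= thresholds$antral_max, "antral", "Graafian"))
  factor(lab, levels = c("primary", "antral", "Graafian"))
}

#' Per-stage cohort volume statistics
#'
#' For each stage: n, mean, median and interquartile range of the follicle
#' volume (mm^3), with a formatted "value \[Q1-Q3\]" column. Percentiles use
#' the linear-interpolation convention (R type 7).
#'
#' @param measurements data.frame with columns `stage` and `volume_mm3`.
#' @return data.frame, one row per stage present.
#' @export
cohort_volume_summary <- function(measurements) {
  if (nrow(measurements) == 0L) {
    return(data.frame(stage = character(), n = integer(), mean_mm3 = numeric(),
                      median_mm3 = numeric(), q25_mm3 = numeric(),
                      q75_mm3 = numeric(), formatted = character()))
  }
  stages <- intersect(c("primordial", "primary", "antral", "Graafian"),
                      unique(as.character(measurements$stage)))
  rows <- lapply(stages, function(s) {
    v <- measurements$volume_mm3[measurements$stage == s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(stage = s, n = length(v), mean_mm3 = mean(v),
               median_mm3 = q[[2]], q25_mm3 = q[[1]], q75_mm3 = q[[3]],
               formatted = sprintf("%.2g [%.2g-%.2g] mm^3", mean(v), q[[1]], q[[3]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`; equals R^2 when p = 0.
#'
#' @param r_squared plain R^2.
#' @param n number of observations.
#' @param p number of model parameters (excluding the intercept-equivalent).
#' @export
adjusted_r_squared <- function(r_squared, n, p) {
  1 - (1 - r_squared) * (n - 1) / (n - p - 1)
}

new_regression_result <- function(family, coefficients, n, r2, adj_r2, resid_sd,
                                  fitted_fun) {
  structure(list(family = family, coefficients = coefficients, n = n,
                 r_squared = r2, adj_r_squared = adj_r2,
                 residual_sd = resid_sd, predict = fitted_fun),
            class = "folli_regression")
}

#' @export
print.folli_regression <- function(x, ...) {
  cat(sprintf("<%s regression> n = %d, R^2 = %.3f, adj. R^2 = %.3f, residual sd = %.3g\n",
              x$family, x$n, x$r_squared, x$adj_r_squared, x$residual_sd))
  cat("  coefficients:", paste(sprintf("%s = %.5g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

r2_against <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Fit the oocyte-vs-follicle growth curve
#'
#' Oocyte diameter grows quickly in small follicles and plateaus in large
#' ones, so the default family is the saturating hyperbola
#' `oocyte_d = a d / (b + d)`; a log-linear alternative
#' `oocyte_d = a + b ln d` is available. When `validation` points are
#' supplied (e.g. literature histology values), R^2 and adjusted R^2 are
#' evaluated for the fitted curve against those points, mirroring the
#' literature-validation design; otherwise against the fitting points.
#'
#' @param follicle_d,oocyte_d paired diameters, micrometres (n >= 4).
#' @param family `"hyperbola"` or `"loglinear"`.
#' @param validation optional data.frame with columns `follicle_d`, `oocyte_d`.
#' @return a `folli_regression`.
#' @export
fit_oocyte_growth <- function(follicle_d, oocyte_d,
                              family = c("hyperbola", "loglinear"),
                              validation = NULL) {
  family <- match.arg(family)
  if (length(follicle_d) < 4L) stop("need at least 4 points")
  if (any(follicle_d <= 0) || any(oocyte_d <= 0)) stop("diameters must be positive")
  if (family == "hyperbola") {
    df <- data.frame(d = follicle_d, o = oocyte_d)
    fit <- minpack.lm::nlsLM(o ~ a * d / (b + d), data = df,
                             start = list(a = max(oocyte_d) * 1.1,
                                          b = stats::median(follicle_d)),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    pred_fun <- function(d) cf[["a"]] * d / (cf[["b"]] + d)
  } else {
    fit <- lm(oocyte_d ~ log(follicle_d))
    cf <- c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    pred_fun <- function(d) cf[["a"]] + cf[["b"]] * log(d)
  }
  p <- 2L
  if (is.null(validation)) {
    obs <- oocyte_d; pred <- pred_fun(follicle_d)
  } else {
    obs <- validation$oocyte_d; pred <- pred_fun(validation$follicle_d)
  }
  n_eval <- length(obs)
  r2 <- r2_against(obs, pred)
  new_regression_result(paste0("oocyte-growth ", family), cf, n_eval, r2,
                        adjusted_r_squared(r2, n_eval, p),
                        sqrt(sum((obs - pred)^2) / max(n_eval - p, 1)), pred_fun)
}

#' Regress a response on log10 follicle volume
#'
#' Ordinary least squares of a folliculometric response (asymmetry, wall
#' thickness) against log10(volume); both relationships show inverse trends
#' (negative slopes) across development.
#'
#' @param volume_mm3 follicle volumes, mm^3 (positive, n >= 3).
#' @param response response values, same length.
#' @return a `folli_regression` with coefficients intercept and slope.
#' @export
loglinear_regression <- function(volume_mm3, response) {
  if (length(volume_mm3) < 3L) stop("need at least 3 points")
  if (any(volume_mm3 <= 0)) stop("volumes must be positive")
  lv <- log10(volume_mm3)
  if (stats::var(lv) == 0) stop("zero variance in log10(volume)")
  keep <- is.finite(response)
  fit <- lm(response[keep] ~ lv[keep])
  cf <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  s <- summary(fit)
  pred_fun <- function(v) cf[["intercept"]] + cf[["slope"]] * log10(v)
  new_regression_result("log10-volume linear", cf, sum(keep), s$r.squared,
                        s$adj.r.squared, s$sigma, pred_fun)
}

#' @importFrom stats var
NULL

#' Simulate a measurement-level follicle cohort
#'
#' Draws per-stage follicle volumes from stage-specific lognormals whose
#' medians and interquartile ranges follow the reported porcine per-stage
#' statistics (primary median 4.4e-4 mm^3, antral 1.6e-2 mm^3, Graafian
#' 0.54 mm^3), then derives asymmetry and wall thickness with inverse
#' log-volume trends plus Gaussian noise, and oocyte diameters from a
#' saturating growth curve. This is a statistics-level simulator used to
#' exercise the cohort machinery; it does not render images.
#'
#' @param n_per_stage follicles per stage.
#' @param seed RNG seed.
#' @param asym_slope,thick_slope generating slopes per decade of volume.
#' @return data.frame with stage, volume, diameter, asymmetry, thickness and
#'   oocyte diameter columns; generating parameters attached as attribute
#'   `"params"`.
#' @export
simulate_cohort_measurements <- function(n_per_stage = c(primary = 20, antral = 20,
                                                         Graafian = 20),
                                         seed = 1L,
                                         asym_slope = -0.13, thick_slope = -13.6) {
  med <- c(primary = 4.4e-4, antral = 1.6e-2, Graafian = 0.54)
  iqr_hi <- c(primary = 5.0e-4, antral = 3.8e-2, Graafian = 2.63)
  iqr_lo <- c(primary = 3.0e-4, antral = 2.9e-3, Graafian = 0.15)
  sdlog <- (log(iqr_hi) - log(iqr_lo)) / (2 * stats::qnorm(0.75))
  with_seed(seed, {
    rows <- lapply(names(n_per_stage), function(s) {
      n <- n_per_stage[[s]]
      v <- stats::rlnorm(n, meanlog = log(med[[s]]), sdlog = sdlog[[s]])
      data.frame(stage = s, volume_mm3 = v)
    })
    df <- do.call(rbind, rows)
    df$equivalent_diameter_um <- equivalent_diameter(df$volume_mm3)
    lv <- log10(df$volume_mm3)
    df$asymmetry <- pmax(1, 1 + 0.08 + asym_slope * lv + rnorm(nrow(df), 0, 0.06))
    df$thickness_mean_um <- pmax(20, 95.5 + thick_slope * lv + rnorm(nrow(df), 0, 8))
    df$thickness_mean_um[df$stage == "primary"] <- NA_real_
    a <- 125; b <- 180
    df$oocyte_diameter_um <- pmax(
      15, a * df$equivalent_diameter_um / (b + df$equivalent_diameter_um) +
        rnorm(nrow(df), 0, 6))
    attr(df, "params") <- list(median_mm3 = med, sdlog = sdlog,
                               asym = c(0.08 + 1, asym_slope),
                               thick = c(95.5, thick_slope),
                               oocyte = c(a = a, b = b))
    df
  })
}
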