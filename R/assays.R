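#' One-site saturation binding fit
#'
#' Fits the one-site specific-binding hyperbola B(x) = Bmax * x / (Kd + x)
#' to a saturation curve by nonlinear least squares (Levenberg-Marquardt).
#' Initial values are Bmax0 = max response and Kd0 = the concentration at
#' half-maximal response, interpolated from the per-concentration means.
#' Standard errors come from the Jacobian-based covariance at the optimum.
#'
#' @param conc Ligand concentrations (e.g. nM), >= 0, at least 4 distinct
#'   values.
#' @param response Measured responses (e.g. A490), same length as `conc`;
#'   replicates are simply repeated (conc, response) rows.
#' @param background `"none"` (default) or `"shared_intercept"`, which adds
#'   a fitted constant c0 for plates with a nonzero blank.
#' @return A `binding_fit`: list with `Kd`, `Bmax`, `se_Kd`, `se_Bmax`,
#'   (`c0`, `se_c0` for the intercept variant), `converged`, and `fit` (the
#'   underlying `nls` object).
#' @export
fit_saturation <- function(conc, response,
                           background = c("none", "shared_intercept")) {
  background <- match.arg(background)
  if (length(conc) != length(response)) stop("conc/response length mismatch")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  if (diff(range(response)) == 0) stop("responses are all equal")
  mu <- tapply(response, conc, mean)
  cu <- as.numeric(names(mu))
  bmax0 <- max(mu)
  half <- bmax0 / 2
  above <- which(mu >= half)
  kd0 <- if (length(above) > 0L && min(above) > 1L) {
    i <- min(above)
    stats::approx(mu[(i - 1):i], cu[(i - 1):i], xout = half)$y
  } else {
    stats::median(cu)
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(cu[cu > 0])
  dat <- data.frame(x = conc, y = response)
  fml <- if (background == "none") {
    y ~ Bmax * x / (Kd + x)
  } else {
    y ~ c0 + Bmax * x / (Kd + x)
  }
  start <- if (background == "none") {
    list(Bmax = bmax0, Kd = kd0)
  } else {
    list(c0 = min(mu), Bmax = bmax0 - min(mu), Kd = kd0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      lower = c(rep(-Inf, length(start) - 2), 1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(Kd = NA_real_, Bmax = NA_real_, se_Kd = NA_real_,
                          se_Bmax = NA_real_, converged = FALSE, fit = NULL),
                     class = "binding_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    rep(NA_real_, length(cf))
  })
  out <- list(Kd = unname(cf["Kd"]), Bmax = unname(cf["Bmax"]),
              se_Kd = unname(se["Kd"]), se_Bmax = unname(se["Bmax"]),
              converged = isTRUE(fit$convInfo$isConv))
  if (background == "shared_intercept") {
    out$c0 <- unname(cf["c0"])
    out$se_c0 <- unname(se["c0"])
  }
  out$fit <- fit
  structure(out, class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-site binding fit: Kd =", signif(x$Kd, 4), "+/-",
      signif(x$se_Kd, 3), " Bmax =", signif(x$Bmax, 4),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

round_half_away <- function(x, decimals) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Fold change between two positive quantities
#'
#' Computes `value / reference`. With `decimals` given, the ratio is rounded
#' for reporting: `"half_up"` rounds half away from zero; `"trunc"`
#' truncates towards zero (some published fold columns are truncations of
#' the underlying ratio, so both conventions are exposed).
#'
#' @param value,reference Positive numbers (e.g. mutant and wild-type Kd).
#' @param decimals Integer number of decimals, or `NULL` (default) for the
#'   exact ratio.
#' @param mode Rounding convention, `"half_up"` or `"trunc"`.
#' @return The (optionally rounded) ratio.
#' @export
fold_change <- function(value, reference, decimals = NULL,
                        mode = c("half_up", "trunc")) {
  mode <- match.arg(mode)
  if (any(value <= 0) || any(reference <= 0)) {
    stop("fold_change requires positive inputs")
  }
  r <- value / reference
  if (is.null(decimals)) return(r)
  if (mode == "half_up") {
    round_half_away(r, decimals)
  } else {
    trunc(r * 10^decimals) / 10^decimals
  }
}

#' Probit dose-response fit with Fieller fiducial limits
#'
#' Maximum-likelihood binomial regression with a probit link on log10(dose).
#' The median lethal concentration is LC50 = 10^(-intercept/slope); its 95
#' percent fiducial limits come from Fieller's theorem on the parameter
#' ratio, including the g-correction. Mirroring Polo-style output, a
#' heterogeneity factor (Pearson chi-square / df) inflates the covariance
#' and switches the reference quantile from normal to Student t when the
#' chi-square lack-of-fit test is significant at 0.05. Natural-mortality
#' (Abbott) correction is optional and off by default.
#'
#' @param dose Doses (> 0), at least 3 distinct values.
#' @param n Number of exposed subjects per dose.
#' @param dead Number of dead per dose.
#' @param conf Confidence level for the fiducial limits (default 0.95).
#' @param control_mortality Optional natural-mortality fraction in `[0, 1)`;
#'   when given, observed kill proportions are Abbott-corrected before
#'   fitting.
#' @return A `probit_fit`: list with `lc50`, `fiducial` (lower, upper),
#'   `slope`, `intercept`, `se_slope`, `vcov`, `heterogeneity`, `g`,
#'   `converged`.
#' @export
fit_probit <- function(dose, n, dead, conf = 0.95, control_mortality = NULL) {
  if (any(dose <= 0)) stop("doses must be > 0")
  if (any(dead < 0 | dead > n)) stop("need 0 <= dead <= n")
  if (length(unique(dose)) < 3L) stop("need at least 3 distinct doses")
  if (all(dead == 0 | dead == n)) {
    stop("all-or-nothing mortality at every dose: ",
         "the likelihood has no finite maximum (complete separation)")
  }
  if (!is.null(control_mortality)) {
    stopifnot(control_mortality >= 0, control_mortality < 1)
    p <- pmax(0, (dead / n - control_mortality) / (1 - control_mortality))
    dead <- p * n
  }
  ld <- log10(dose)
  fit <- suppressWarnings(
    stats::glm(cbind(dead, n - dead) ~ ld,
               family = stats::binomial(link = "probit")))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  V <- stats::vcov(fit)
  k <- length(dose)
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df <- k - 2L
  het <- if (df > 0) pearson / df else NA_real_
  use_het <- is.finite(het) && het > 1 &&
    stats::pchisq(pearson, df, lower.tail = FALSE) < 0.05
  if (use_het) {
    V <- V * het
    q <- stats::qt(1 - (1 - conf) / 2, df)
  } else {
    q <- stats::qnorm(1 - (1 - conf) / 2)
  }
  m <- -a / b
  lc50 <- 10^m
  fid <- c(NA_real_, NA_real_)
  g <- NA_real_
  if (b <= 0) {
    warning("non-positive probit slope; fiducial limits undefined")
  } else {
    vnn <- V[1, 1]            # Var(-a)
    vdd <- V[2, 2]            # Var(b)
    cnd <- -V[1, 2]           # Cov(-a, b)
    g <- q^2 * vdd / b^2
    if (g >= 1) {
      warning("g >= 1: slope too poorly determined for finite limits")
    } else {
      disc <- vnn - 2 * m * cnd + m^2 * vdd - g * (vnn - cnd^2 / vdd)
      half <- (q / b) * sqrt(max(0, disc))
      centre <- m - g * cnd / vdd
      fid <- 10^((centre + c(-half, half)) / (1 - g))
    }
  }
  structure(list(lc50 = lc50, fiducial = fid, slope = b, intercept = a,
                 se_slope = sqrt(V[2, 2]),
                 vcov = V, heterogeneity = het, g = g,
                 converged = fit$converged),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit fit: LC50 =", signif(x$lc50, 4), " (",
      signif(x$fiducial[1], 4), "-", signif(x$fiducial[2], 4),
      "), slope =", signif(x$slope, 4), "\n")
  invisible(x)
}

#' Mortality rate from treated vs control cell counts
#'
#' Mortality is the relative reduction in mean cell count:
#' (1 - mean(treated) / mean(control)) * 100 percent. It may be negative if
#' the treated wells outgrow the controls. The standard error propagates
#' the two group means' standard errors through the ratio.
#'
#' @param treated,control Per-image cell counts.
#' @return List with `mortality_pct` and `se`.
#' @export
mortality_rate <- function(treated, control) {
  if (length(treated) == 0L || length(control) == 0L) {
    stop("both groups must be non-empty")
  }
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be > 0")
  mt <- mean(treated)
  se_t <- stats::sd(treated) / sqrt(length(treated))
  se_c <- stats::sd(control) / sqrt(length(control))
  if (length(treated) == 1L) se_t <- 0
  if (length(control) == 1L) se_c <- 0
  se <- 100 / mc * sqrt(se_t^2 + (mt / mc)^2 * se_c^2)
  list(mortality_pct = (1 - mt / mc) * 100, se = se)
}

stars_from_p <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Cell-size summary with significance stars
#'
#' Mean area per group (sum of areas / number of cells) with standard
#' errors, compared by Welch's two-sample t-test; the p-value is mapped to
#' the conventional star categories (*** < 0.001, ** < 0.01, * < 0.05, ns
#' otherwise).
#'
#' @param areas_control,areas_treated Per-cell areas, >= 2 cells each.
#' @param var_equal Pooled-variance t-test instead of Welch (default
#'   `FALSE`).
#' @return A `cytotox_summary`: list with `mean_control`, `mean_treated`,
#'   `se_control`, `se_treated`, `p_value`, `stars`.
#' @export
size_summary <- function(areas_control, areas_treated, var_equal = FALSE) {
  if (length(areas_control) < 2L || length(areas_treated) < 2L) {
    stop("need at least 2 cells per group")
  }
  tt <- tryCatch(
    stats::t.test(areas_treated, areas_control, var.equal = var_equal),
    error = function(e) list(p.value = NA_real_))
  structure(list(
    mean_control = mean(areas_control),
    mean_treated = mean(areas_treated),
    se_control = stats::sd(areas_control) / sqrt(length(areas_control)),
    se_treated = stats::sd(areas_treated) / sqrt(length(areas_treated)),
    p_value = tt$p.value,
    stars = stars_from_p(tt$p.value)
  ), class = "cytotox_summary")
}
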