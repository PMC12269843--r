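#' Fit a steady-state one-site binding model to SPR equilibrium responses
#'
#' Fits `R_eq(C) = Rmax * C / (KD + C)` to equilibrium surface plasmon
#' resonance responses by unweighted nonlinear least squares. Replicate
#' points are fitted jointly (pooled) by default, mirroring affinity
#' determination from independent experiments run in duplicate; set
#' `pool = FALSE` for per-replicate fits. Standard errors come from the
#' Jacobian at the optimum. Inputs are assumed reference-cell subtracted.
#'
#' @param data Data frame with columns `concentration_uM` (strictly
#'   positive), `response` (RU) and optionally `replicate`.
#' @param pool Fit all replicates jointly (default) or one fit per
#'   replicate.
#' @return A `kd_fit` object (or a tibble of per-replicate `glance` rows when
#'   `pool = FALSE`): estimates `kd` (uM), `rmax` (RU), standard errors,
#'   residual sum of squares and a convergence flag. Non-convergence is
#'   flagged, never silent.
#' @export
#' @examples
#' curve <- simulate_spr(kd = 10, rmax = 100, noise_sd = 0, seed = 1)
#' glance(fit_steady_state(curve))
fit_steady_state <- function(data, pool = TRUE) {
  data <- validate_binding_curve(data)
  if (!pool) {
    out <- data %>%
      group_by(.data$replicate) %>%
      dplyr::group_modify(~ glance(fit_steady_state(.x, pool = TRUE))) %>%
      ungroup()
    return(out)
  }
  conc <- data$concentration_uM
  resp <- data$response
  kd0 <- conc[which.min(abs(resp - max(resp) / 2))]
  start <- list(rmax = 1.1 * max(resp), kd = max(kd0, min(conc)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ rmax * concentration_uM / (kd + concentration_uM),
      data = data, start = start,
      lower = c(rmax = 1e-8, kd = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(kd = NA_real_, rmax = NA_real_, se_kd = NA_real_,
           se_rmax = NA_real_, rss = NA_real_, converged = FALSE,
           diagnostics = conditionMessage(fit), n = nrow(data), data = data,
           fit = NULL),
      class = "kd_fit"
    ))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(
    list(
      kd = unname(est["kd"]), rmax = unname(est["rmax"]),
      se_kd = unname(se["kd"]), se_rmax = unname(se["rmax"]),
      rss = sum(stats::resid(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      diagnostics = "",
      n = nrow(data), data = data, fit = fit
    ),
    class = "kd_fit"
  )
}

validate_binding_curve <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("concentration_uM", "response") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (any(!is.finite(data$concentration_uM)) ||
      any(data$concentration_uM <= 0)) {
    abort("Concentrations must be finite and strictly positive")
  }
  if (any(!is.finite(data$response))) abort("Responses must be finite")
  if (dplyr::n_distinct(data$concentration_uM) < 5) {
    abort("Need at least 5 distinct concentrations to fit")
  }
  span <- range(data$concentration_uM)
  if (span[2] / span[1] < 10) {
    warn("Concentration series spans less than one order of magnitude")
  }
  data
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged && is.na(x$kd)) {
    cat("Steady-state fit FAILED:", x$diagnostics, "\n")
  } else {
    cat(sprintf("One-site steady-state fit (n = %d): KD = %.3g +/- %.2g uM, Rmax = %.3g +/- %.2g RU\n",
                x$n, x$kd, x$se_kd, x$rmax, x$se_rmax))
  }
  invisible(x)
}

#' @describeIn fit_steady_state Term/estimate/std.error tibble.
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble(term = c("kd", "rmax"),
         estimate = c(x$kd, x$rmax),
         std.error = c(x$se_kd, x$se_rmax))
}

#' @describeIn fit_steady_state One-row fit summary.
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(kd = x$kd, rmax = x$rmax, se_kd = x$se_kd, se_rmax = x$se_rmax,
         rss = x$rss, n = x$n, converged = x$converged)
}

#' Classify mutational impact from affinity fold change
#'
#' Bins the affinity fold change `kd_mut / kd_wt` of a mutant receptor into
#' the four-category taxonomy used for alanine-scanning interface residues:
#' fold < 2 `no_effect`, 2-5 `moderate`, 5-10 `severe`, >= 10 `deleterious`.
#' Bins are left-closed (a fold of exactly 5 is `severe`). Improved affinity
#' (fold < 1) is `no_effect` with an `improved` note.
#'
#' @param kd_mut,kd_wt Mutant and wild-type dissociation constants (same
#'   units, strictly positive; vectorized over `kd_mut`).
#' @return Tibble with `fold`, `label` (ordered factor) and `note`.
#' @export
#' @examples
#' classify_impact(50, 25.8)    # ~1.94-fold: no_effect
#' classify_impact(c(60, 300), 25.8)
classify_impact <- function(kd_mut, kd_wt) {
  if (any(!is.finite(kd_mut)) || any(!is.finite(kd_wt)) ||
      any(kd_mut <= 0) || any(kd_wt <= 0)) {
    abort("Domain error: dissociation constants must be positive and finite")
  }
  fold <- kd_mut / kd_wt
  label <- dplyr::case_when(
    fold < 2 ~ "no_effect",
    fold < 5 ~ "moderate",
    fold < 10 ~ "severe",
    TRUE ~ "deleterious"
  )
  tibble(
    fold = fold,
    label = factor(label, levels = c("no_effect", "moderate", "severe",
                                     "deleterious")),
    note = ifelse(fold < 1, "improved", "")
  )
}

#' Normalize raw polarization to relative binding percent
#'
#' Linear map anchoring the uninhibited control to 100% and the
#' fully-inhibited (zero-binding) control to 0%, giving the normalized
#' relative binding used in competition assays. Invariant under any affine
#' transform applied to both the readings and the controls.
#'
#' @param data Data frame with columns `competitor_conc_uM` and
#'   `polarization` (and optionally `replicate`).
#' @param zero_ctrl Polarization at zero binding (full inhibition).
#' @param full_ctrl Polarization of the uninhibited control.
#' @return Tibble with `competitor_conc_uM`, `normalized_binding` (%) and
#'   `replicate`.
#' @export
normalize_relative_binding <- function(data, zero_ctrl, full_ctrl) {
  if (isTRUE(all.equal(zero_ctrl, full_ctrl))) {
    abort("Normalization error: controls are equal")
  }
  data <- as_tibble(data)
  stopifnot(all(c("competitor_conc_uM", "polarization") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  tibble(
    competitor_conc_uM = data$competitor_conc_uM,
    normalized_binding = 100 * (data$polarization - zero_ctrl) /
      (full_ctrl - zero_ctrl),
    replicate = data$replicate
  )
}

#' Fit a sigmoidal dose-response (4PL) competition curve
#'
#' Fits the four-parameter logistic
#' `y(C) = bottom + (top - bottom) / (1 + (C / ic50)^hill)` to normalized
#' relative binding versus competitor concentration and reads the IC50 as
#' the concentration giving 50% inhibition. With `hill = 1`, `bottom = 0`,
#' `top = 100` this degenerates to the one-site binding isotherm. When no
#' inhibition is resolved within the tested range the IC50 is flagged
#' unbounded and reported as greater than the highest tested concentration;
#' a fitted bottom plateau above `full_inhibition_floor` flags
#' `reached_full_inhibition = FALSE`.
#'
#' @param data Data frame with columns `competitor_conc_uM` (positive, >= 6
#'   distinct values) and `normalized_binding` (%).
#' @param full_inhibition_floor Residual-binding ceiling (%) below which the
#'   curve is considered to reach full inhibition (default 20).
#' @return An `ic50_fit` object: `ic50` (uM), `hill`, `top`, `bottom`,
#'   standard errors, `reached_full_inhibition`, `ic50_gt_max` and the
#'   maximum tested concentration.
#' @export
fit_competition <- function(data, full_inhibition_floor = 20) {
  data <- as_tibble(data)
  stopifnot(all(c("competitor_conc_uM", "normalized_binding") %in%
                  names(data)))
  conc <- data$competitor_conc_uM
  if (any(conc <= 0) || dplyr::n_distinct(conc) < 6) {
    abort("Need >= 6 distinct positive competitor concentrations")
  }
  y <- data$normalized_binding
  max_tested <- max(conc)
  # monotonicity sanity check: binding should fall with competitor, beyond
  # noise
  lo <- mean(y[conc >= quantile(conc, 0.75)])
  hi <- mean(y[conc <= quantile(conc, 0.25)])
  if (lo > hi + 2 * sd(y)) warn("Binding increases with competitor")
  start <- list(
    top = max(y), bottom = max(min(y), 0),
    ic50 = exp(mean(log(conc))), hill = 1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      normalized_binding ~ bottom + (top - bottom) /
        (1 + (competitor_conc_uM / ic50)^hill),
      data = data, start = start,
      lower = c(top = 0, bottom = 0, ic50 = 1e-6, hill = 0.1),
      upper = c(top = 200, bottom = 150, ic50 = 1e6, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
           bottom = NA_real_, se_ic50 = NA_real_,
           reached_full_inhibition = FALSE, ic50_gt_max = TRUE,
           max_tested = max_tested, converged = FALSE,
           diagnostics = conditionMessage(fit), data = data, fit = NULL),
      class = "ic50_fit"
    ))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ic50 <- unname(est["ic50"])
  bottom <- unname(est["bottom"])
  top <- unname(est["top"])
  # inhibition at the top tested concentration under the fitted curve; if
  # the curve never falls below 50% of control, IC50 is not resolved
  y_end <- bottom + (top - bottom) / (1 + (max_tested / ic50)^est["hill"])
  gt_max <- ic50 > max_tested || y_end > 50
  structure(
    list(
      ic50 = ic50, hill = unname(est["hill"]), top = top, bottom = bottom,
      se_ic50 = unname(se["ic50"]),
      reached_full_inhibition = bottom <= full_inhibition_floor,
      ic50_gt_max = gt_max, max_tested = max_tested,
      converged = TRUE, diagnostics = "", data = data, fit = fit
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Competition fit FAILED:", x$diagnostics, "\n")
  } else if (x$ic50_gt_max) {
    cat(sprintf("IC50 > %g uM (not resolved within tested range)\n",
                x$max_tested))
  } else {
    cat(sprintf("4PL competition fit: IC50 = %.3g +/- %.2g uM (hill %.2f, plateau %.1f%%)\n",
                x$ic50, x$se_ic50, x$hill, x$bottom))
  }
  if (!x$reached_full_inhibition && x$converged) {
    cat("  note: curve does not reach full inhibition\n")
  }
  invisible(x)
}

#' @describeIn fit_competition Parameter tibble.
#' @param x An `ic50_fit` object.
#' @param ... Unused.
#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @describeIn fit_competition One-row fit summary, with `ic50_label` of the
#'   form `"> 500"` when unresolved.
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, se_ic50 = x$se_ic50, hill = x$hill, top = x$top,
    bottom = x$bottom,
    reached_full_inhibition = x$reached_full_inhibition,
    ic50_gt_max = x$ic50_gt_max,
    ic50_label = if (isTRUE(x$ic50_gt_max)) paste0("> ", x$max_tested)
    else formatC(x$ic50, digits = 3, format = "g"),
    converged = x$converged
  )
}
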