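#' Linear mixed model for group comparisons with a plot random effect
#'
#' Fits `response ~ group + (1 | plot)` by REML, the standard model for
#' plot-based isotope surveys: plant identity (taxon/phenotype, including
#' the pooled reference plants) is the fixed factor and the sampling plot
#' a random intercept, absorbing shared microsite variation. When the
#' data contain a single plot, or the mixed fit fails, the model reduces
#' to ordinary least squares with zero plot variance — in that case the
#' fixed-effect group means equal the OLS group means exactly.
#'
#' @param data Data frame of samples or enrichment records.
#' @param response Name of the response column, one of `delta13C`,
#'   `delta15N`, `eps13C`, `eps15N` (any numeric column is accepted).
#' @param group,plot Names of the fixed-factor and random-grouping
#'   columns (defaults `"group"`, `"plot_id"`).
#' @return An object of class `group_lmm`: a list with the fitted model,
#'   per-level group means and their covariance, variance components
#'   (`plot_variance`, `residual_variance`, per mil squared), the
#'   contrast degrees of freedom, and bookkeeping (`n_obs`, `n_plots`,
#'   `singular`). Internally the fixed factor uses treatment
#'   (reference-level) coding; reported coefficients are transformed to
#'   per-level group means.
#' @seealso [tukey_kramer()] for post-hoc contrasts; [tidy.group_lmm()]
#'   and [glance.group_lmm()] for tabular summaries.
#' @export
fit_group_lmm <- function(data, response, group = "group", plot = "plot_id") {
  if (!is.data.frame(data)) stop_invalid("`data` must be a data frame.")
  for (col in c(response, group, plot)) {
    if (!col %in% names(data)) {
      stop_invalid(sprintf("Column `%s` not found.", col))
    }
  }
  df <- tibble(
    y = as.numeric(data[[response]]),
    g = factor(data[[group]]),
    p = factor(data[[plot]])
  )
  df <- df[is.finite(df$y), , drop = FALSE]
  if (nrow(df) < 2) stop_invalid("Need at least 2 observations.")
  if (nlevels(droplevels(df$g)) < 2) {
    stop_invalid("Need at least 2 groups to compare.")
  }
  df$g <- droplevels(df$g)
  df$p <- droplevels(df$p)
  levels_g <- levels(df$g)
  n_obs <- nrow(df)
  n_plots <- nlevels(df$p)

  fit <- NULL
  singular <- FALSE
  messages <- character()
  if (n_plots >= 2) {
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(
          y ~ g + (1 | p), data = df, REML = TRUE,
          control = lme4::lmerControl(
            check.conv.singular = "ignore",
            optCtrl = list(FtolAbs = 1e-8, FtolRel = 1e-8)
          )
        ),
        error = function(e) {
          messages <<- c(messages, conditionMessage(e))
          NULL
        }
      ),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        messages <<- c(messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }

  extracted <- NULL
  if (!is.null(fit)) {
    # extraction can fail on degenerate fits (e.g. zero residual
    # variance); treat that like a failed mixed fit
    extracted <- tryCatch(
      list(
        singular = lme4::isSingular(fit, tol = 1e-6),
        beta = lme4::fixef(fit),
        vbeta = as.matrix(vcov(fit)),
        vc = as.data.frame(lme4::VarCorr(fit))
      ),
      error = function(e) {
        messages <<- c(messages, conditionMessage(e))
        NULL
      }
    )
    if (is.null(extracted)) fit <- NULL
  }

  if (!is.null(extracted)) {
    singular <- extracted$singular
    beta <- extracted$beta
    vbeta <- extracted$vbeta
    vc <- extracted$vc
    plot_var <- vc$vcov[vc$grp == "p"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
  } else {
    # Single plot (or failed mixed fit): plot variance is not estimable
    # and is reported as 0; fixed effects are the OLS solution.
    fit <- lm(y ~ g, data = df)
    beta <- coef(fit)
    vbeta <- vcov(fit)
    plot_var <- 0
    resid_var <- summary(fit)$sigma^2
    if (n_plots >= 2) {
      warn(paste(
        "Mixed-model fit failed; falling back to ordinary least squares:",
        paste(messages, collapse = "; ")
      ))
    }
  }

  # Treatment coding -> per-level means: mu = C beta with C = [1 | e_i].
  k <- length(levels_g)
  C <- cbind(1, rbind(0, diag(k - 1)))
  rownames(C) <- levels_g
  mu <- drop(C %*% beta)
  vmu <- C %*% vbeta %*% t(C)

  # Containment-style residual df for contrasts: observations minus fixed
  # effect levels minus the (n_plots - 1) plot effects.
  df_contrast <- max(n_obs - k - (n_plots - 1), 1)

  structure(
    list(
      model = fit,
      response = response,
      fixed_levels = levels_g,
      coefficients = setNames(mu, levels_g),
      vcov_means = vmu,
      plot_variance = as.numeric(plot_var),
      residual_variance = as.numeric(resid_var),
      n_obs = n_obs,
      n_plots = n_plots,
      df_contrast = df_contrast,
      singular = singular,
      mixed = inherits(fit, "merMod"),
      fit_messages = messages
    ),
    class = "group_lmm"
  )
}

#' @export
print.group_lmm <- function(x, ...) {
  cat(sprintf(
    "Linear mixed model: %s ~ group + (1 | plot)%s\n",
    x$response, if (x$mixed) "" else "  [OLS fallback: single plot]"
  ))
  cat(sprintf(
    "  %d observations, %d plots; plot variance %.4g, residual variance %.4g\n",
    x$n_obs, x$n_plots, x$plot_variance, x$residual_variance
  ))
  cat("  Group means (per mil):\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Tidy a fitted group mixed model
#'
#' @param x A `group_lmm` object from [fit_group_lmm()].
#' @param ... Unused.
#' @return A tibble with one row per group level: `group`, `estimate`
#'   (model-based group mean), `std_error`.
#' @method tidy group_lmm
#' @export
tidy.group_lmm <- function(x, ...) {
  tibble(
    group = x$fixed_levels,
    estimate = unname(x$coefficients),
    std_error = sqrt(diag(x$vcov_means))
  )
}

#' @rdname tidy.group_lmm
#' @return For `glance()`: a one-row tibble with the variance components
#'   and fit bookkeeping.
#' @method glance group_lmm
#' @export
glance.group_lmm <- function(x, ...) {
  tibble(
    response = x$response,
    n_obs = x$n_obs,
    n_plots = x$n_plots,
    n_groups = length(x$fixed_levels),
    plot_variance = x$plot_variance,
    residual_variance = x$residual_variance,
    singular = x$singular,
    REML = x$mixed
  )
}

#' Tukey-Kramer all-pairwise contrasts
#'
#' Computes all pairwise differences between model-based group means with
#' single-step family-wise adjusted p-values. The adjustment integrates
#' the joint multivariate t distribution of the contrasts (the
#' Tukey-Kramer generalization to unequal group sizes and correlated
#' estimates), using the fitted covariance of the fixed effects and
#' containment-style residual degrees of freedom. With exactly two groups
#' the adjusted p-value equals the unadjusted one.
#'
#' @param fit A `group_lmm` object from [fit_group_lmm()].
#' @return A tibble of class `tukey_contrasts` with columns `group_a`,
#'   `group_b`, `estimate` (a minus b, per mil), `std_error`, `statistic`,
#'   `adj_p`.
#' @export
tukey_kramer <- function(fit) {
  if (!inherits(fit, "group_lmm")) {
    stop_invalid("`fit` must be a `group_lmm` object.")
  }
  k <- length(fit$fixed_levels)
  if (k < 2) stop_invalid("Need at least 2 groups for contrasts.")
  counts <- setNames(rep(1L, k), fit$fixed_levels)
  K <- multcomp::contrMat(counts, type = "Tukey")
  pairs <- strsplit(rownames(K), " - ", fixed = TRUE)
  est <- drop(K %*% fit$coefficients)
  se <- sqrt(diag(K %*% fit$vcov_means %*% t(K)))
  if (all(se < 1e-12)) {
    # degenerate fit (zero response variance): resolve by convention
    out <- tibble(
      group_a = vapply(pairs, `[[`, character(1), 1),
      group_b = vapply(pairs, `[[`, character(1), 2),
      estimate = unname(est),
      std_error = unname(se),
      statistic = ifelse(abs(est) < 1e-12, 0, sign(est) * Inf),
      adj_p = ifelse(abs(est) < 1e-12, 1, 0)
    )
    class(out) <- c("tukey_contrasts", class(out))
    return(out)
  }
  gl <- multcomp::glht(
    multcomp::parm(fit$coefficients, fit$vcov_means, df = fit$df_contrast),
    linfct = K
  )
  sm <- summary(gl, test = multcomp::adjusted("single-step"))
  out <- tibble(
    group_a = vapply(pairs, `[[`, character(1), 1),
    group_b = vapply(pairs, `[[`, character(1), 2),
    estimate = unname(sm$test$coefficients),
    std_error = unname(sm$test$sigma),
    statistic = unname(sm$test$tstat),
    adj_p = pmin(pmax(as.numeric(sm$test$pvalues), 0), 1)
  )
  class(out) <- c("tukey_contrasts", class(out))
  out
}

#' Two-sample t-test, classic or Welch
#'
#' Pooled-variance (Student's) two-sample t-test by default, matching how
#' physiological traits (chlorophyll concentration, Fv/Fm) are compared
#' between two phenotypes; Welch's unequal-variance form is available via
#' `welch = TRUE`. Degenerate zero-variance inputs are resolved by
#' convention: identical constant samples give t = 0, p = 1; constant
#' samples with different means give p = 0.
#'
#' @param a,b Numeric vectors of measurements, each of length >= 2.
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("Each sample needs at least 2 observations.")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_invalid("Samples must be finite.")
  }
  method <- if (welch) "Welch two-sample t" else "Student pooled-variance t"
  if (var(a) == 0 && var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a), mean_b = mean(b), method = method
    ))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b), method = method
  )
}

#' @describeIn two_sample_t Same test from published summary statistics
#'   (mean, SD, n per group) when raw values are unavailable.
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group sample standard deviations.
#' @param n_a,n_b Group sizes (each >= 2).
#' @export
two_sample_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 welch = FALSE) {
  if (n_a < 2 || n_b < 2) stop_invalid("Each sample needs n >= 2.")
  if (sd_a < 0 || sd_b < 0) stop_invalid("Standard deviations must be >= 0.")
  method <- if (welch) "Welch two-sample t" else "Student pooled-variance t"
  if (sd_a == 0 && sd_b == 0) {
    equal <- isTRUE(all.equal(mean_a, mean_b))
    return(tibble(
      statistic = if (equal) 0 else sign(mean_a - mean_b) * Inf,
      df = n_a + n_b - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean_a, mean_b = mean_b, method = method
    ))
  }
  if (welch) {
    se2a <- sd_a^2 / n_a
    se2b <- sd_b^2 / n_b
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (n_a - 1) + se2b^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t_stat <- (mean_a - mean_b) / se
  tibble(
    statistic = t_stat,
    df = df,
    p_value = 2 * pt(-abs(t_stat), df),
    mean_a = mean_a, mean_b = mean_b, method = method
  )
}
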