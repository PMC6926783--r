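# Group comparisons for the per-defect outcome tables: a Gaussian linear
# mixed model with fixed material-group effects and a per-animal random
# intercept (REML), Scheffe-adjusted pairwise contrasts, correlations, and
# the noncentral-F sample-size computation for a one-way fixed-effects
# ANOVA.

#' Fit a random-intercept model for a study outcome
#'
#' Fits `outcome ~ group + (1 | animal)` by REML. The random intercept is
#' the minimal structure encoding that the defects of one animal share that
#' animal; on balanced data the REML variance components coincide with the
#' expected-mean-squares solution of the animal-blocked ANOVA. Degenerate
#' noise-free tables (zero residual variance) are detected and resolved by
#' ordinary least squares with both variance components reported as zero.
#'
#' @param table data frame with columns `animal`, `group` and the outcome.
#' @param outcome name of the outcome column (default `"outcome"`).
#' @return An object of class `ri_fit`: group means, variance components
#'   `sigma2_animal` and `sigma2_resid`, the overall group F test (with
#'   denominator df from the blocked-design residual df), and Scheffe
#'   machinery inputs.
#' @export
fit_random_intercept <- function(table, outcome = "outcome") {
  if (!all(c("animal", "group", outcome) %in% names(table)))
    stop("table must contain 'animal', 'group' and the outcome column")
  table <- table[!is.na(table[[outcome]]), , drop = FALSE]
  table$animal <- factor(table$animal)
  table$group <- factor(table$group)
  if (nlevels(table$animal) < 2)
    stop("at least 2 animals are required; a single animal is degenerate")
  if (nlevels(table$group) < 2) stop("at least 2 groups are required")
  y <- table[[outcome]]
  k <- nlevels(table$group)
  n <- nrow(table)
  n_a <- nlevels(table$animal)
  # residual df of the animal-blocked design
  df_err <- n - n_a - k + 1
  if (df_err < 1) stop("not enough observations for a residual df")

  ols <- lm(y ~ group + animal, data = cbind(table, y = y))
  rss <- sum(resid(ols)^2)
  if (rss < 1e-10 * max(1, sum(y^2))) {
    # noise-free table: means are exact, both components zero
    mu <- tapply(y, table$group, mean)
    fit <- NULL
    s2a <- 0; s2e <- 0
    vc_warn <- FALSE
  } else {
    fml <- stats::as.formula(paste0("`", outcome, "` ~ group + (1 | animal)"))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = table, REML = TRUE),
      warning = function(w) {
        # the zero-boundary case is re-reported below in the package's terms
        if (grepl("boundary \\(singular\\)", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2a <- vc$vcov[vc$grp == "animal"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    vc_warn <- lme4::isSingular(fit, tol = 1e-8) && s2a <= 1e-8
    if (vc_warn)
      warning("animal variance component estimated at the zero boundary")
    beta <- lme4::fixef(fit)
    X <- matrix(0, k, k); X[, 1] <- 1
    if (k > 1) X[cbind(2:k, 2:k)] <- 1
    mu <- setNames(as.vector(X %*% beta), levels(table$group))
  }

  # per-group means and contrast variance from the within-animal error
  n_g <- table(table$group)
  grand <- tapply(y, table$group, mean)
  if (is.null(fit)) mu <- grand
  mu <- setNames(as.numeric(mu), levels(table$group))

  # overall group F test on the blocked layout
  ms_group <- sum(n_g * (grand - mean(y))^2) / (k - 1)
  if (is.null(fit)) {
    ms_err <- 0
    f_stat <- if (ms_group > 0) Inf else NaN
    p_overall <- if (ms_group > 0) 0 else NA_real_
  } else {
    ms_err <- rss / df_err
    f_stat <- ms_group / ms_err
    p_overall <- pf(f_stat, k - 1, df_err, lower.tail = FALSE)
  }

  res <- list(groups = levels(table$group),
              n_per_group = as.vector(n_g),
              group_means = mu,
              sigma2_animal = s2a,
              sigma2_resid = s2e,
              ms_error = ms_err,
              df_error = df_err,
              f_overall = f_stat,
              p_overall = p_overall,
              n_obs = n, n_animals = n_a,
              outcome = outcome,
              lmer_fit = fit)
  class(res) <- "ri_fit"
  res
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Random-intercept fit of '%s' (%d defects, %d animals)\n",
              x$outcome, x$n_obs, x$n_animals))
  cat("  group means:\n")
  for (g in seq_along(x$groups))
    cat(sprintf("    %-8s %8.3f  (n = %d)\n", x$groups[g], x$group_means[g],
                x$n_per_group[g]))
  cat(sprintf("  variance components: animal %.4f, residual %.4f\n",
              x$sigma2_animal, x$sigma2_resid))
  cat(sprintf("  group effect: F(%d, %d) = %.3f, p = %.4g\n",
              length(x$groups) - 1, x$df_error, x$f_overall, x$p_overall))
  invisible(x)
}

#' @export
coef.ri_fit <- function(object, ...) object$group_means

#' @export
summary.ri_fit <- function(object, ...) {
  out <- object
  out$scheffe <- scheffe_pairwise(object)
  class(out) <- "summary.ri_fit"
  out
}

#' @export
print.summary.ri_fit <- function(x, ...) {
  y <- x; class(y) <- "ri_fit"
  print(y)
  cat("  Scheffe pairwise comparisons:\n")
  print(x$scheffe, row.names = FALSE)
  invisible(x)
}

#' Scheffe-adjusted pairwise group comparisons
#'
#' For each pair of groups the contrast F statistic is referred to the
#' Scheffe criterion: `p = P(F(k-1, df_err) >= F_contrast / (k-1))`, using
#' the model's within-animal error variance and residual degrees of
#' freedom. Conservative for all contrasts by construction.
#'
#' @param fit an `ri_fit` from [fit_random_intercept()].
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `difference`, `f_contrast`, `p_scheffe`.
#' @export
scheffe_pairwise <- function(fit) {
  stopifnot(inherits(fit, "ri_fit"))
  k <- length(fit$groups)
  if (k < 2) stop("need at least 2 fitted groups")
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- fit$group_means[i1] - fit$group_means[i2]
    v <- fit$ms_error * (1 / fit$n_per_group[i1] + 1 / fit$n_per_group[i2])
    if (v <= 0) {
      # zero error variance: limit convention
      p <- if (abs(diff) > 0) 0 else 1
      fstat <- if (abs(diff) > 0) Inf else 0
      warning("zero error variance: Scheffe p-values set by limit convention")
    } else {
      fstat <- diff^2 / v
      p <- pf(fstat / (k - 1), k - 1, fit$df_error, lower.tail = FALSE)
    }
    data.frame(group1 = fit$groups[i1], group2 = fit$groups[i2],
               difference = unname(diff), f_contrast = unname(fstat),
               p_scheffe = unname(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between two study variables
#'
#' @param table study data frame.
#' @param x,y column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @export
correlate <- function(table, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- table[[x]]; yv <- table[[y]]
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (var(xv[ok]) == 0 || var(yv[ok]) == 0)
    stop("zero variance in ", if (var(xv[ok]) == 0) x else y)
  ct <- suppressWarnings(cor.test(xv[ok], yv[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), method = method)
}

#' One-way ANOVA power at a given total sample size
#'
#' Power of the fixed-effects one-way ANOVA F test with `k` equal groups,
#' Cohen effect size `f`, and noncentrality `lambda = f^2 N`:
#' `P(F'(k-1, N-k, lambda) >= F_crit(alpha; k-1, N-k))`.
#'
#' @param n_total total sample size (equal allocation assumed).
#' @param k number of groups.
#' @param f Cohen's effect size f.
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
anova_power <- function(n_total, k, f, alpha = 0.05) {
  stopifnot(k >= 2, f > 0, alpha > 0, alpha < 1, n_total > k)
  fcrit <- qf(1 - alpha, k - 1, n_total - k)
  pf(fcrit, k - 1, n_total - k, ncp = f^2 * n_total, lower.tail = FALSE)
}

#' Total sample size for a one-way ANOVA
#'
#' Smallest total N, in equal groups (N a multiple of `k`), such that the
#' one-way fixed-effects ANOVA attains the target power under the
#' noncentral F distribution with `lambda = f^2 N`. With `k = 3`,
#' `f = 0.6`, `alpha = 0.05` and power 0.8 this returns 30, the classical
#' a-priori computation for a three-arm design.
#'
#' @param k number of groups (>= 2).
#' @param f Cohen's effect size f (> 0).
#' @param alpha significance level.
#' @param power target power in `(0, 1)`.
#' @return Total sample size N (multiple of `k`).
#' @export
anova_sample_size <- function(k, f, alpha = 0.05, power = 0.8) {
  stopifnot(k >= 2, f > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- k * max(2L, ceiling((k + 1) / k))  # smallest N with positive error df
  while (n <= 1e6) {
    if (anova_power(n, k, f, alpha) >= power) return(as.integer(n))
    n <- n + k
  }
  stop("target power unattainable at N <= 1e6")
}
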