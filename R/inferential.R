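# Frequentist tests and the default Bayesian t-test.
#
# The Bayes factor follows the default (JZS) one-sample t-test: the effect
# size delta carries a Cauchy(0, r_scale) prior under H1 and the null fixes
# delta = 0. BF01 is the ratio of the central t density of the observed
# statistic to its marginal density under H1, the latter a one-dimensional
# integral of the noncentral t density over the Cauchy prior evaluated by
# adaptive quadrature (deterministic, unlike sampling-based evaluations of
# the same test, which agree to ~2 decimals).

#' Paired t-test
#'
#' Two-sided paired t-test wrapped around [stats::t.test()], returning the
#' statistic, degrees of freedom, p-value and mean difference.
#'
#' @param x,y equal-length per-subject measurements.
#' @return An object of class `t_test_result` with fields `t`, `df`, `p`,
#'   `mean_diff`, `n`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0 && !all(d == 0)) stop("zero variance of differences")
  if (sd(d) == 0) {
    # all differences exactly zero: t = 0 by convention, p = 1
    return(structure(list(t = 0, df = length(x) - 1L, p = 1, mean_diff = 0,
                          n = length(x)), class = "t_test_result"))
  }
  ht <- t.test(x, y, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate),
                 n = length(x)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4f, mean difference = %.4g\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' 2x2 repeated-measures ANOVA
#'
#' Fully within-subject two-by-two ANOVA (both factors at two levels), the
#' design used for session (drug vs. placebo) by cue (speed vs. accuracy)
#' comparisons. Fitted via [stats::aov()] with the error stratum
#' `Error(subject/(f1*f2))`; each effect is tested on (1, n-1) degrees of
#' freedom, and each F equals the square of the paired t on the matching
#' within-subject contrast.
#'
#' @param cells numeric matrix, one row per subject, four columns named
#'   `<f1 level>.<f2 level>` (e.g. `"drug.speed"`).
#' @param factor_names length-2 character vector naming the factors.
#' @return An object of class `anova_2x2` with per-effect `F`, `df`, `p`,
#'   and the cell means.
#' @export
rm_anova_2x2 <- function(cells, factor_names = c("session", "cue")) {
  if (is.null(dim(cells)) || ncol(cells) != 4) {
    stop("cells must be an n x 4 matrix")
  }
  if (anyNA(cells)) stop("missing cell values")
  if (nrow(cells) < 2) stop("need at least 2 subjects")
  lev <- strsplit(colnames(cells), ".", fixed = TRUE)
  if (any(lengths(lev) != 2)) stop("column names must be '<f1>.<f2>'")
  n <- nrow(cells)
  long <- data.frame(
    y = as.vector(cells),
    subject = factor(rep(seq_len(n), times = 4)),
    f1 = factor(rep(vapply(lev, `[`, "", 1), each = n)),
    f2 = factor(rep(vapply(lev, `[`, "", 2), each = n)))
  fit <- aov(y ~ f1 * f2 + Error(subject / (f1 * f2)), data = long)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    list(F = tab[i, "F value"], df = c(tab[i, "Df"], tab[nrow(tab), "Df"]),
         p = tab[i, "Pr(>F)"])
  }
  eff <- list(pull("Error: subject:f1", "f1"),
              pull("Error: subject:f2", "f2"),
              pull("Error: subject:f1:f2", "f1:f2"))
  names(eff) <- c(factor_names, paste(factor_names, collapse = ":"))
  structure(list(effects = eff,
                 cell_means = colMeans(cells),
                 n = n, factor_names = factor_names),
            class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (n = %d)\n", x$n))
  for (nm in names(x$effects)) {
    e <- x$effects[[nm]]
    cat(sprintf("  %-16s F(%d,%d) = %8.3f, p = %.4f\n",
                nm, e$df[1], e$df[2], e$F, e$p))
  }
  invisible(x)
}

#' Default Bayes factor BF01 for a one-sample t statistic
#'
#' Ratio of the marginal likelihood of the observed t statistic under the
#' point null to its marginal under the default alternative, where the
#' standardised effect size has a Cauchy(0, `r_scale`) prior: the numerator
#' is the central t density at `t` on n - 1 degrees of freedom, the
#' denominator integrates the noncentral t density over the prior by
#' adaptive quadrature.
#'
#' @param t observed t statistic.
#' @param n sample size (>= 2); degrees of freedom are n - 1.
#' @param r_scale Cauchy prior scale (default 1).
#' @param rel_tol relative tolerance of the quadrature.
#' @return BF01 (> 0); values above 1 favour the null.
#' @export
jzs_bayes_factor_01 <- function(t, n, r_scale = 1, rel_tol = 1e-8) {
  if (n < 2) stop("n must be >= 2")
  if (!is.finite(t)) stop("t must be finite")
  nu <- n - 1
  num <- dt(t, df = nu)
  den <- suppressWarnings(
    integrate(function(delta) {
      dt(t, df = nu, ncp = delta * sqrt(n)) * dcauchy(delta, 0, r_scale)
    }, lower = -Inf, upper = Inf, rel.tol = rel_tol, abs.tol = 0))
  if (den$message != "OK") stop("quadrature failed: ", den$message)
  num / den$value
}

#' Posterior probability of the null from a Bayes factor
#'
#' @param bf01 Bayes factor in favour of the null (> 0).
#' @param prior_h0 prior probability of the null in (0, 1); equal prior
#'   odds by default.
#' @return `prior_h0 * bf01 / (prior_h0 * bf01 + 1 - prior_h0)`.
#' @export
posterior_prob_h0 <- function(bf01, prior_h0 = 0.5) {
  if (any(bf01 <= 0)) stop("bf01 must be > 0")
  if (prior_h0 <= 0 || prior_h0 >= 1) stop("prior_h0 must be in (0, 1)")
  prior_h0 * bf01 / (prior_h0 * bf01 + 1 - prior_h0)
}

#' Default Bayesian one-sample t-test
#'
#' Computes the JZS Bayes factor and the posterior plausibility of the null,
#' either from raw difference scores (`x`, optionally minus `y` pairwise) or
#' directly from a t statistic and sample size.
#'
#' @param x per-subject values (difference scores for a paired design), or
#'   `NULL` when `t` and `n` are given.
#' @param y optional paired second measurement, subtracted from `x`.
#' @param t,n t statistic and sample size, used when `x` is `NULL`.
#' @param r_scale Cauchy prior scale for the effect size (default 1).
#' @param prior_h0 prior probability of the null (default 0.5).
#' @return An object of class `bayes_t_result` with fields `t`, `n`, `df`,
#'   `r_scale`, `bf01`, `prior_h0`, `posterior_h0`.
#' @export
bayes_t_test <- function(x = NULL, y = NULL, t = NULL, n = NULL,
                         r_scale = 1, prior_h0 = 0.5) {
  if (!is.null(x)) {
    d <- if (!is.null(y)) x - y else x
    if (length(d) < 2) stop("need at least 2 observations")
    if (sd(d) == 0) stop("zero variance")
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
  }
  if (is.null(t) || is.null(n)) stop("provide data x (and y) or both t and n")
  bf01 <- jzs_bayes_factor_01(t, n, r_scale)
  structure(list(t = t, n = n, df = n - 1L, r_scale = r_scale, bf01 = bf01,
                 prior_h0 = prior_h0,
                 posterior_h0 = posterior_prob_h0(bf01, prior_h0)),
            class = "bayes_t_result")
}

#' @export
print.bayes_t_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f | BF01 = %.3f | pBayes(H0) = %.3f (prior %.2f)\n",
              x$df, x$t, x$bf01, x$posterior_h0, x$prior_h0))
  invisible(x)
}

#' Pearson correlation screen with Bonferroni control
#'
#' Correlates each per-subject drug-effect measure with each trait covariate
#' and applies a Bonferroni-corrected alpha of `family_alpha` divided by the
#' number of comparisons. Zero-variance columns yield an undefined (NA)
#' correlation flagged in the report.
#'
#' @param effects data frame or matrix of per-subject effect measures
#'   (subjects in rows).
#' @param covariates data frame or matrix of per-subject trait scores.
#' @param family_alpha family-wise level (default 0.05).
#' @return An object of class `correlation_screen`: data frame of pairs with
#'   `r`, `p`, `significant`, plus `alpha_corrected` and `n_comparisons`.
#' @export
correlation_screen <- function(effects, covariates, family_alpha = 0.05) {
  effects <- as.data.frame(effects)
  covariates <- as.data.frame(covariates)
  if (nrow(effects) != nrow(covariates)) stop("unequal subject sets")
  if (nrow(effects) < 3) stop("need at least 3 subjects")
  n_comp <- ncol(effects) * ncol(covariates)
  alpha <- family_alpha / n_comp
  rows <- list()
  for (m in names(effects)) {
    for (cv in names(covariates)) {
      if (sd(effects[[m]]) == 0 || sd(covariates[[cv]]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, covariate = cv, r = NA_real_, p = NA_real_,
          significant = NA, undefined = TRUE)
      } else {
        ct <- cor.test(effects[[m]], covariates[[cv]], method = "pearson")
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, covariate = cv, r = unname(ct$estimate),
          p = ct$p.value, significant = ct$p.value < alpha, undefined = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 family_alpha = family_alpha,
                 alpha_corrected = alpha,
                 n_comparisons = n_comp),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("Correlation screen: %d comparisons, corrected alpha = %.4g\n",
              x$n_comparisons, x$alpha_corrected))
  print(x$table, row.names = FALSE)
  invisible(x)
}
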