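# Wiener diffusion first-passage machinery and chi-square quantile fitting.
#
# All first-passage formulas are evaluated in diffusion-coefficient-1 units
# (a' = a/s, z' = z/s, v' = v/s); time is untouched by the rescaling. The
# lower-boundary density uses the classic dual series: a small-time
# (image-sum) expansion and a large-time (sine-series) expansion, with the
# cheaper series picked per time point from truncation-error bounds. The
# defective CDF integrates the large-time series term by term.

#' Wiener diffusion parameters
#'
#' Core parameter set of the drift diffusion model for one condition:
#' boundary separation `a`, starting point `z`, mean drift `v`, across-trial
#' drift SD `eta`, non-decision time `ter` with across-trial range `st0`, and
#' diffusion coefficient `s` (a scaling constant, 0.1 by classic convention).
#' The upper boundary is the correct response (directions are collapsed, so
#' drift toward correct is positive by construction).
#'
#' @param a boundary separation (> 0, evidence units).
#' @param v mean drift rate (evidence/s).
#' @param ter non-decision time (s, >= 0).
#' @param z starting point (0 < z < a), default the unbiased midpoint.
#' @param eta across-trial SD of drift (>= 0).
#' @param st0 across-trial range of non-decision time (s, >= 0).
#' @param s diffusion coefficient (> 0).
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(a, v, ter, z = a / 2, eta = 0, st0 = 0, s = 0.1) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(z) || z <= 0 || z >= a) stop("z must satisfy 0 < z < a")
  if (!is.finite(ter) || ter < 0) stop("ter must be >= 0")
  if (!is.finite(eta) || eta < 0) stop("eta must be >= 0")
  if (!is.finite(st0) || st0 < 0) stop("st0 must be >= 0")
  if (!is.finite(s) || s <= 0) stop("s must be > 0")
  structure(list(a = a, v = v, ter = ter, z = z, eta = eta, st0 = st0, s = s),
            class = "ddm_params")
}

#' Per-session diffusion parameters with cue-specific threshold and Ter
#'
#' The fitted model: boundary separation and non-decision time free per cue
#' (speed vs. accuracy), drift and its variability shared, unbiased start
#' (`z_ratio = 0.5`) since stimulus directions are collapsed.
#'
#' @param a_speed,a_accuracy boundary separations per cue.
#' @param ter_speed,ter_accuracy non-decision times (s) per cue.
#' @param v shared mean drift; `eta` shared drift SD.
#' @param z_ratio starting point as a fraction of `a` (shared).
#' @param st0 across-trial Ter range (s); `s` diffusion coefficient.
#' @return An object of class `ddm_session_params`.
#' @export
ddm_session_params <- function(a_speed, a_accuracy, ter_speed, ter_accuracy,
                               v, eta = 0, z_ratio = 0.5, st0 = 0, s = 0.1) {
  out <- structure(list(a_speed = a_speed, a_accuracy = a_accuracy,
                        ter_speed = ter_speed, ter_accuracy = ter_accuracy,
                        v = v, eta = eta, z_ratio = z_ratio, st0 = st0, s = s),
                   class = "ddm_session_params")
  ddm_cue_params(out, "speed")     # validates
  ddm_cue_params(out, "accuracy")
  out
}

#' Extract one cue's core parameters from session parameters
#' @param p a `ddm_session_params`.
#' @param cue `"speed"` or `"accuracy"`.
#' @return A [ddm_params()] object.
#' @export
ddm_cue_params <- function(p, cue = c("speed", "accuracy")) {
  cue <- match.arg(cue)
  a <- if (cue == "speed") p$a_speed else p$a_accuracy
  ter <- if (cue == "speed") p$ter_speed else p$ter_accuracy
  ddm_params(a = a, v = p$v, ter = ter, z = p$z_ratio * a,
             eta = p$eta, st0 = p$st0, s = p$s)
}

# --- first-passage series, diffusion coefficient 1 ------------------------

# Density of absorption at the LOWER boundary at decision time t, for drift
# v, separation a, relative start w = z/a (all diffusion-1 units).
# Truncation counts for the two series follow the usual error-bound rule at
# tolerance eps; the series needing fewer terms wins per time point.
.wfpt_lower <- function(t, v, a, w, eps = 1e-8) {
  out <- numeric(length(t))
  idx <- which(is.finite(t) & t > 0)
  for (i in idx) {
    tt <- t[i] / a^2  # normalized time
    ks <- 2
    arg <- 2 * eps * sqrt(2 * pi * tt)
    if (arg < 1) ks <- max(2 + sqrt(-2 * tt * log(arg)), sqrt(tt) + 1)
    kl <- 1 / (pi * sqrt(tt))
    if (pi * tt * eps < 1) {
      kl <- max(sqrt(-2 * log(pi * tt * eps) / (pi^2 * tt)), kl)
    }
    if (ks < kl) {   # small-time (image) series
      K <- ceiling(ks)
      k <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
      f <- sum((w + 2 * k) * exp(-((w + 2 * k)^2) / (2 * tt))) /
        sqrt(2 * pi * tt^3)
    } else {         # large-time (sine) series
      K <- ceiling(kl)
      k <- seq_len(K)
      f <- pi * sum(k * exp(-(k^2) * pi^2 * tt / 2) * sin(k * pi * w))
    }
    out[i] <- f * exp(-v * a * w - v^2 * t[i] / 2) / a^2
  }
  pmax(out, 0)
}

# P(absorb at lower boundary | v, a, w), diffusion-1 units. Stable for
# strongly negative drift via reflection.
.prob_lower <- function(v, a, w) {
  if (abs(v) < 1e-12) return(1 - w)
  if (v < 0) return(1 - .prob_lower(-v, a, 1 - w))
  z <- w * a
  # P(hit upper first) = (1 - e^{-2vz}) / (1 - e^{-2va}); v > 0 here
  p_up <- expm1(-2 * v * z) / expm1(-2 * v * a)
  1 - p_up
}

# Defective CDF at the LOWER boundary: termwise integral of the sine series.
.wfpt_cdf_lower <- function(t, v, a, w, eps = 1e-10) {
  p_low <- .prob_lower(v, a, w)
  out <- numeric(length(t))
  pos <- which(is.finite(t) & t > 0)
  if (length(pos) > 0) {
    tmin <- min(t[pos])
    # terms decay as exp(-k^2 pi^2 t / (2 a^2)); bound K by the slowest time
    K <- ceiling(a / pi * sqrt(2 * max(0, -log(eps)) / tmin)) + 5L
    K <- min(max(K, 5L), 200000L)
    k <- seq_len(K)
    lam <- (v^2 + k^2 * pi^2 / a^2) / 2
    coef <- k * sin(k * pi * w) / lam
    for (i in pos) {
      S <- sum(coef * exp(-lam * t[i]))
      out[i] <- p_low - pi * exp(-v * a * w) * S / a^2
    }
  }
  out[is.infinite(t) & t > 0] <- p_low
  pmin(pmax(out, 0), 1)
}

# Gauss-Hermite averaging over across-trial drift v ~ N(v, eta).
.eta_average <- function(fun, p, n_nodes = 20L) {
  if (p$eta <= 0) return(fun(p$v))
  gh <- pracma::gaussHermite(n_nodes)
  vals <- lapply(seq_along(gh$x),
                 function(i) fun(p$v + sqrt(2) * p$eta * gh$x[i]) * gh$w[i])
  Reduce(`+`, vals) / sqrt(pi)
}

# Uniform averaging over non-decision time when st0 > 0 (trapezoid on a
# fixed grid; st0 defaults to 0 throughout, this path is rarely exercised).
.st0_offsets <- function(p, n = 11L) {
  if (p$st0 <= 0) return(0)
  seq(-p$st0 / 2, p$st0 / 2, length.out = n)
}

#' First-passage time density of the Wiener diffusion
#'
#' Density (per second) of the decision time at the correct (upper) or error
#' (lower) boundary, marginal over across-trial drift variability. The two
#' defective densities integrate jointly to one.
#'
#' @param t decision time(s), seconds (excluding non-decision time).
#' @param boundary `"correct"` (upper) or `"error"` (lower).
#' @param p a [ddm_params()] object.
#' @return Numeric vector of densities; 0 for `t <= 0`.
#' @export
wiener_fpt_density <- function(t, boundary = c("correct", "error"), p) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  av <- p$a / p$s
  wv <- p$z / p$a
  dens1 <- function(v) {
    vv <- v / p$s
    if (boundary == "error") .wfpt_lower(t, vv, av, wv)
    else .wfpt_lower(t, -vv, av, 1 - wv)
  }
  .eta_average(dens1, p)
}

#' Defective first-passage CDF of the Wiener diffusion
#'
#' Cumulative probability of a response at the given boundary by decision
#' time `t`. The `t -> Inf` limit is the boundary's choice probability; the
#' two limits sum to one.
#'
#' @inheritParams wiener_fpt_density
#' @return Numeric vector of probabilities, nondecreasing in `t`.
#' @export
ddm_defective_cdf <- function(t, boundary = c("correct", "error"), p) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  av <- p$a / p$s
  wv <- p$z / p$a
  cdf1 <- function(v) {
    vv <- v / p$s
    if (boundary == "error") .wfpt_cdf_lower(t, vv, av, wv)
    else .wfpt_cdf_lower(t, -vv, av, 1 - wv)
  }
  .eta_average(cdf1, p)
}

#' Choice probability of the Wiener diffusion
#'
#' Closed-form absorption probability of drifted Brownian motion between two
#' barriers, marginal over drift variability.
#'
#' @inheritParams wiener_fpt_density
#' @return Probability of responding at `boundary`.
#' @export
ddm_choice_prob <- function(boundary = c("correct", "error"), p) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(p, "ddm_params"))
  av <- p$a / p$s
  wv <- p$z / p$a
  prob1 <- function(v) {
    vv <- v / p$s
    if (boundary == "error") .prob_lower(vv, av, wv)
    else .prob_lower(-vv, av, 1 - wv)
  }
  .eta_average(prob1, p)
}

#' Model-implied probability masses in observed quantile bins
#'
#' For one cue, returns the predicted probability of each RT bin delimited by
#' the observed quantile edges (expressed as total RT, i.e. decision time
#' plus non-decision time), separately for correct and error responses. With
#' 5 quantile edges per response class this yields 6 + 6 bins; when the error
#' class is sparse it is collapsed to a single bin holding the whole error
#' probability. Probabilities are nonnegative and sum to 1 up to series
#' truncation tolerance.
#'
#' @param p a [ddm_session_params()] object.
#' @param cue `"speed"` or `"accuracy"`.
#' @param edges_correct,edges_error nondecreasing total-RT quantile edges (s);
#'   pass `NULL` for `edges_error` to collapse the error class.
#' @return List with components `correct` and `error` (bin probability
#'   vectors) and attribute `degenerate` counting edges at or below Ter.
#' @export
ddm_bin_probabilities <- function(p, cue, edges_correct, edges_error = NULL) {
  cp <- ddm_cue_params(p, cue)
  degenerate <- 0L
  offs <- .st0_offsets(cp)
  cdf_at <- function(edges, boundary) {
    if (length(offs) == 1L) {
      dtm <- edges - cp$ter
      degenerate <<- degenerate + sum(dtm <= 0)
      ddm_defective_cdf(pmax(dtm, 0), boundary, cp)
    } else {
      acc <- 0
      for (o in offs) acc <- acc + ddm_defective_cdf(pmax(edges - cp$ter - o, 0), boundary, cp)
      acc / length(offs)
    }
  }
  p_corr <- ddm_choice_prob("correct", cp)
  p_err <- 1 - p_corr
  bins <- function(edges, boundary, p_total) {
    if (is.null(edges)) return(p_total)
    if (is.unsorted(edges)) stop("edges must be nondecreasing")
    Fv <- cdf_at(edges, boundary)
    pmax(diff(c(0, Fv, p_total)), 0)
  }
  out <- list(correct = bins(edges_correct, "correct", p_corr),
              error = bins(edges_error, "error", p_err))
  attr(out, "degenerate") <- degenerate
  out
}

#' Chi-square discrepancy between observed and predicted quantile bins
#'
#' The quantile-based chi-square statistic: for each cue and response class,
#' the observed bin proportions (fixed by the quantile construction at 0.1,
#' 0.2, 0.2, 0.2, 0.2, 0.1 of the class probability) are compared with the
#' model-implied masses; `chi2 = sum N (p_obs - p_exp)^2 / p_exp` with N the
#' cue's responded-trial count. Expected masses are floored to avoid division
#' blow-ups; floored bins are counted in the `"floored"` attribute.
#'
#' @param summaries named list with `speed` and `accuracy`
#'   [summarize_cell()] summaries from one session.
#' @param p a [ddm_session_params()] object.
#' @param p_floor floor for expected bin probabilities (default 1e-5).
#' @return Chi-square value (>= 0) with attribute `floored`.
#' @export
ddm_chi_square <- function(summaries, p, p_floor = 1e-5) {
  chi2 <- 0
  floored <- 0L
  for (cue in c("speed", "accuracy")) {
    sm <- summaries[[cue]]
    if (is.null(sm)) stop("missing summary for cue ", cue)
    pred <- ddm_bin_probabilities(
      p, cue,
      edges_correct = sm$correct_quantiles,
      edges_error = if (sm$sparse_error) NULL else sm$error_quantiles)
    wts <- diff(c(0, sm$probs, 1))
    obs_c <- if (is.null(sm$correct_quantiles)) sm$p_correct else sm$p_correct * wts
    obs_e <- if (sm$sparse_error) 1 - sm$p_correct else (1 - sm$p_correct) * wts
    p_obs <- c(obs_c, obs_e)
    p_exp <- c(pred$correct, pred$error)
    low <- p_exp < p_floor
    floored <- floored + sum(low)
    p_exp[low] <- p_floor
    chi2 <- chi2 + sm$n_trials * sum((p_obs - p_exp)^2 / p_exp)
  }
  structure(chi2, floored = floored)
}

#' Configuration for the simplex chi-square diffusion fit
#'
#' @param bounds named list of lower/upper box constraints for `a` (both
#'   cues), `ter` (s), `v`, `eta`.
#' @param restarts number of Nelder-Mead simplex runs, started from the best
#'   of `n_coarse` seeded uniform draws inside the box.
#' @param seed integer seed controlling the restart draws.
#' @param eta_fixed if `TRUE`, fix drift variability to 0 instead of
#'   estimating it.
#' @param maxit maximum objective evaluations per simplex run.
#' @param n_coarse size of the seeded uniform screening sample.
#' @param s diffusion coefficient; `z_ratio` relative start point.
#' @return A configuration list.
#' @export
ddm_fit_config <- function(bounds = list(a = c(0.05, 0.40),
                                         ter = c(0.10, 0.60),
                                         v = c(0, 0.60),
                                         eta = c(0, 0.30)),
                           restarts = 3L, seed = 1L, eta_fixed = FALSE,
                           maxit = 800L, n_coarse = 200L,
                           s = 0.1, z_ratio = 0.5) {
  list(bounds = bounds, restarts = restarts, seed = seed,
       eta_fixed = eta_fixed, maxit = maxit, n_coarse = n_coarse,
       s = s, z_ratio = z_ratio)
}

# Logistic box transform: unconstrained theta <-> bounded x.
.box_to <- function(x, lb, ub) qlogis(pmin(pmax((x - lb) / (ub - lb), 1e-9), 1 - 1e-9))
.box_from <- function(theta, lb, ub) lb + (ub - lb) / (1 + exp(-theta))

#' Fit the diffusion model to one session by chi-square quantile minimisation
#'
#' Minimises [ddm_chi_square()] over `{a_speed, a_accuracy, ter_speed,
#' ter_accuracy, v, eta}` (eta optionally fixed at 0) with Nelder-Mead
#' simplex runs started from the best points of a seeded uniform screen of
#' the parameter box, each iterated from its own optimum until stable; box
#' constraints are enforced by a logistic transform. Deterministic given the
#' configuration seed.
#'
#' @param summaries named list with `speed` and `accuracy` summaries from
#'   one session (see [summarize_session()]).
#' @param config a [ddm_fit_config()].
#' @return An object of class `ddm_fit`: fitted [ddm_session_params()],
#'   objective value `chi2`, evaluation count, convergence flag, restart
#'   count and seed.
#' @export
fit_ddm <- function(summaries, config = ddm_fit_config()) {
  b <- config$bounds
  free <- c("a_speed", "a_accuracy", "ter_speed", "ter_accuracy", "v",
            if (!config$eta_fixed) "eta")
  lb <- c(b$a[1], b$a[1], b$ter[1], b$ter[1], b$v[1],
          if (!config$eta_fixed) b$eta[1])
  ub <- c(b$a[2], b$a[2], b$ter[2], b$ter[2], b$v[2],
          if (!config$eta_fixed) b$eta[2])
  n_eval <- 0L
  make_params <- function(x) {
    ddm_session_params(a_speed = x[1], a_accuracy = x[2],
                       ter_speed = x[3], ter_accuracy = x[4], v = x[5],
                       eta = if (config$eta_fixed) 0 else x[6],
                       z_ratio = config$z_ratio, s = config$s)
  }
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    x <- .box_from(theta, lb, ub)
    suppressWarnings(as.numeric(ddm_chi_square(summaries, make_params(x))))
  }
  k <- length(free)
  best <- with_seed(config$seed, {
    draws <- matrix(runif(k * config$n_coarse, lb, ub), nrow = k)
    vals <- apply(draws, 2, function(x) objective(.box_to(x, lb, ub)))
    top <- order(vals)[seq_len(max(1L, config$restarts))]
    incumbent <- NULL
    for (i in top) {
      res <- tryCatch(
        optim(.box_to(draws[, i], lb, ub), objective, method = "Nelder-Mead",
              control = list(maxit = config$maxit, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(res)) next
      for (chain in 1:3) {  # iterate the simplex from its own optimum
        res2 <- optim(res$par, objective, method = "Nelder-Mead",
                      control = list(maxit = config$maxit, reltol = 1e-8))
        improved <- res$value - res2$value > 1e-8
        res <- res2
        res$stable <- !improved
        if (!improved) break
      }
      if (is.null(incumbent) || res$value < incumbent$value) incumbent <- res
    }
    incumbent
  })
  if (is.null(best)) stop("all fit_ddm restarts failed")
  x_hat <- .box_from(best$par, lb, ub)
  structure(list(params = make_params(x_hat),
                 chi2 = best$value,
                 n_eval = n_eval,
                 converged = best$convergence == 0 || isTRUE(best$stable),
                 restarts = config$restarts,
                 seed = config$seed),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<ddm_fit> chi2 = %.3f (%s, %d evals, %d restarts)\n",
                     "  a: speed %.4f accuracy %.4f | Ter: speed %.3f accuracy %.3f",
                     " | v %.3f eta %.3f\n"),
              x$chi2, if (x$converged) "converged" else "not converged",
              x$n_eval, x$restarts, p$a_speed, p$a_accuracy,
              p$ter_speed, p$ter_accuracy, p$v, p$eta))
  invisible(x)
}

#' Model-implied total-RT quantiles of the diffusion model
#'
#' Inverts the defective CDF (conditional on the response class) at the
#' given probabilities; used to overlay model predictions on vincentized
#' data.
#'
#' @param p a [ddm_session_params()].
#' @param cue `"speed"` or `"accuracy"`.
#' @param probs probabilities within the response class.
#' @param boundary `"correct"` or `"error"`.
#' @return Total RT quantiles (s), including non-decision time.
#' @export
ddm_predicted_quantiles <- function(p, cue, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    boundary = c("correct", "error")) {
  boundary <- match.arg(boundary)
  cp <- ddm_cue_params(p, cue)
  p_total <- ddm_choice_prob(boundary, cp)
  vapply(probs, function(q) {
    target <- q * p_total
    f <- function(t) ddm_defective_cdf(t, boundary, cp) - target
    cp$ter + uniroot(f, lower = 1e-6, upper = 30, tol = 1e-6)$root
  }, numeric(1))
}
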