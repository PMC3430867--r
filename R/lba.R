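# Linear ballistic accumulator: defective densities, log-likelihood and
# maximum-likelihood fitting of a single model with the response threshold
# free across cue x session.
#
# Two independent accumulators race linearly to threshold b from a start
# point uniform on [0, A], with trial-to-trial drift rates drawn from
# N(v, s_drift). The accumulator matching the stimulus has mean drift
# v_correct, the other v_error. Trials where both sampled drifts are
# negative never finish; the defective density is normalised by the
# probability that at least one drift is positive, mirroring the exclusion
# of non-response trials from the data.

.lba_cells <- c("speed.drug", "speed.placebo", "accuracy.drug", "accuracy.placebo")

#' Linear ballistic accumulator parameters
#'
#' @param b named response thresholds, one per (cue, session) cell; names
#'   `"speed.drug"`, `"speed.placebo"`, `"accuracy.drug"`,
#'   `"accuracy.placebo"` (a single unnamed value is recycled to all cells).
#' @param A upper bound of the uniform start-point distribution (`0 <= A <= b`).
#' @param v_correct,v_error mean drift of the matching / mismatching
#'   accumulator (`v_correct > v_error`, the identifiability convention).
#' @param t0 non-decision time (s, >= 0).
#' @param s_drift across-trial SD of drift rates (fixed scaling, default 1).
#' @return An object of class `lba_params`.
#' @export
lba_params <- function(b, A, v_correct, v_error, t0, s_drift = 1) {
  if (length(b) == 1L && is.null(names(b))) b <- setNames(rep(b, 4), .lba_cells)
  if (!all(.lba_cells %in% names(b))) {
    stop("b must be named with cells: ", paste(.lba_cells, collapse = ", "))
  }
  b <- b[.lba_cells]
  if (!is.finite(A) || A < 0) stop("A must be >= 0")
  if (any(!is.finite(b)) || any(b < A)) stop("every b must be >= A")
  if (!is.finite(t0) || t0 < 0) stop("t0 must be >= 0")
  if (!is.finite(s_drift) || s_drift <= 0) stop("s_drift must be > 0")
  if (!(v_correct > v_error)) stop("v_correct must exceed v_error")
  structure(list(b = b, A = A, v_correct = v_correct, v_error = v_error,
                 t0 = t0, s_drift = s_drift),
            class = "lba_params")
}

# Density / CDF of the first-passage time of ONE linear accumulator with
# threshold b, start ~ U(0, A), drift ~ N(v, s). Brown & Heathcote's closed
# forms; the A -> 0 limit is handled analytically.
.lba_pdf1 <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  ok <- which(t > 0)
  if (length(ok) == 0) return(out)
  t <- t[ok]
  if (A < 1e-10) {
    out[ok] <- b / (t^2 * s) * dnorm((b / t - v) / s)
    return(out)
  }
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  out[ok] <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A
  pmax(out, 0)
}

.lba_cdf1 <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  ok <- which(t > 0)
  if (length(ok) == 0) return(out)
  t <- t[ok]
  if (A < 1e-10) {
    out[ok] <- pnorm((t * v - b) / (t * s))
    return(out)
  }
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  val <- 1 + ((b - A - t * v) / A) * pnorm(z1) -
    ((b - t * v) / A) * pnorm(z2) +
    (ts / A) * (dnorm(z1) - dnorm(z2))
  out[ok] <- pmin(pmax(val, 0), 1)
  out
}

#' Defective RT density of the LBA race
#'
#' Density (per second) of total RT for the given winner in the given cell:
#' the winner's first-passage density times the probability the loser has
#' not yet finished, normalised by the probability that at least one drift
#' is positive (both-negative draws correspond to non-response trials, which
#' the analysis excludes).
#'
#' @param t total RT (s), including non-decision time.
#' @param winner `"correct"` or `"error"`.
#' @param cell cell name, e.g. `"speed.drug"` (see [lba_params()]).
#' @param p an [lba_params()] object.
#' @return Numeric vector of densities; 0 for `t <= t0`.
#' @export
lba_defective_density <- function(t, winner = c("correct", "error"), cell, p) {
  winner <- match.arg(winner)
  stopifnot(inherits(p, "lba_params"))
  if (!cell %in% names(p$b)) stop("unknown cell: ", cell)
  b <- p$b[[cell]]
  td <- t - p$t0
  vw <- if (winner == "correct") p$v_correct else p$v_error
  vl <- if (winner == "correct") p$v_error else p$v_correct
  z <- 1 - pnorm(-p$v_correct / p$s_drift) * pnorm(-p$v_error / p$s_drift)
  .lba_pdf1(td, b, p$A, vw, p$s_drift) *
    (1 - .lba_cdf1(td, b, p$A, vl, p$s_drift)) / z
}

#' Log-likelihood of a trial table under the LBA
#'
#' Sum over responded trials of the log defective density at each trial's RT
#' and winner; densities below `floor` are floored to keep the objective
#' finite (the floored count is attached as an attribute).
#'
#' @param trials a preprocessed [trial_table()] with `session`, `cue`,
#'   `correct` and `rt` (s) columns.
#' @param p an [lba_params()] object.
#' @param floor density floor inside the log (default 1e-10).
#' @return Log-likelihood with attribute `floored`.
#' @export
lba_log_likelihood <- function(trials, p, floor = 1e-10) {
  df <- as.data.frame(trials)
  z <- 1 - pnorm(-p$v_correct / p$s_drift) * pnorm(-p$v_error / p$s_drift)
  cell <- paste(df$cue, df$session, sep = ".")
  td <- df$rt - p$t0
  dens <- numeric(nrow(df))
  for (cl in unique(cell)) {
    b <- p$b[[cl]]
    if (is.null(b)) stop("unknown cell: ", cl)
    for (w in c(TRUE, FALSE)) {
      idx <- which(cell == cl & df$correct == w)
      if (length(idx) == 0) next
      vw <- if (w) p$v_correct else p$v_error
      vl <- if (w) p$v_error else p$v_correct
      dens[idx] <- .lba_pdf1(td[idx], b, p$A, vw, p$s_drift) *
        (1 - .lba_cdf1(td[idx], b, p$A, vl, p$s_drift)) / z
    }
  }
  low <- dens < floor
  structure(sum(log(pmax(dens, floor))), floored = sum(low))
}

#' Configuration for the maximum-likelihood LBA fit
#'
#' @param bounds named list of box constraints: `k` is the threshold gap
#'   `b - A`, plus `A`, drifts `v`, and `t0` (s).
#' @param restarts number of Nelder-Mead simplex runs, started from the best
#'   of `n_coarse` seeded uniform draws inside the box.
#' @param seed integer seed.
#' @param maxit maximum objective evaluations per simplex run.
#' @param n_coarse size of the seeded uniform screening sample providing the
#'   simplex start points.
#' @param s_drift fixed drift-rate SD (scaling constant).
#' @return A configuration list.
#' @export
lba_fit_config <- function(bounds = list(k = c(0.01, 5), A = c(0.01, 5),
                                         v = c(0, 10), t0 = c(0.05, 0.6)),
                           restarts = 3L, seed = 1L, maxit = 1500L,
                           n_coarse = 300L, s_drift = 1) {
  list(bounds = bounds, restarts = restarts, seed = seed, maxit = maxit,
       n_coarse = n_coarse, s_drift = s_drift)
}

#' Fit a single LBA model with threshold free across cue and session
#'
#' Maximises the summed log-likelihood over 8 free parameters: four cell
#' thresholds (via the gaps `b - A`), the start-point range `A`, the two
#' drift means, and `t0`; the drift SD is the fixed scaling constant.
#' `v_error` is parameterised as a fraction of `v_correct` so the
#' identifiability convention `v_correct > v_error` holds throughout the
#' search. The likelihood surface is multimodal in this parameterisation, so
#' the simplex runs are started from the best points of a seeded uniform
#' screen of the box, and each run is iterated from its own optimum until no
#' further improvement. Deterministic given the seed.
#'
#' @param trials preprocessed [trial_table()] containing both sessions and
#'   both cues (one subject's data, or any pooled set to be fit jointly).
#' @param config an [lba_fit_config()].
#' @return An object of class `lba_fit` with fitted [lba_params()],
#'   `loglik`, evaluation count, convergence flag, restarts and seed.
#' @export
fit_lba <- function(trials, config = lba_fit_config()) {
  df <- as.data.frame(trials)
  need <- .lba_cells
  have <- unique(paste(df$cue, df$session, sep = "."))
  if (!all(need %in% have)) {
    stop("fit_lba needs all four cells; missing: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  b_ <- config$bounds
  # theta: k1..k4 (b - A per cell), A, v_correct, frac (v_error/v_correct), t0
  lb <- c(rep(b_$k[1], 4), b_$A[1], b_$v[1] + 1e-6, 0.01, b_$t0[1])
  ub <- c(rep(b_$k[2], 4), b_$A[2], b_$v[2], 0.99, b_$t0[2])
  n_eval <- 0L
  make_params <- function(x) {
    A <- x[5]
    lba_params(b = setNames(x[1:4] + A, .lba_cells), A = A,
               v_correct = x[6], v_error = x[7] * x[6], t0 = x[8],
               s_drift = config$s_drift)
  }
  # hot-path likelihood over RT vectors grouped once per (cell, winner)
  key <- paste(paste(df$cue, df$session, sep = "."), df$correct)
  groups <- lapply(split(df$rt, key), identity)
  cell_of <- sub(" (TRUE|FALSE)$", "", names(groups))
  win_of <- grepl("TRUE$", names(groups))
  floor_d <- 1e-10
  s_d <- config$s_drift
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    x <- .box_from(theta, lb, ub)
    A <- x[5]; vc <- x[6]; ve <- x[7] * x[6]; t0 <- x[8]
    z <- 1 - pnorm(-vc / s_d) * pnorm(-ve / s_d)
    ll <- 0
    for (g in seq_along(groups)) {
      bcell <- x[match(cell_of[g], .lba_cells)] + A
      td <- groups[[g]] - t0
      vw <- if (win_of[g]) vc else ve
      vl <- if (win_of[g]) ve else vc
      dens <- .lba_pdf1(td, bcell, A, vw, s_d) *
        (1 - .lba_cdf1(td, bcell, A, vl, s_d)) / z
      ll <- ll + sum(log(pmax(dens, floor_d)))
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- with_seed(config$seed, {
    draws <- matrix(runif(8L * config$n_coarse, lb, ub), nrow = 8L)
    vals <- apply(draws, 2, function(x) objective(.box_to(x, lb, ub)))
    top <- order(vals)[seq_len(max(1L, config$restarts))]
    incumbent <- NULL
    for (i in top) {
      res <- tryCatch(
        optim(.box_to(draws[, i], lb, ub), objective, method = "Nelder-Mead",
              control = list(maxit = config$maxit, reltol = 1e-9)),
        error = function(e) NULL)
      if (is.null(res)) next
      for (chain in 1:3) {  # iterate the simplex from its own optimum
        res2 <- optim(res$par, objective, method = "Nelder-Mead",
                      control = list(maxit = config$maxit, reltol = 1e-9))
        improved <- res$value - res2$value > 1e-6
        res <- res2
        res$stable <- !improved
        if (!improved) break
      }
      if (is.null(incumbent) || res$value < incumbent$value) incumbent <- res
    }
    incumbent
  })
  if (is.null(best) || best$value >= 1e12) {
    stop("all fit_lba restarts failed (non-finite likelihood)")
  }
  x_hat <- .box_from(best$par, lb, ub)
  structure(list(params = make_params(x_hat),
                 loglik = -best$value,
                 n_eval = n_eval,
                 converged = best$convergence == 0 || isTRUE(best$stable),
                 restarts = config$restarts,
                 seed = config$seed),
            class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<lba_fit> logLik = %.2f (%s, %d evals, %d restarts)\n",
              x$loglik, if (x$converged) "converged" else "not converged",
              x$n_eval, x$restarts))
  cat("  b:", paste(sprintf("%s=%.3f", names(p$b), p$b), collapse = " "), "\n")
  cat(sprintf("  A %.3f | v+ %.3f v- %.3f | t0 %.3f | s %.2f\n",
              p$A, p$v_correct, p$v_error, p$t0, p$s_drift))
  invisible(x)
}

#' Model-implied total-RT quantiles of the LBA
#'
#' Numerically inverts the (conditional) defective CDF on a time grid; used
#' to overlay model predictions on vincentized data.
#'
#' @param p an [lba_params()] object.
#' @param cell cell name.
#' @param probs probabilities within the response class.
#' @param winner `"correct"` or `"error"`.
#' @param t_max upper limit of the integration grid (s).
#' @return Total RT quantiles (s).
#' @export
lba_predicted_quantiles <- function(p, cell, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    winner = c("correct", "error"),
                                    t_max = 10) {
  winner <- match.arg(winner)
  grid <- seq(p$t0, t_max, length.out = 4000L)
  dens <- lba_defective_density(grid, winner, cell, p)
  dgrid <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dgrid))
  total <- cdf[length(cdf)]
  vapply(probs, function(q) grid[which.max(cdf >= q * total)], numeric(1))
}

#' Choice probability of the LBA race
#'
#' Winner probability by numerical integration of the defective density,
#' normalised as in [lba_defective_density()].
#'
#' @inheritParams lba_predicted_quantiles
#' @return Probability that `winner` wins the race.
#' @export
lba_choice_prob <- function(p, cell, winner = c("correct", "error"),
                            t_max = 60) {
  winner <- match.arg(winner)
  integrate(function(t) lba_defective_density(t, winner, cell, p),
            lower = p$t0, upper = t_max, rel.tol = 1e-8)$value
}
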