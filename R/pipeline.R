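# End-to-end behavioural analysis pipeline and parameter-recovery harness.
#
# Stage order is fixed: preprocessing -> subject exclusions -> per-cell
# summary statistics -> RT / accuracy ANOVAs -> per-session diffusion fits
# -> joint LBA fit -> threshold ANOVAs -> paired and Bayesian t-tests on
# drug-minus-placebo differences -> correlation screen -> vincentized
# summaries with model predictions. Every stage logs counts; the whole run
# is deterministic given the configuration seed.

#' Configuration of the behavioural analysis pipeline
#'
#' @param min_accuracy subject-exclusion threshold (see
#'   [apply_subject_exclusions()]).
#' @param exclusions set to `FALSE` to skip the exclusion stage (recorded in
#'   the log).
#' @param probs RT quantile probabilities.
#' @param sparse_n sparse-error threshold for quantile summaries.
#' @param ddm_config,lba_config fit configurations; pass `NULL` to skip a
#'   model stage.
#' @param prior_h0,r_scale Bayesian t-test settings.
#' @param family_alpha family-wise level of the correlation screen.
#' @param seed master seed; per-subject fit seeds are derived from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(min_accuracy = 0.60, exclusions = TRUE,
                            probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            sparse_n = 5L,
                            ddm_config = ddm_fit_config(eta_fixed = TRUE,
                                                        restarts = 3L,
                                                        maxit = 500L),
                            lba_config = lba_fit_config(restarts = 3L,
                                                        maxit = 1200L),
                            prior_h0 = 0.5, r_scale = 1,
                            family_alpha = 0.05, seed = 1L) {
  list(min_accuracy = min_accuracy, exclusions = exclusions, probs = probs,
       sparse_n = sparse_n, ddm_config = ddm_config, lba_config = lba_config,
       prior_h0 = prior_h0, r_scale = r_scale, family_alpha = family_alpha,
       seed = as.integer(seed))
}

# derive a per-subject, per-stage fit seed from the master seed (kept well
# below .Machine$integer.max)
.derive_seed <- function(seed, i, stage) {
  (seed * 1009L + i * 97L + stage) %% 2147480000L
}

.cells_2x2 <- function(values, f1 = c("drug", "placebo"),
                       f2 = c("speed", "accuracy")) {
  # values: named list [[session]][[cue]] -> per-subject vector
  m <- do.call(cbind, lapply(f1, function(a)
    do.call(cbind, lapply(f2, function(b) values[[a]][[b]]))))
  colnames(m) <- as.vector(outer(f2, f1, function(b, a) paste(a, b, sep = ".")))
  m[, order(colnames(m)), drop = FALSE]
}

#' Run the full behavioural analysis
#'
#' Executes the pipeline on a validated trial table and returns a structured
#' report: exclusions, per-cell mean RT and accuracy, 2x2 repeated-measures
#' ANOVAs on RT and accuracy, per-subject per-session diffusion fits and a
#' joint LBA fit, threshold ANOVAs for both models, paired and default
#' Bayesian t-tests on the drug-minus-placebo differences of every measure,
#' a Bonferroni-controlled correlation screen against trait covariates (when
#' available in the table metadata), and vincentized quantile summaries with
#' model-predicted quantiles for plotting.
#'
#' @param data a [trial_table()].
#' @param cfg an [analysis_config()].
#' @return An object of class `analysis_report`.
#' @export
run_behavioral_analysis <- function(data, cfg = analysis_config()) {
  log <- list()
  report <- list(config = cfg, log = log)
  class(report) <- "analysis_report"

  # --- preprocessing and exclusions ---------------------------------------
  pp <- preprocess(data)
  md <- trial_metadata(pp)
  report$log$preprocess <- list(dummy_removed = md$n_dummy_removed,
                                noresponse_removed = md$n_noresponse_removed)
  if (isTRUE(cfg$exclusions)) {
    pp <- apply_subject_exclusions(pp, cfg$min_accuracy)
    report$log$exclusions <- trial_metadata(pp)$excluded_subjects
  } else {
    report$log$exclusions <- "skipped"
  }
  subjects <- sort(unique(pp$subject))
  n <- length(subjects)
  report$subjects <- subjects

  # --- per-cell summary statistics ----------------------------------------
  grid <- expand.grid(subject = subjects, session = c("drug", "placebo"),
                      cue = c("speed", "accuracy"),
                      stringsAsFactors = FALSE)
  grid$mean_rt <- NA_real_
  grid$accuracy <- NA_real_
  df <- as.data.frame(pp)
  for (r in seq_len(nrow(grid))) {
    sel <- df$subject == grid$subject[r] & df$session == grid$session[r] &
      df$cue == grid$cue[r]
    grid$mean_rt[r] <- mean(df$rt[sel])
    grid$accuracy[r] <- mean(df$correct[sel])
  }
  report$cell_stats <- grid

  per_subject <- function(col) {
    vals <- list()
    for (sess in c("drug", "placebo")) {
      vals[[sess]] <- list()
      for (cue in c("speed", "accuracy")) {
        v <- vapply(subjects, function(s) {
          grid[[col]][grid$subject == s & grid$session == sess &
                        grid$cue == cue]
        }, numeric(1))
        vals[[sess]][[cue]] <- v
      }
    }
    vals
  }
  rt_vals <- per_subject("mean_rt")
  acc_vals <- per_subject("accuracy")

  # --- RT and accuracy ANOVAs ---------------------------------------------
  report$anova_rt <- rm_anova_2x2(.cells_2x2(rt_vals))
  report$anova_accuracy <- rm_anova_2x2(.cells_2x2(acc_vals))

  # --- model fits ----------------------------------------------------------
  summaries <- list()
  for (s in subjects) {
    sub_tt <- structure(df[df$subject == s, , drop = FALSE],
                        metadata = list(), class = c("trial_table", "data.frame"))
    summaries[[s]] <- lapply(setNames(c("drug", "placebo"), c("drug", "placebo")),
                             function(sess) summarize_session(sub_tt, sess,
                                                              cfg$probs,
                                                              cfg$sparse_n))
  }
  report$vincentized <- list()
  for (sess in c("drug", "placebo")) {
    for (cue in c("speed", "accuracy")) {
      report$vincentized[[paste(cue, sess, sep = ".")]] <-
        vincentize(lapply(summaries, function(x) x[[sess]][[cue]]))
    }
  }

  if (!is.null(cfg$ddm_config)) {
    ddm_fits <- list()
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      ddm_fits[[s]] <- lapply(setNames(c("drug", "placebo"), c("drug", "placebo")),
        function(sess) {
          fc <- cfg$ddm_config
          fc$seed <- .derive_seed(cfg$seed, i,
                                  if (sess == "drug") 1L else 2L)
          fit_ddm(summaries[[s]][[sess]], fc)
        })
    }
    report$ddm_fits <- ddm_fits
    a_vals <- list()
    for (sess in c("drug", "placebo")) {
      a_vals[[sess]] <- list(
        speed = vapply(subjects, function(s) ddm_fits[[s]][[sess]]$params$a_speed, numeric(1)),
        accuracy = vapply(subjects, function(s) ddm_fits[[s]][[sess]]$params$a_accuracy, numeric(1)))
    }
    report$anova_threshold_ddm <- rm_anova_2x2(.cells_2x2(a_vals))
    report$ddm_thresholds <- a_vals
  }

  if (!is.null(cfg$lba_config)) {
    lba_fits <- list()
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      fc <- cfg$lba_config
      fc$seed <- .derive_seed(cfg$seed, i, 3L)
      sub_tt <- df[df$subject == s, , drop = FALSE]
      lba_fits[[s]] <- fit_lba(sub_tt, fc)
    }
    report$lba_fits <- lba_fits
    b_vals <- list()
    for (sess in c("drug", "placebo")) {
      b_vals[[sess]] <- list(
        speed = vapply(subjects, function(s)
          lba_fits[[s]]$params$b[[paste0("speed.", sess)]], numeric(1)),
        accuracy = vapply(subjects, function(s)
          lba_fits[[s]]$params$b[[paste0("accuracy.", sess)]], numeric(1)))
    }
    report$anova_threshold_lba <- rm_anova_2x2(.cells_2x2(b_vals))
    report$lba_thresholds <- b_vals
  }

  # --- drug comparisons: paired and Bayesian t-tests ----------------------
  measures <- list(rt_speed = rt_vals, rt_accuracy = rt_vals,
                   accuracy_speed = acc_vals, accuracy_accuracy = acc_vals)
  cue_of <- c(rt_speed = "speed", rt_accuracy = "accuracy",
              accuracy_speed = "speed", accuracy_accuracy = "accuracy")
  if (!is.null(report$ddm_thresholds)) {
    measures$ddm_threshold_speed <- report$ddm_thresholds
    measures$ddm_threshold_accuracy <- report$ddm_thresholds
    cue_of <- c(cue_of, ddm_threshold_speed = "speed",
                ddm_threshold_accuracy = "accuracy")
  }
  if (!is.null(report$lba_thresholds)) {
    measures$lba_threshold_speed <- report$lba_thresholds
    measures$lba_threshold_accuracy <- report$lba_thresholds
    cue_of <- c(cue_of, lba_threshold_speed = "speed",
                lba_threshold_accuracy = "accuracy")
  }
  report$drug_tests <- list()
  for (m in names(measures)) {
    cue <- cue_of[[m]]
    x <- measures[[m]][["drug"]][[cue]]
    y <- measures[[m]][["placebo"]][[cue]]
    report$drug_tests[[m]] <- list(
      t_test = paired_t_test(x, y),
      bayes = bayes_t_test(x = x, y = y, r_scale = cfg$r_scale,
                           prior_h0 = cfg$prior_h0))
  }

  # --- correlation screen --------------------------------------------------
  traits <- trial_metadata(data)$traits
  if (!is.null(traits)) {
    traits <- traits[match(subjects, traits$subject), , drop = FALSE]
    effects <- data.frame(
      rt_speed = rt_vals$drug$speed - rt_vals$placebo$speed,
      rt_accuracy = rt_vals$drug$accuracy - rt_vals$placebo$accuracy,
      accuracy_speed = acc_vals$drug$speed - acc_vals$placebo$speed,
      accuracy_accuracy = acc_vals$drug$accuracy - acc_vals$placebo$accuracy)
    report$correlations <- correlation_screen(
      effects, traits[, setdiff(names(traits), "subject"), drop = FALSE],
      cfg$family_alpha)
  }

  # --- model-predicted group quantiles for plotting ------------------------
  if (!is.null(report$ddm_fits)) {
    report$predicted_quantiles <- list()
    for (sess in c("drug", "placebo")) {
      for (cue in c("speed", "accuracy")) {
        pq <- lapply(subjects, function(s)
          ddm_predicted_quantiles(report$ddm_fits[[s]][[sess]]$params, cue,
                                  cfg$probs, "correct"))
        report$predicted_quantiles[[paste(cue, sess, sep = ".")]] <-
          colMeans(do.call(rbind, pq))
      }
    }
  }
  report$provenance <- list(seed = cfg$seed,
                            n_subjects = n,
                            input_metadata = trial_metadata(data)["config"])
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Behavioural analysis report ==\n")
  cat(sprintf("Subjects analysed: %d (excluded: %s)\n", length(x$subjects),
              if (length(x$log$exclusions) == 0) "none"
              else paste(x$log$exclusions, collapse = ", ")))
  cat(sprintf("Trials removed: %d dummy, %d without response\n",
              x$log$preprocess$dummy_removed,
              x$log$preprocess$noresponse_removed))
  cat("\n-- Mean RT ANOVA --\n"); print(x$anova_rt)
  cat("\n-- Accuracy ANOVA --\n"); print(x$anova_accuracy)
  if (!is.null(x$anova_threshold_ddm)) {
    cat("\n-- DDM threshold ANOVA (session x cue) --\n")
    print(x$anova_threshold_ddm)
  }
  if (!is.null(x$anova_threshold_lba)) {
    cat("\n-- LBA threshold ANOVA (session x cue) --\n")
    print(x$anova_threshold_lba)
  }
  cat("\n-- Drug vs placebo comparisons --\n")
  for (m in names(x$drug_tests)) {
    tt <- x$drug_tests[[m]]$t_test
    bt <- x$drug_tests[[m]]$bayes
    cat(sprintf("  %-24s t(%d) = %6.3f, p = %.3f, pBayes(H0) = %.3f\n",
                m, tt$df, tt$t, tt$p, bt$posterior_h0))
  }
  if (!is.null(x$correlations)) {
    cat("\n"); print(x$correlations)
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Flattens the report (tests, ANOVAs, thresholds, log, provenance) into a
#' JSON document; fitted model objects are reduced to their parameter
#' vectors and objective values.
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  simplify_fit <- function(f) {
    if (inherits(f, "ddm_fit")) {
      c(unclass(f$params), list(chi2 = f$chi2, converged = f$converged))
    } else if (inherits(f, "lba_fit")) {
      list(b = as.list(f$params$b), A = f$params$A,
           v_correct = f$params$v_correct, v_error = f$params$v_error,
           t0 = f$params$t0, loglik = f$loglik, converged = f$converged)
    } else f
  }
  out <- list(
    subjects = report$subjects,
    log = report$log,
    cell_stats = report$cell_stats,
    anova_rt = report$anova_rt$effects,
    anova_accuracy = report$anova_accuracy$effects,
    anova_threshold_ddm = report$anova_threshold_ddm$effects,
    anova_threshold_lba = report$anova_threshold_lba$effects,
    drug_tests = lapply(report$drug_tests, function(dt)
      list(t = dt$t_test$t, df = dt$t_test$df, p = dt$t_test$p,
           bf01 = dt$bayes$bf01, posterior_h0 = dt$bayes$posterior_h0)),
    ddm_fits = if (!is.null(report$ddm_fits))
      lapply(report$ddm_fits, function(x) lapply(x, simplify_fit)),
    lba_fits = if (!is.null(report$lba_fits))
      lapply(report$lba_fits, simplify_fit),
    correlations = if (!is.null(report$correlations))
      list(table = report$correlations$table,
           alpha_corrected = report$correlations$alpha_corrected),
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate datasets from known parameters and refits them,
#' reporting truth, estimate, bias and relative error per parameter — the
#' standard validation harness for quantile chi-square and maximum-likelihood
#' accumulator fitting.
#'
#' @param model `"ddm"` or `"lba"`.
#' @param n_replicates number of simulated datasets.
#' @param trials_per_cell trials per cue (diffusion; one session) or per
#'   cue-session cell (LBA).
#' @param truth true parameters: a [ddm_session_params()] or [lba_params()];
#'   defaults follow the synthetic-study population means.
#' @param fit_config fit configuration for the model.
#' @param seed master seed.
#' @return An object of class `recovery_report`: long data frame of
#'   truth/estimate pairs plus a per-parameter summary (median relative
#'   error, bias).
#' @export
run_parameter_recovery <- function(model = c("ddm", "lba"),
                                   n_replicates = 10L,
                                   trials_per_cell = 2000L,
                                   truth = NULL,
                                   fit_config = NULL,
                                   seed = 1L) {
  model <- match.arg(model)
  rows <- list()
  if (n_replicates < 1) {
    return(structure(list(results = data.frame(), summary = data.frame(),
                          model = model), class = "recovery_report"))
  }
  if (model == "ddm") {
    if (is.null(truth)) {
      truth <- ddm_session_params(a_speed = 0.08, a_accuracy = 0.16,
                                  ter_speed = 0.30, ter_accuracy = 0.35,
                                  v = 0.25, eta = 0, s = 0.1)
    }
    if (is.null(fit_config)) {
      fit_config <- ddm_fit_config(eta_fixed = TRUE, restarts = 3L,
                                   maxit = 500L)
    }
    for (r in seq_len(n_replicates)) {
      sim_seed <- .derive_seed(seed, r, 10L)
      frag <- rbind(
        simulate_ddm_trials(ddm_cue_params(truth, "speed"), trials_per_cell,
                            deadline = Inf, seed = sim_seed, cue = "speed"),
        simulate_ddm_trials(ddm_cue_params(truth, "accuracy"), trials_per_cell,
                            deadline = Inf, seed = sim_seed + 1L,
                            cue = "accuracy"))
      tt <- preprocess(trial_table(frag))
      sm <- summarize_session(tt, "placebo")
      fc <- fit_config
      fc$seed <- .derive_seed(seed, r, 11L)
      fit <- fit_ddm(sm, fc)
      for (par in c("a_speed", "a_accuracy", "ter_speed", "ter_accuracy", "v")) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, parameter = par, truth = truth[[par]],
          estimate = fit$params[[par]])
      }
    }
  } else {
    if (is.null(truth)) {
      truth <- lba_params(b = c(speed.drug = 1.0, speed.placebo = 1.0,
                                accuracy.drug = 1.6, accuracy.placebo = 1.6),
                          A = 0.8, v_correct = 3.0, v_error = 1.5, t0 = 0.25,
                          s_drift = 1)
    }
    if (is.null(fit_config)) {
      fit_config <- lba_fit_config(restarts = 3L, maxit = 1200L)
    }
    for (r in seq_len(n_replicates)) {
      sim_seed <- .derive_seed(seed, r, 20L)
      frag <- do.call(rbind, lapply(seq_along(names(truth$b)), function(i) {
        simulate_lba_trials(truth, names(truth$b)[i], trials_per_cell,
                            deadline = Inf, seed = sim_seed + i)
      }))
      tt <- preprocess(trial_table(frag))
      fc <- fit_config
      fc$seed <- .derive_seed(seed, r, 21L)
      fit <- fit_lba(tt, fc)
      for (cell in names(truth$b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, parameter = paste0("b.", cell),
          truth = truth$b[[cell]], estimate = fit$params$b[[cell]])
      }
      for (par in c("A", "v_correct", "v_error", "t0")) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, parameter = par, truth = truth[[par]],
          estimate = fit$params[[par]])
      }
    }
  }
  res <- do.call(rbind, rows)
  res$rel_error <- (res$estimate - res$truth) / res$truth
  summ <- do.call(rbind, lapply(split(res, res$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               truth = d$truth[1],
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate - d$truth),
               median_abs_rel_error = stats::median(abs(d$rel_error)))
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ, model = model, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s, %d replicates)\n", x$model,
              if (nrow(x$results)) max(x$results$replicate) else 0L))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Vincentized defective quantile plot with model predictions
#'
#' Plots group (vincentized) correct-response RT quantiles against their
#' cumulative defective probability for each cue, overlaying model-predicted
#' quantiles when available — the standard visual check of quantile fits.
#'
#' @param report an `analysis_report` from [run_behavioral_analysis()].
#' @param session which session to plot.
#' @param ... passed to [graphics::plot()].
#' @return The report, invisibly.
#' @export
plot_quantile_fit <- function(report, session = "placebo", ...) {
  cues <- c("speed", "accuracy")
  cols <- c(speed = "firebrick", accuracy = "navy")
  xs <- list(); ys <- list()
  for (cue in cues) {
    v <- report$vincentized[[paste(cue, session, sep = ".")]]
    xs[[cue]] <- v$correct_quantiles
    ys[[cue]] <- v$probs * v$p_correct
  }
  graphics::plot(NA, xlim = range(unlist(xs)), ylim = c(0, 1),
                 xlab = "RT (s)", ylab = "defective cumulative probability",
                 main = paste0("Vincentized quantiles (", session, ")"), ...)
  for (cue in cues) {
    graphics::points(xs[[cue]], ys[[cue]], pch = 19, col = cols[[cue]])
    pred <- report$predicted_quantiles[[paste(cue, session, sep = ".")]]
    if (!is.null(pred)) {
      v <- report$vincentized[[paste(cue, session, sep = ".")]]
      graphics::lines(pred, v$probs * v$p_correct, col = cols[[cue]], lty = 2)
    }
  }
  graphics::legend("bottomright", legend = cues, col = unlist(cols),
                   pch = 19, bty = "n")
  invisible(report)
}
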