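# Programmatic fixtures shared across test files.

# A minimal well-formed trial data frame (one subject, both sessions/cues).
make_trial_df <- function(n_per_cell = 4L, subject = "s01") {
  grid <- expand.grid(session = c("drug", "placebo"),
                      cue = c("speed", "accuracy"),
                      i = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  direction <- rep(c("left", "right"), length.out = n)
  correct <- rep(c(TRUE, TRUE, TRUE, FALSE), length.out = n)
  response <- ifelse(correct, direction,
                     ifelse(direction == "left", "right", "left"))
  data.frame(subject = subject, session = grid$session, block = 1L,
             cue = grid$cue, direction = direction, response = response,
             correct = correct,
             rt_ms = 300 + 10 * seq_len(n), responded = TRUE,
             stringsAsFactors = FALSE)
}

# Trials for one cell with an exact number of correct/error responses.
make_cell_trials <- function(n_correct, n_error, subject = "s01",
                             session = "placebo", cue = "accuracy",
                             rt_start = 300) {
  n <- n_correct + n_error
  correct <- c(rep(TRUE, n_correct), rep(FALSE, n_error))
  direction <- rep("left", n)
  data.frame(subject = subject, session = session, block = 1L, cue = cue,
             direction = direction,
             response = ifelse(correct, "left", "right"),
             correct = correct, rt_ms = rt_start + 5 * seq_len(n),
             responded = TRUE, stringsAsFactors = FALSE)
}

# Full four-cell table for one subject with given accuracy-cue accuracy.
make_subject_df <- function(subject, acc_accuracy = 0.8, n_per_cell = 20L) {
  n_corr <- round(acc_accuracy * n_per_cell)
  rbind(
    make_cell_trials(n_corr, n_per_cell - n_corr, subject, "drug", "accuracy"),
    make_cell_trials(n_corr, n_per_cell - n_corr, subject, "placebo", "accuracy"),
    make_cell_trials(n_per_cell - 2, 2, subject, "drug", "speed"),
    make_cell_trials(n_per_cell - 2, 2, subject, "placebo", "speed"))
}

ddm_truth <- function() {
  ddm_session_params(a_speed = 0.08, a_accuracy = 0.16,
                     ter_speed = 0.30, ter_accuracy = 0.35,
                     v = 0.25, eta = 0, s = 0.1)
}

lba_truth <- function() {
  lba_params(b = c(speed.drug = 1.0, speed.placebo = 1.0,
                   accuracy.drug = 1.6, accuracy.placebo = 1.6),
             A = 0.8, v_correct = 3.0, v_error = 1.5, t0 = 0.25, s_drift = 1)
}

# The in-study Bayesian t-test worked examples: printed t, n and posterior.
printed_bayes_cases <- function() {
  data.frame(
    label = c("rt_speed", "rt_accuracy", "acc_speed", "acc_accuracy",
              "ddm_thr_accuracy", "ddm_thr_speed", "lba_thr_accuracy",
              "lba_thr_speed", "roi_l_caudate", "roi_r_caudate",
              "roi_l_putamen", "roi_r_putamen", "roi_l_presma",
              "roi_r_presma"),
    t = c(1.6, 0.07, 1.07, 1.182, -0.71, 0.52, -0.12, -1.0,
          1.096, 1.293, 1.358, 1.211, 0.842, 1.216),
    n = c(rep(17L, 8), rep(14L, 6)),
    posterior = c(0.613, 0.845, 0.793, 0.795, 0.81, 0.83, 0.84, 0.77,
                  0.74, 0.70, 0.68, 0.72, 0.78, 0.72))
}
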