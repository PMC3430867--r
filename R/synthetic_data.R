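# Seeded generators for diffusion/LBA trials and for a full two-session,
# two-cue synthetic study with the task's structure (blocks with dummy
# trials, a response deadline with censoring) and configurable cue and drug
# effects on the decision threshold.

#' Simulate diffusion-model trials
#'
#' Draws first-passage times of the Wiener diffusion by Euler-Maruyama
#' simulation (compiled; step size `dt`), adds non-decision time, and
#' censors at the response deadline: trials not absorbed or finishing after
#' the deadline are marked as non-responses. Identical output for identical
#' seed.
#'
#' @param p a [ddm_params()] object.
#' @param n number of trials (>= 0).
#' @param deadline response window (s, default 1.0).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param dt Euler step (s, default 1e-4).
#' @param subject,session,cue,block labels stamped on the generated rows.
#' @return A [trial_table()] fragment (data frame rows in the trial schema).
#' @export
simulate_ddm_trials <- function(p, n, deadline = 1.0, seed = NULL,
                                dt = 1e-4, subject = "s1",
                                session = "placebo", cue = "accuracy",
                                block = 1L) {
  stopifnot(inherits(p, "ddm_params"), n >= 0)
  if (n == 0) return(.empty_trials())
  with_seed(seed, {
    sim <- ddm_sim_cpp(n, p$a, p$v, p$z, p$eta, p$s, dt, max_t = 10)
    ter <- p$ter + if (p$st0 > 0) runif(n, -p$st0 / 2, p$st0 / 2) else 0
    rt <- sim$dec_time + ter
    correct_bound <- !is.na(sim$boundary) & sim$boundary == 1L
    responded <- !is.na(rt) & rt <= deadline
    direction <- sample(c("left", "right"), n, replace = TRUE)
    response <- ifelse(responded,
                       ifelse(correct_bound, direction,
                              ifelse(direction == "left", "right", "left")),
                       "none")
    .trials_frame(subject, session, block, cue, direction, response,
                  correct = ifelse(responded, correct_bound, NA),
                  rt_ms = ifelse(responded, round(rt * 1000, 1), NA_real_),
                  responded = responded)
  })
}

#' Simulate LBA trials for one (cue, session) cell
#'
#' Uniform start points on `[0, A]`, normally distributed drift rates, the
#' faster accumulator wins; draws where both drifts are negative never
#' finish and are recorded as non-responses, as are races finishing after
#' the deadline.
#'
#' @param p an [lba_params()] object.
#' @param cell cell name, e.g. `"speed.drug"`.
#' @param n number of trials.
#' @param deadline response window (s).
#' @param seed integer seed, or `NULL`.
#' @param subject,block labels stamped on the generated rows.
#' @return A trial-schema data frame fragment.
#' @export
simulate_lba_trials <- function(p, cell, n, deadline = 1.0, seed = NULL,
                                subject = "s1", block = 1L) {
  stopifnot(inherits(p, "lba_params"), n >= 0)
  parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !cell %in% names(p$b)) stop("unknown cell: ", cell)
  if (n == 0) return(.empty_trials())
  with_seed(seed, {
    b <- p$b[[cell]]
    start_c <- runif(n, 0, max(p$A, 0))
    start_e <- runif(n, 0, max(p$A, 0))
    v_c <- rnorm(n, p$v_correct, p$s_drift)
    v_e <- rnorm(n, p$v_error, p$s_drift)
    t_c <- ifelse(v_c > 0, (b - start_c) / v_c, Inf)
    t_e <- ifelse(v_e > 0, (b - start_e) / v_e, Inf)
    dec <- pmin(t_c, t_e)
    correct_bound <- t_c <= t_e
    rt <- p$t0 + dec
    responded <- is.finite(rt) & rt <= deadline
    direction <- sample(c("left", "right"), n, replace = TRUE)
    response <- ifelse(responded,
                       ifelse(correct_bound, direction,
                              ifelse(direction == "left", "right", "left")),
                       "none")
    .trials_frame(subject, parts[2], block, parts[1], direction, response,
                  correct = ifelse(responded, correct_bound, NA),
                  rt_ms = ifelse(responded, round(rt * 1000, 1), NA_real_),
                  responded = responded)
  })
}

.trials_frame <- function(subject, session, block, cue, direction, response,
                          correct, rt_ms, responded) {
  data.frame(subject = subject, session = session, block = block, cue = cue,
             direction = direction, response = response, correct = correct,
             rt_ms = rt_ms, responded = responded,
             stringsAsFactors = FALSE)
}

.empty_trials <- function() {
  .trials_frame(character(0), character(0), integer(0), character(0),
                character(0), character(0), logical(0), numeric(0),
                logical(0))
}

#' Configuration of a synthetic two-session study
#'
#' Defines the population a synthetic cohort is drawn from and the task
#' structure: per session, two blocks each holding 50 speed, 50 accuracy and
#' 5 labelled dummy trials, with a 1.0 s response window. The speed cue
#' multiplies the decision threshold by `cue_effect_on_threshold`; the drug
#' session multiplies it by `drug_effect_on_threshold` (1 = no effect, the
#' default). Per-subject trait covariates (BIS, BAS, Barratt impulsiveness)
#' can be given a target correlation with the subject's (latent) drug
#' multiplier.
#'
#' @param n_subjects cohort size.
#' @param trials_per_cue_per_session responded-or-censored trials per cue and
#'   session (split over the two blocks).
#' @param dummy_per_block labelled dummy trials per block.
#' @param generator `"ddm"` or `"lba"`.
#' @param ddm_pop,lba_pop named lists of population means (`*_mean`) and SDs
#'   (`*_sd`) for the subject-level parameters.
#' @param cue_effect_on_threshold multiplicative threshold factor for the
#'   speed cue (< 1).
#' @param drug_effect_on_threshold multiplicative threshold factor for the
#'   drug session (1 = none); `drug_effect_sd` adds subject-level spread.
#' @param deadline response window (s).
#' @param trait_covariates named list of `c(mean, sd)` per trait;
#'   `trait_effect_correlation` is the target correlation between each trait
#'   and the subject's drug multiplier (requires `drug_effect_sd > 0`).
#' @param seed integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 20L,
                         trials_per_cue_per_session = 100L,
                         dummy_per_block = 5L,
                         generator = c("ddm", "lba"),
                         ddm_pop = list(a_mean = 0.16, a_sd = 0.025,
                                        v_mean = 0.25, v_sd = 0.05,
                                        ter_speed_mean = 0.30,
                                        ter_accuracy_mean = 0.35,
                                        ter_sd = 0.03, eta = 0, s = 0.1),
                         lba_pop = list(b_accuracy_mean = 1.6, b_sd = 0.10,
                                        A_mean = 0.8, A_sd = 0.05,
                                        v_correct_mean = 3.0, v_error_mean = 1.5,
                                        v_sd = 0.2, t0_mean = 0.25, t0_sd = 0.02,
                                        s_drift = 1),
                         cue_effect_on_threshold = 0.5,
                         drug_effect_on_threshold = 1.0,
                         drug_effect_sd = 0,
                         deadline = 1.0,
                         trait_covariates = list(bis = c(20, 4),
                                                 bas = c(25, 4),
                                                 barratt = c(62, 8)),
                         trait_effect_correlation = 0,
                         seed = 1L) {
  generator <- match.arg(generator)
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_cue_per_session = as.integer(trials_per_cue_per_session),
              dummy_per_block = as.integer(dummy_per_block),
              generator = generator, ddm_pop = ddm_pop, lba_pop = lba_pop,
              cue_effect_on_threshold = cue_effect_on_threshold,
              drug_effect_on_threshold = drug_effect_on_threshold,
              drug_effect_sd = drug_effect_sd, deadline = deadline,
              trait_covariates = trait_covariates,
              trait_effect_correlation = trait_effect_correlation,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1 || cfg$trials_per_cue_per_session < 1) {
    stop("counts must be >= 1")
  }
  if (cfg$deadline <= 0) stop("deadline must be > 0")
  structure(cfg, class = "study_config")
}

# Truncated-normal draw (rejection at the parameter's admissible range).
.rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
  }
  x
}

#' Generate a full synthetic study
#'
#' Draws subject-level model parameters from the configured population,
#' applies the cue and drug threshold effects, simulates every cell with
#' deadline censoring, interleaves labelled dummy trials, and attaches trait
#' covariates plus full provenance (config and seed) so any study can be
#' regenerated bit-exactly.
#'
#' @param cfg a [study_config()].
#' @return A [trial_table()]; `metadata` carries the config, the per-subject
#'   true parameters, and the trait covariate table.
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  with_seed(cfg$seed, {
    subjects <- sprintf("s%02d", seq_len(cfg$n_subjects))
    # latent per-subject drug multiplier on threshold
    z_drug <- rnorm(cfg$n_subjects)
    drug_mult <- cfg$drug_effect_on_threshold + cfg$drug_effect_sd * z_drug
    traits <- as.data.frame(lapply(cfg$trait_covariates, function(ms) {
      r <- cfg$trait_effect_correlation
      z <- r * z_drug + sqrt(max(0, 1 - r^2)) * rnorm(cfg$n_subjects)
      ms[1] + ms[2] * z
    }))
    traits$subject <- subjects
    n_blocks <- 2L
    per_block <- cfg$trials_per_cue_per_session / n_blocks
    rows <- list()
    true_params <- list()
    for (i in seq_len(cfg$n_subjects)) {
      if (cfg$generator == "ddm") {
        pop <- cfg$ddm_pop
        a_i <- .rtrunc(1, pop$a_mean, pop$a_sd, lower = 0.02)
        v_i <- .rtrunc(1, pop$v_mean, pop$v_sd, lower = 0.01)
        ter_s <- .rtrunc(1, pop$ter_speed_mean, pop$ter_sd, lower = 0.05)
        ter_a <- .rtrunc(1, pop$ter_accuracy_mean, pop$ter_sd, lower = 0.05)
        true_params[[i]] <- data.frame(subject = subjects[i], a = a_i, v = v_i,
                                       ter_speed = ter_s, ter_accuracy = ter_a,
                                       drug_mult = drug_mult[i])
        for (sess in c("drug", "placebo")) {
          mult <- if (sess == "drug") drug_mult[i] else 1
          for (cue in c("speed", "accuracy")) {
            a_cell <- a_i * mult *
              (if (cue == "speed") cfg$cue_effect_on_threshold else 1)
            p_cell <- ddm_params(a = a_cell, v = v_i,
                                 ter = if (cue == "speed") ter_s else ter_a,
                                 eta = pop$eta, s = pop$s)
            for (blk in seq_len(n_blocks)) {
              rows[[length(rows) + 1L]] <- simulate_ddm_trials(
                p_cell, n = per_block, deadline = cfg$deadline,
                subject = subjects[i], session = sess, cue = cue, block = blk)
            }
          }
        }
      } else {
        pop <- cfg$lba_pop
        A_i <- .rtrunc(1, pop$A_mean, pop$A_sd, lower = 0.01)
        b_acc <- .rtrunc(1, pop$b_accuracy_mean, pop$b_sd, lower = A_i + 0.01)
        vc_i <- .rtrunc(1, pop$v_correct_mean, pop$v_sd, lower = 0.1)
        ve_i <- .rtrunc(1, pop$v_error_mean, pop$v_sd, lower = 0.01,
                        upper = vc_i)
        t0_i <- .rtrunc(1, pop$t0_mean, pop$t0_sd, lower = 0.05)
        true_params[[i]] <- data.frame(subject = subjects[i], b_accuracy = b_acc,
                                       A = A_i, v_correct = vc_i,
                                       v_error = ve_i, t0 = t0_i,
                                       drug_mult = drug_mult[i])
        b_cells <- c(
          speed.drug = max(b_acc * cfg$cue_effect_on_threshold * drug_mult[i], A_i),
          speed.placebo = max(b_acc * cfg$cue_effect_on_threshold, A_i),
          accuracy.drug = max(b_acc * drug_mult[i], A_i),
          accuracy.placebo = b_acc)
        p_i <- lba_params(b = b_cells, A = A_i, v_correct = vc_i,
                          v_error = ve_i, t0 = t0_i, s_drift = pop$s_drift)
        for (cell in names(b_cells)) {
          for (blk in seq_len(n_blocks)) {
            rows[[length(rows) + 1L]] <- simulate_lba_trials(
              p_i, cell, n = per_block, deadline = cfg$deadline,
              subject = subjects[i], block = blk)
          }
        }
      }
      # labelled dummy (fixation-only) trials, removed by preprocess()
      for (sess in c("drug", "placebo")) {
        for (blk in seq_len(n_blocks)) {
          nd <- cfg$dummy_per_block
          if (nd > 0) {
            rows[[length(rows) + 1L]] <- .trials_frame(
              subjects[i], sess, blk, "dummy", "left", "none",
              correct = NA, rt_ms = NA_real_, responded = FALSE)[rep(1, nd), ]
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    trial_table(df, metadata = list(
      config = unclass(cfg), seed = cfg$seed,
      true_params = do.call(rbind, true_params),
      traits = traits))
  })
}
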