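# Trial-table I/O, preprocessing, exclusions, quantiles, vincentizing.

test_that("read_trials parses well-formed tables and rejects bad rows by number", {
  df <- make_trial_df(1L)  # 4 rows
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  tt <- read_trials(path)
  expect_s3_class(tt, "trial_table")
  expect_equal(nrow(tt), 4L)
  expect_equal(tt$rt, tt$rt_ms / 1000)

  bad <- df
  bad$rt_ms[3] <- -5
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_trials(path), "3")

  nocol <- df[, setdiff(names(df), "cue")]
  write.csv(nocol, path, row.names = FALSE, quote = FALSE)
  expect_error(read_trials(path), "cue")
})

test_that("write-then-read round-trips a generated trial table", {
  tt <- generate_study(study_config(n_subjects = 2,
                                    trials_per_cue_per_session = 10,
                                    seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tt, path)
  back <- read_trials(path)
  for (col in c("subject", "session", "block", "cue", "direction",
                "response", "correct", "rt_ms", "responded")) {
    expect_equal(back[[col]], tt[[col]], info = col)
  }
})

test_that("preprocess removes dummies and non-responses, logs counts, and is idempotent", {
  df <- make_trial_df(25L)  # 100 trials
  df$responded[c(10, 20)] <- FALSE
  df$response[c(10, 20)] <- "none"
  df$rt_ms[c(10, 20)] <- NA
  df$correct[c(10, 20)] <- NA
  tt <- trial_table(df)
  pp <- preprocess(tt)
  expect_equal(nrow(pp), 98L)
  expect_equal(trial_metadata(pp)$n_noresponse_removed, 2L)
  expect_false("direction" %in% names(pp))

  pp2 <- preprocess(pp)
  expect_equal(as.data.frame(pp2), as.data.frame(pp))

  # no non-responses: table unchanged in size (4 cells x 10 trials)
  clean <- preprocess(trial_table(make_trial_df(10L)))
  expect_equal(nrow(clean), 40L)
})

test_that("model-facing summaries are invariant to direction labels", {
  df <- make_trial_df(25L)
  tt1 <- preprocess(trial_table(df))
  flip <- function(x) ifelse(x == "left", "right", "left")
  df2 <- df
  df2$direction <- flip(df$direction)
  df2$response <- flip(df$response)
  tt2 <- preprocess(trial_table(df2))
  s1 <- summarize_cell(tt1, "placebo", "accuracy")
  s2 <- summarize_cell(tt2, "placebo", "accuracy")
  expect_equal(s1, s2)
})

test_that("subject exclusion uses a strict threshold on accuracy-cue accuracy", {
  df <- rbind(make_subject_df("low", acc_accuracy = 0.59, n_per_cell = 100L),
              make_subject_df("edge", acc_accuracy = 0.60, n_per_cell = 100L),
              make_subject_df("high", acc_accuracy = 0.80, n_per_cell = 100L))
  tt <- preprocess(trial_table(df))
  kept <- apply_subject_exclusions(tt, min_accuracy = 0.60)
  expect_setequal(unique(kept$subject), c("edge", "high"))
  expect_equal(trial_metadata(kept)$excluded_subjects, "low")

  all_low <- preprocess(trial_table(make_subject_df("only", 0.3, 50L)))
  expect_error(apply_subject_exclusions(all_low), "all subjects")
})

test_that("planted near-chance subjects are exactly the ones excluded", {
  good <- generate_study(study_config(n_subjects = 5,
                                      trials_per_cue_per_session = 40,
                                      seed = 21))
  flat <- ddm_params(a = 0.16, v = 0, ter = 0.35, s = 0.1)  # chance accuracy
  bad_rows <- do.call(rbind, lapply(c("bad1", "bad2"), function(s) {
    base <- 1000L * match(s, c("bad1", "bad2"))
    do.call(rbind, lapply(c("drug", "placebo"), function(sess) {
      rbind(simulate_ddm_trials(flat, 150, deadline = Inf,
                                seed = base + nchar(sess),
                                subject = s, session = sess, cue = "accuracy"),
            simulate_ddm_trials(flat, 150, deadline = Inf,
                                seed = base + nchar(sess) + 50,
                                subject = s, session = sess, cue = "speed"))
    }))
  }))
  tt <- preprocess(trial_table(rbind(as.data.frame(good)[
    , c("subject", "session", "block", "cue", "direction", "response",
        "correct", "rt_ms", "responded")], bad_rows)))
  kept <- apply_subject_exclusions(tt, 0.60)
  expect_setequal(trial_metadata(kept)$excluded_subjects, c("bad1", "bad2"))
})

test_that("rt_quantiles follows linear order-statistic interpolation", {
  expect_equal(unname(rt_quantiles(rep(0.42, 9))), rep(0.42, 5))
  x <- as.numeric(1:100)
  # type-7 oracle at p: h = (n-1)p + 1; value = x[floor(h)] + frac * diff
  oracle <- function(x, p) {
    xs <- sort(x); h <- (length(x) - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(unname(rt_quantiles(x, 0.5)), oracle(x, 0.5))
  set.seed(1)
  y <- rexp(37)
  for (p in c(0.1, 0.3, 0.7, 0.9)) {
    expect_equal(unname(rt_quantiles(y, p)), oracle(y, p))
  }
  expect_equal(rt_quantiles(sample(y)), rt_quantiles(y))
  expect_equal(unname(rt_quantiles(0.5)), rep(0.5, 5))
  expect_error(rt_quantiles(numeric(0)), "non-empty")
  expect_error(rt_quantiles(y, c(0, 0.5)), "probs")
  expect_error(rt_quantiles(y, c(0.5, 0.2)), "probs")
})

test_that("summarize_cell computes defective proportions and flags sparse errors", {
  tt <- preprocess(trial_table(make_cell_trials(80, 20)))
  sm <- summarize_cell(tt, "placebo", "accuracy")
  expect_equal(sm$p_correct, 0.8)
  expect_false(sm$sparse_error)
  expect_false(is.unsorted(sm$correct_quantiles))

  tt3 <- preprocess(trial_table(make_cell_trials(50, 3)))
  sm3 <- summarize_cell(tt3, "placebo", "accuracy")
  expect_true(sm3$sparse_error)
  expect_null(sm3$error_quantiles)

  expect_error(summarize_cell(tt, "drug", "speed"), "no responded trials")
})

test_that("summary of simulated diffusion trials approaches model-implied accuracy", {
  p <- ddm_params(a = 0.16, v = 0.25, ter = 0.35, s = 0.1)
  sim <- simulate_ddm_trials(p, 1e5, deadline = Inf, seed = 99)
  tt <- preprocess(trial_table(sim))
  sm <- summarize_cell(tt, "placebo", "accuracy")
  p_model <- ddm_choice_prob("correct", p)
  se <- sqrt(p_model * (1 - p_model) / 1e5)
  expect_lt(abs(sm$p_correct - p_model), 3.5 * se)
})

test_that("vincentizing averages quantiles and respects the subject envelope", {
  tt <- preprocess(trial_table(make_cell_trials(80, 20)))
  sm <- summarize_cell(tt, "placebo", "accuracy")
  grp <- vincentize(list(sm, sm, sm))
  expect_equal(grp$correct_quantiles, sm$correct_quantiles)
  expect_equal(grp$p_correct, sm$p_correct)

  # two subjects: group median is the mean of subject medians
  t2 <- preprocess(trial_table(make_cell_trials(80, 20, rt_start = 500)))
  s2 <- summarize_cell(t2, "placebo", "accuracy")
  grp2 <- vincentize(list(sm, s2))
  expect_equal(grp2$correct_quantiles[3],
               mean(c(sm$correct_quantiles[3], s2$correct_quantiles[3])))

  # random subjects: group quantiles within min/max envelope; shift commutes
  set.seed(7)
  subs <- lapply(1:6, function(i) {
    tt_i <- preprocess(trial_table(make_cell_trials(60, 10,
                                                    rt_start = 250 + 40 * i)))
    summarize_cell(tt_i, "placebo", "accuracy")
  })
  grp3 <- vincentize(subs)
  qs <- do.call(rbind, lapply(subs, function(s) s$correct_quantiles))
  expect_true(all(grp3$correct_quantiles >= apply(qs, 2, min) - 1e-12))
  expect_true(all(grp3$correct_quantiles <= apply(qs, 2, max) + 1e-12))

  shifted <- lapply(subs, function(s) {
    s$correct_quantiles <- s$correct_quantiles + 0.1
    s$error_quantiles <- s$error_quantiles + 0.1
    s
  })
  expect_equal(vincentize(shifted)$correct_quantiles,
               grp3$correct_quantiles + 0.1)

  bad <- subs[[1]]; bad$probs <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  expect_error(vincentize(list(subs[[2]], bad)), "probability grids")
})
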