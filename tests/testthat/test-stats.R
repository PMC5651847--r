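# Statistics module: GLMM fits, likelihood-ratio tests, Tukey contrasts,
# search efficiency, and the trial-table reader.

shading_5 <- c("0" = 0, "15" = 0.15, "30" = 0.3, "45" = 0.5, "90" = 1)

make_trials <- function(seed, n_participants = 10, n_trials = 200,
                        params = default_observer_params(), shading = shading_5) {
  design <- make_design(seed = seed, n_trials = n_trials)
  simulate_trials(design, n_participants, shading, params, seed = seed + 1000)
}

test_that("with no participant heterogeneity the GLMM collapses to the GLM", {
  params <- observer_params(sigma_u = 0, sigma_v = 0, guess = 0)
  trials0 <- make_trials(22, n_participants = 8, params = params)
  for (resp in c("accuracy", "rt")) {
    mer <- fit_glmm(trials0, glmm_spec(resp, "level"))
    glm_fit <- fit_glmm(trials0, glmm_spec(resp, "level", random = FALSE))
    expect_lt(mer$re_sd, 0.05)
    expect_equal(mer$fixed$estimate, glm_fit$fixed$estimate,
                 tolerance = 1e-4)
  }
})

test_that("the fit recovers known generative parameters", {
  params <- observer_params(beta0 = -1, beta1 = 4, sigma_u = 0.8,
                            guess = 0, sigma_v = 0)
  design <- make_design(seed = 23, n_trials = 2000)
  trials <- simulate_trials(design, 20, shading_5, params, seed = 99)
  fit <- fit_glmm(trials, glmm_spec("accuracy", "shading"))
  b0 <- fit$fixed[fit$fixed$term == "(Intercept)", ]
  b1 <- fit$fixed[fit$fixed$term == "shading", ]
  expect_lt(abs(b0$estimate - (-1)), 2 * b0$se)
  expect_lt(abs(b1$estimate - 4), 2 * b1$se)
  # sigma_u to roughly twice its large-sample SE at 20 participants
  expect_lt(abs(fit$re_sd - 0.8), 0.3)
  expect_true(fit$converged)
})

test_that("likelihood-ratio tests have the right degrees of freedom", {
  trials <- make_trials(24, n_participants = 6)
  full <- fit_glmm(trials, glmm_spec("accuracy", "level"))
  null <- fit_glmm(trials, glmm_spec("accuracy", "none"))
  res <- lrt(full, null)
  expect_equal(res$df, 4)          # 5-level factor vs intercept-only
  expect_gte(res$statistic, 0)
  # self-test: identical models give a null result
  self <- lrt(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(lrt(null, full), "nested")
  rtf <- fit_glmm(trials, glmm_spec("rt", "level"))
  expect_error(lrt(rtf, null), "responses")
})

test_that("a strong shading effect is detected at the study design size", {
  trials <- make_trials(25, n_participants = 10, n_trials = 200)
  for (resp in c("accuracy", "rt")) {
    full <- fit_glmm(trials, glmm_spec(resp, "level"))
    null <- fit_glmm(trials, glmm_spec(resp, "none"))
    expect_lt(lrt(full, null)$p_value, 0.001)
  }
})

test_that("Tukey tables carry 10 seeded single-step contrasts for 5 levels", {
  trials <- make_trials(26, n_participants = 8)
  fit <- fit_glmm(trials, glmm_spec("accuracy", "level"))
  tab <- tukey_pairwise(fit, seed = 3)
  expect_equal(nrow(tab), choose(5, 2))
  expect_true(all(tab$p_adj >= tab$p_raw))
  # adjusted p monotone in raw p
  expect_true(all(diff(tab$p_adj[order(tab$p_raw)]) >= -1e-8))
  # contrast estimates are differences of the fixed-effect coefficients
  fe <- fit$fixed$estimate
  names(fe) <- fit$fixed$term
  expect_equal(tab$estimate[tab$contrast == "90 - 0"],
               unname(fe["level90"]), tolerance = 1e-9)
  expect_equal(tab$estimate[tab$contrast == "90 - 15"],
               unname(fe["level90"] - fe["level15"]), tolerance = 1e-9)
  # seeded reproducibility of the quasi-random integration
  expect_identical(tab$p_adj, tukey_pairwise(fit, seed = 3)$p_adj)
})

test_that("with two levels the Tukey adjustment is the identity", {
  design <- make_design(seed = 27, levels = c(0, 90), n_trials = 200)
  trials <- simulate_trials(design, 6, shading_5[c("0", "90")],
                            default_observer_params(), seed = 12)
  fit <- fit_glmm(trials, glmm_spec("accuracy", "level"))
  tab <- tukey_pairwise(fit)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$p_adj, tab$p_raw, tolerance = 1e-6)
})

test_that("the Tukey family-wise error rate is controlled under the null", {
  null_params <- observer_params(beta1 = 0, sigma_u = 0.5, guess = 0,
                                 alpha1 = 0, alpha2 = 0)
  n_rep <- 100
  rejections <- vapply(seq_len(n_rep), function(r) {
    design <- make_design(seed = 3000 + r, n_trials = 100)
    trials <- simulate_trials(design, 8, shading_5, null_params,
                              seed = 4000 + r)
    fit <- fit_glmm(trials, glmm_spec("accuracy", "level", nAGQ = 1))
    any(tukey_pairwise(fit, seed = r)$p_adj < 0.05)
  }, logical(1))
  fwer <- mean(rejections)
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the condition contrast detects the countershading advantage with df = 1", {
  design <- make_design(seed = 31)
  cs <- simulate_trials(design, 8, shading_5, default_observer_params(),
                        seed = 61, condition = "countershaded")
  # a uniform target stays conspicuous at every orientation
  un <- simulate_trials(design, 8, shading_5,
                        observer_params(beta0 = 2, beta1 = 0.5, guess = 0),
                        seed = 62, condition = "uniform")
  trials <- rbind(cs, un)
  full <- fit_glmm(trials, glmm_spec("accuracy", "level", condition = TRUE))
  null <- fit_glmm(trials, glmm_spec("accuracy", "level"))
  res <- lrt(full, null)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 1e-6)
  expect_error(fit_glmm(cs[setdiff(names(cs), "condition")],
                        glmm_spec("accuracy", "level", condition = TRUE)),
               "condition column")
})

test_that("search-efficiency slopes vanish without a set-size effect", {
  params <- observer_params(alpha2 = 0, sigma_v = 0, guess = 0)
  trials <- make_trials(28, n_participants = 8, params = params)
  eff <- search_efficiency(trials, n_boot = 300, seed = 2)
  expect_equal(nrow(eff), 5)
  expect_true(all(abs(eff$slope) < 3 * eff$se))
  # degenerate constant-RT table gives exactly zero slopes
  trials$rt <- 2
  eff0 <- search_efficiency(trials, n_boot = 50, seed = 2)
  expect_true(all(eff0$slope == 0))
})

test_that("trial tables round-trip through the CSV reader with column maps", {
  trials <- make_trials(29, n_participants = 3, n_trials = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- data.frame(subj = trials$participant, angle = trials$level,
                    setsize = trials$n_distractors, hit = trials$correct,
                    seconds = trials$rt)
  utils::write.csv(out, path, row.names = FALSE)
  back <- read_trials(path, columns = list(participant = "subj",
                                           level = "angle",
                                           n_distractors = "setsize",
                                           correct = "hit", rt = "seconds"))
  expect_s3_class(back, "trial_table")
  expect_equal(back$rt, trials$rt)
  expect_equal(back$correct, trials$correct)
  expect_equal(as.character(back$participant), as.character(trials$participant))
  expect_error(read_trials(path), "not found")
})
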