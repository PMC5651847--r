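# Mixed-model analysis of visual-search data: binomial (logit) models for
# detection accuracy and Gamma models for reaction time, with a
# per-participant random intercept, likelihood-ratio tests of the
# departure-level factor, Tukey single-step pairwise contrasts, and the
# set-size search-efficiency summary.

#' Specify a visual-search GLMM
#'
#' @param response \code{"accuracy"} (binomial, logit link) or \code{"rt"}
#'   (Gamma).
#' @param predictor \code{"level"} fits the departure level as a factor
#'   (the headline analysis), \code{"shading"} fits the normalized apparent
#'   shading as a continuous covariate (used for parameter recovery),
#'   \code{"none"} is the intercept-only null.
#' @param link Gamma link, \code{"log"} (default; numerically safer and
#'   standard for RT means) or \code{"inverse"}. Ignored for accuracy.
#' @param set_size include \code{log(n_distractors)} as a covariate?
#' @param condition include the target-coloration factor (countershaded vs
#'   uniform) as a fixed term? Requires a \code{condition} column; the
#'   2-level comparison against a null without it has 1 degree of freedom.
#' @param random include the per-participant random intercept? With
#'   \code{FALSE} a plain GLM is fitted.
#' @param correct_only for RT models, keep correct trials only (default).
#' @param nAGQ adaptive Gauss--Hermite nodes for the scalar random
#'   intercept; default 25 (1 = Laplace).
#' @return a \code{glmm_spec} object.
#' @export
glmm_spec <- function(response = c("accuracy", "rt"),
                      predictor = c("level", "shading", "none"),
                      link = c("log", "inverse"),
                      set_size = FALSE, condition = FALSE, random = TRUE,
                      correct_only = TRUE, nAGQ = 25) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  link <- match.arg(link)
  structure(list(response = response, predictor = predictor, link = link,
                 set_size = set_size, condition = condition, random = random,
                 correct_only = correct_only, nAGQ = nAGQ),
            class = "glmm_spec")
}

glmm_formula <- function(spec, aggregated) {
  lhs <- if (spec$response == "accuracy") {
    if (aggregated) "cbind(n_correct, n_incorrect)" else "correct"
  } else "rt"
  rhs <- switch(spec$predictor, level = "level", shading = "shading",
                none = "1")
  if (spec$set_size) rhs <- paste(rhs, "+ log_n")
  if (spec$condition) rhs <- paste(rhs, "+ condition")
  if (spec$random) rhs <- paste(rhs, "+ (1 | participant)")
  stats::as.formula(paste(lhs, "~", rhs))
}

#' Fit a visual-search GLMM
#'
#' Fits the mixed model by maximum likelihood with the scalar
#' per-participant intercept integrated by adaptive Gauss--Hermite
#' quadrature (\code{nAGQ} nodes; 1 is the Laplace approximation). Accuracy
#' data are aggregated to binomial counts per participant-by-cell, which
#' leaves every likelihood ratio unchanged and speeds the fit. Complete
#' separation (a cell with all trials correct or all incorrect, pooled over
#' participants) triggers a warning and a mild data-augmentation penalty
#' (half a success and half a failure added per aggregated cell).
#' Non-convergence is flagged on the result, not thrown.
#'
#' @param trials a \code{trial_table} (from [simulate_trials()] or
#'   [read_trials()]).
#' @param spec a [glmm_spec()].
#' @return a \code{glmm_fit}: the fitted model plus fixed-effect table,
#'   random-intercept SD, log-likelihood, fixed-parameter count and a
#'   convergence flag.
#' @export
fit_glmm <- function(trials, spec = glmm_spec()) {
  stopifnot(inherits(spec, "glmm_spec"))
  dat <- as.data.frame(trials)
  if (!"participant" %in% names(dat)) stop("trials must have a participant column")
  dat$participant <- factor(dat$participant)
  if (spec$random && nlevels(dat$participant) < 2)
    stop("random intercept requires >= 2 participants")
  if (spec$predictor == "level") {
    dat$level <- factor(dat$level, levels = sort(unique(as.numeric(dat$level))))
    if (any(table(dat$level) == 0)) stop("empty level")
  }
  dat$log_n <- log(dat$n_distractors)
  if (spec$condition) {
    if (!"condition" %in% names(dat))
      stop("spec includes a condition term but trials have no condition column")
    dat$condition <- factor(dat$condition)
  }

  if (spec$response == "accuracy") {
    # one fixed aggregation grain for every accuracy model on these data,
    # so the binomial coefficients cancel in likelihood ratios
    by_vars <- intersect(c("participant", "level", "shading", "log_n",
                           "condition"),
                         names(dat))
    agg <- stats::aggregate(dat$correct, by = dat[by_vars],
                            FUN = function(x) c(sum(x), length(x)))
    agg <- cbind(agg[by_vars], n_correct = agg$x[, 1],
                 n_incorrect = agg$x[, 2] - agg$x[, 1])
    separated <- FALSE
    if (spec$predictor == "level") {
      pooled <- stats::aggregate(cbind(n_correct, n_incorrect) ~ level,
                                 data = agg, FUN = sum)
      separated <- any(pooled$n_correct == 0 | pooled$n_incorrect == 0)
    }
    if (separated) {
      warning("complete separation detected (a level with all-correct or ",
              "all-incorrect responses); applying a 0.5-count ",
              "data-augmentation penalty")
      agg$n_correct <- agg$n_correct + 0.5
      agg$n_incorrect <- agg$n_incorrect + 0.5
    }
    fml <- glmm_formula(spec, aggregated = TRUE)
    model <- if (spec$random) {
      suppressMessages(suppressWarnings(
        lme4::glmer(fml, data = agg, family = stats::binomial(),
                    nAGQ = spec$nAGQ)))
    } else {
      suppressWarnings(stats::glm(fml, data = agg, family = stats::binomial()))
    }
    n_obs <- nrow(dat)
  } else {
    if (spec$correct_only) dat <- dat[dat$correct == 1, , drop = FALSE]
    if (!nrow(dat)) stop("no trials left for the RT model")
    if (any(dat$rt <= 0)) stop("reaction times must be positive")
    fml <- glmm_formula(spec, aggregated = FALSE)
    fam <- stats::Gamma(link = spec$link)
    model <- if (spec$random) {
      suppressMessages(suppressWarnings(
        lme4::glmer(fml, data = dat, family = fam, nAGQ = spec$nAGQ)))
    } else {
      suppressWarnings(stats::glm(fml, data = dat, family = fam))
    }
    n_obs <- nrow(dat)
  }

  is_mer <- inherits(model, "merMod")
  fixed <- if (is_mer) lme4::fixef(model) else stats::coef(model)
  se <- if (is_mer) sqrt(Matrix::diag(stats::vcov(model))) else
    sqrt(diag(stats::vcov(model)))
  re_sd <- if (is_mer) {
    vc <- lme4::VarCorr(model)
    sqrt(as.numeric(vc$participant))
  } else 0
  converged <- if (is_mer) {
    msgs <- model@optinfo$conv$lme4$messages
    model@optinfo$conv$opt == 0 &&
      (is.null(msgs) || !any(grepl("failed to converge", msgs)))
  } else model$converged
  structure(list(model = model,
                 spec = spec,
                 fixed = data.frame(term = names(fixed),
                                    estimate = unname(fixed),
                                    se = unname(se)),
                 re_sd = re_sd,
                 logLik = as.numeric(stats::logLik(model)),
                 df_fixed = length(fixed),
                 converged = converged,
                 n_obs = n_obs),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("GLMM fit: %s ~ %s%s, %s\n", x$spec$response,
              x$spec$predictor, if (x$spec$set_size) " + log(set size)" else "",
              if (x$spec$random) "participant random intercept" else "no random effect"))
  cat(sprintf("  logLik %.3f, random-intercept SD %.3f, %d fixed parameters%s\n",
              x$logLik, x$re_sd, x$df_fixed,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$fixed, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' \code{chi^2 = 2 (logLik_full - logLik_null)} referred to the chi-square
#' distribution with df = difference in fixed-parameter counts. The
#' 5-level departure factor against the intercept-only null has df = 4.
#'
#' @param full,null \code{glmm_fit}s of the same response on the same data,
#'   with the null's fixed terms nested in the full's.
#' @return an \code{lrt_result}: \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
lrt <- function(full, null) {
  stopifnot(inherits(full, "glmm_fit"), inherits(null, "glmm_fit"))
  if (full$spec$response != null$spec$response)
    stop("fits model different responses")
  if (full$n_obs != null$n_obs)
    stop("fits use different numbers of observations")
  if (full$df_fixed < null$df_fixed)
    stop("null model is not nested in the full model")
  stat <- max(0, 2 * (full$logLik - null$logLik))
  df <- full$df_fixed - null$df_fixed
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.2f, d.f. = %d, p %s\n", x$statistic,
              x$df, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Tukey single-step pairwise comparisons of departure levels
#'
#' All pairwise contrasts of the level factor with single-step adjusted
#' p-values from the joint multivariate-normal distribution of the
#' contrast z statistics (the Tukey procedure for unbalanced mixed models).
#' The multivariate-normal integration uses a seeded quasi-random rule so
#' adjusted p-values are reproducible to its tolerance.
#'
#' @param fit a \code{glmm_fit} whose predictor is the level factor.
#' @param seed seed for the integration rule.
#' @return a \code{contrast_table} data frame: \code{contrast},
#'   \code{estimate}, \code{se}, \code{z}, \code{p_raw}, \code{p_adj}.
#' @export
tukey_pairwise <- function(fit, seed = 1) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (fit$spec$predictor != "level")
    stop("Tukey comparisons need the level-factor model")
  gl <- multcomp::glht(fit$model, linfct = multcomp::mcp(level = "Tukey"))
  adj <- with_seed(seed, summary(gl, test = multcomp::adjusted("single-step")))
  raw <- summary(gl, test = multcomp::adjusted("none"))
  num <- function(x) as.numeric(unname(x))
  out <- data.frame(
    contrast = names(adj$test$coefficients),
    estimate = num(adj$test$coefficients),
    se = num(adj$test$sigma),
    z = num(adj$test$tstat),
    p_raw = num(raw$test$pvalues),
    p_adj = pmax(num(adj$test$pvalues), num(raw$test$pvalues)))
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Per-level set-size slopes (search efficiency)
#'
#' For each departure level, the reaction-time cost per added distractor:
#' \code{(mean RT at 40 - mean RT at 20) / 20} over correct trials, with
#' seeded bootstrap standard errors. A slope near zero is efficient search;
#' the experimental signature is an inefficient slope at the reference
#' orientation that vanishes at 90 degrees.
#'
#' @param trials a \code{trial_table}.
#' @param correct_only use correct trials only (default)?
#' @param n_boot bootstrap resamples for the SE.
#' @param seed bootstrap seed.
#' @return data frame: \code{level}, \code{slope} (s per item), \code{se},
#'   \code{n_small}, \code{n_large}.
#' @export
search_efficiency <- function(trials, correct_only = TRUE, n_boot = 1000,
                              seed = 1) {
  dat <- as.data.frame(trials)
  if (correct_only) dat <- dat[dat$correct == 1, , drop = FALSE]
  sizes <- sort(unique(dat$n_distractors))
  if (length(sizes) != 2)
    stop("search_efficiency needs exactly two set sizes; found ",
         length(sizes))
  d_items <- diff(sizes)
  levels <- sort(unique(as.numeric(dat$level)))
  with_seed(seed, {
    rows <- lapply(levels, function(lv) {
      small <- dat$rt[dat$level == lv & dat$n_distractors == sizes[1]]
      large <- dat$rt[dat$level == lv & dat$n_distractors == sizes[2]]
      if (!length(small) || !length(large)) {
        warning("level ", lv, " lacks one set size; omitted")
        return(NULL)
      }
      slope <- (mean(large) - mean(small)) / d_items
      boot <- vapply(seq_len(n_boot), function(b) {
        (mean(sample(large, replace = TRUE)) -
           mean(sample(small, replace = TRUE))) / d_items
      }, numeric(1))
      data.frame(level = lv, slope = slope, se = stats::sd(boot),
                 n_small = length(small), n_large = length(large))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Read a visual-search trial table from CSV
#'
#' Reads deposited behavioural data whose column names differ from the
#' package's, mapping them via \code{columns}.
#'
#' @param path CSV file path.
#' @param columns named list mapping the package's column names
#'   (\code{participant}, \code{level}, \code{n_distractors},
#'   \code{correct}, \code{rt}, optionally \code{axis}) to the file's.
#' @return a \code{trial_table} data frame.
#' @export
read_trials <- function(path,
                        columns = list(participant = "participant",
                                       level = "level",
                                       n_distractors = "n_distractors",
                                       correct = "correct", rt = "rt")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unlist(columns), names(raw))
  if (length(missing))
    stop("columns not found in ", path, ": ", paste(missing, collapse = ", "))
  out <- data.frame(participant = factor(raw[[columns$participant]]),
                    level = as.numeric(raw[[columns$level]]),
                    n_distractors = as.numeric(raw[[columns$n_distractors]]),
                    correct = as.integer(raw[[columns$correct]]),
                    rt = as.numeric(raw[[columns$rt]]))
  out$axis <- if (!is.null(columns$axis)) raw[[columns$axis]] else NA_character_
  if (any(out$rt <= 0, na.rm = TRUE)) stop("non-positive reaction times")
  class(out) <- c("trial_table", "data.frame")
  out
}
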