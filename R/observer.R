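# Synthetic visual-search observers. Per-trial accuracy is Bernoulli with
# a guess floor and a logistic dependence on the target's normalized
# apparent shading; reaction times are Gamma with a log-linear mean that
# falls with shading and carries a set-size cost that decays as shading
# grows (search turns efficient for conspicuous targets). Participants get
# Gaussian random intercepts on both scales — the generative counterpart of
# the binomial / Gamma mixed models used in the analysis stage.

#' Observer parameter set
#'
#' Generative parameters for [simulate_trials()].
#'
#' Accuracy: \code{P(correct) = g + (1 - g) * plogis(beta0 + beta1 * s +
#' u_j)} with normalized shading \code{s} in [0, 1] and participant
#' intercept \code{u_j ~ N(0, sigma_u^2)}. The guess floor \code{g}
#' reflects the forced-choice identification stage; \code{NA} means
#' \code{1 / (n_items + 1)} computed per trial, 0 disables it.
#'
#' Reaction time: Gamma with shape \code{k} and mean \code{mu},
#' \code{log(mu) = alpha0 + alpha1 * s + alpha2 * exp(-efficiency_decay *
#' s) * log(n_distractors) + v_j}, \code{v_j ~ N(0, sigma_v^2)}. With
#' \code{alpha1 < 0} conspicuous targets are found faster; the
#' \code{exp(-efficiency_decay * s)} factor shrinks the set-size cost so
#' search is inefficient near the reference orientation and efficient at
#' large departures.
#'
#' @param beta0,beta1 accuracy intercept and shading slope (log-odds).
#' @param guess guess floor in [0, 1), or \code{NA} for per-trial
#'   \code{1 / (n_items + 1)}.
#' @param sigma_u accuracy random-intercept SD (log-odds, >= 0).
#' @param alpha0,alpha1,alpha2 RT intercept, shading slope and set-size
#'   slope on the log-seconds scale.
#' @param efficiency_decay decay rate of the set-size slope in s (>= 0).
#' @param shape Gamma shape k (> 0).
#' @param sigma_v RT random-intercept SD (log-seconds, >= 0).
#' @return an \code{observer_params} object.
#' @export
observer_params <- function(beta0 = -0.5, beta1 = 4, guess = NA,
                            sigma_u = 0.8, alpha0 = 0.56, alpha1 = -1,
                            alpha2 = 0.35, efficiency_decay = 3,
                            shape = 8, sigma_v = 0.3) {
  if (!is.na(guess) && (guess < 0 || guess >= 1))
    stop("guess must lie in [0, 1) or be NA")
  if (sigma_u < 0 || sigma_v < 0) stop("random-intercept SDs must be >= 0")
  if (shape <= 0) stop("Gamma shape must be > 0")
  if (efficiency_decay < 0) stop("efficiency_decay must be >= 0")
  structure(list(beta0 = beta0, beta1 = beta1, guess = guess,
                 sigma_u = sigma_u, alpha0 = alpha0, alpha1 = alpha1,
                 alpha2 = alpha2, efficiency_decay = efficiency_decay,
                 shape = shape, sigma_v = sigma_v),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer parameters\n")
  cat(sprintf("  accuracy: beta0 %g, beta1 %g, guess %s, sigma_u %g\n",
              x$beta0, x$beta1,
              if (is.na(x$guess)) "1/(n_items+1)" else format(x$guess),
              x$sigma_u))
  cat(sprintf(
    "  rt: alpha0 %g, alpha1 %g, alpha2 %g, decay %g, shape %g, sigma_v %g\n",
    x$alpha0, x$alpha1, x$alpha2, x$efficiency_decay, x$shape, x$sigma_v))
  invisible(x)
}

#' Default observer parameter presets
#'
#' \code{"qualitative"}: the package defaults, chosen once to reproduce the
#' qualitative experimental pattern (accuracy rising and RT falling with
#' departure from the reference orientation; set-size cost vanishing at 90
#' degrees) at plausible human magnitudes. They are not fitted to any
#' behavioural dataset. \code{"none"}: the same slopes with guess floor 0
#' and both random-intercept SDs 0 — deterministic participant means, the
#' configuration used for parameter-recovery studies.
#'
#' @param calibration \code{"qualitative"} or \code{"none"}.
#' @return an \code{observer_params} object.
#' @export
default_observer_params <- function(calibration = c("qualitative", "none")) {
  calibration <- match.arg(calibration)
  if (calibration == "qualitative") observer_params()
  else observer_params(guess = 0, sigma_u = 0, sigma_v = 0)
}

#' Simulate visual-search trials
#'
#' Runs \code{n_participants} synthetic observers through the trial design,
#' producing the per-trial accuracy and reaction-time table the statistics
#' stage consumes. Fully reproducible from the seed.
#'
#' @param design a [make_design()] table (one session; every participant
#'   sees the same balanced design).
#' @param n_participants number of observers.
#' @param shading named numeric vector mapping each design level to its
#'   normalized apparent shading in [0, 1] (see [shading_lookup()]).
#' @param params an [observer_params()] set.
#' @param seed integer seed.
#' @param axis experiment label stored in the table.
#' @param condition target-coloration label stored in the table
#'   (\code{"countershaded"} or \code{"uniform"}); tables for the two
#'   conditions are simulated separately (with their own parameter sets)
#'   and row-bound for condition-contrast analyses.
#' @return a \code{trial_table} data frame: \code{participant},
#'   \code{axis}, \code{condition}, \code{level}, \code{n_distractors},
#'   \code{shading}, \code{correct} (0/1), \code{rt} (seconds).
#' @examples
#' design <- make_design(seed = 1, n_trials = 50)
#' s <- c("0" = 0, "15" = 0.2, "30" = 0.4, "45" = 0.6, "90" = 1)
#' trials <- simulate_trials(design, n_participants = 3, shading = s,
#'                           params = default_observer_params(), seed = 1)
#' @export
simulate_trials <- function(design, n_participants, shading,
                            params = default_observer_params(),
                            seed = 1, axis = "pitch",
                            condition = "countershaded") {
  stopifnot(inherits(params, "observer_params"))
  lv <- as.character(design$level)
  if (!all(lv %in% names(shading)))
    stop("shading must name every design level: missing ",
         paste(setdiff(unique(lv), names(shading)), collapse = ", "))
  s <- unname(shading[lv])
  if (any(s < 0 | s > 1)) stop("shading values must lie in [0, 1]")
  n_trial <- nrow(design)
  with_seed(seed, {
    u <- stats::rnorm(n_participants, 0, params$sigma_u)
    v <- stats::rnorm(n_participants, 0, params$sigma_v)
    out <- vector("list", n_participants)
    for (j in seq_len(n_participants)) {
      g <- if (is.na(params$guess)) 1 / (design$n_distractors + 2)
      else params$guess
      p <- g + (1 - g) *
        stats::plogis(params$beta0 + params$beta1 * s + u[j])
      mu <- exp(params$alpha0 + params$alpha1 * s +
                  params$alpha2 * exp(-params$efficiency_decay * s) *
                  log(design$n_distractors) + v[j])
      out[[j]] <- data.frame(
        participant = j, axis = axis, condition = condition,
        level = design$level,
        n_distractors = design$n_distractors, shading = s,
        correct = stats::rbinom(n_trial, 1, p),
        rt = stats::rgamma(n_trial, shape = params$shape,
                           rate = params$shape / mu))
    }
    tab <- do.call(rbind, out)
    tab$participant <- factor(tab$participant)
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}
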