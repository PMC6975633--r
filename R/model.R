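#' Exponential-plateau BMD loss model
#'
#' Constructs the one-phase exponential decay model of femoral-neck bone
#' mineral density (BMD) loss in microgravity,
#' \deqn{L(t) = (C - P) e^{-\lambda t} + P,}
#' where \eqn{L(t)} is the percent BMD loss after \eqn{t} days of
#' spaceflight (loss is stored as a POSITIVE percentage), \eqn{C} is the
#' loss at launch, \eqn{P} the asymptotic plateau, and \eqn{\lambda} the
#' per-day decay rate. The defaults \eqn{C = 0}, \eqn{P = 69} encode the
#' terrestrial-disuse evidence that femoral-neck loss plateaus at 69\% of
#' pre-flight BMD, leaving \eqn{\lambda} as the single free parameter.
#'
#' @param lambda_rate decay rate per day; must be positive.
#' @param plateau_pct asymptotic maximum loss, percent of pre-flight BMD.
#' @param baseline_pct loss at launch, percent; defaults to 0.
#' @return an object of class \code{decay_model}.
#' @seealso [predict_loss()], [derive_kinetics()], [fit_decay()]
#' @examples
#' m <- decay_model(6.371e-4)
#' predict_loss(m, c(400, 600, 1000, 1200))
#' @export
decay_model <- function(lambda_rate, plateau_pct = 69.0, baseline_pct = 0.0) {
  stopifnot(is.numeric(lambda_rate), length(lambda_rate) == 1L,
            is.numeric(plateau_pct), length(plateau_pct) == 1L,
            is.numeric(baseline_pct), length(baseline_pct) == 1L)
  if (!is.finite(lambda_rate) || lambda_rate <= 0)
    stop("'lambda_rate' must be a positive, finite decay rate (per day)")
  if (baseline_pct < 0 || baseline_pct >= plateau_pct || plateau_pct > 100)
    stop("require 0 <= baseline_pct < plateau_pct <= 100")
  structure(list(lambda_rate = lambda_rate, plateau_pct = plateau_pct,
                 baseline_pct = baseline_pct),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Exponential-plateau BMD loss model\n")
  cat(sprintf("  loss(t) = (%.4g - %.4g) exp(-%.6g t) + %.4g   [%%, t in days]\n",
              x$baseline_pct, x$plateau_pct, x$lambda_rate, x$plateau_pct))
  k <- derive_kinetics(x)
  cat(sprintf("  half-life %.0f d, time constant %.0f d, plateau %.1f%%\n",
              k$half_life_days, k$time_constant_days, x$plateau_pct))
  invisible(x)
}

check_days <- function(t_days) {
  if (!is.numeric(t_days) || anyNA(t_days) || any(t_days < 0))
    stop("'t_days' must be non-negative and finite")
  invisible(t_days)
}

#' Predicted percent BMD loss at a flight duration
#'
#' Evaluates \eqn{(C - P) e^{-\lambda t} + P}. Vectorised over `t_days`;
#' [predict_trajectory()] is an explicit alias for grid evaluation.
#'
#' @param model a [decay_model()].
#' @param t_days non-negative duration(s) in days.
#' @return percent loss, in `[C, P)`, strictly increasing in `t_days`.
#' @examples
#' predict_loss(decay_model(6.371e-4), 1088)  # ~34.5, half the plateau
#' @export
predict_loss <- function(model, t_days) {
  stopifnot(inherits(model, "decay_model"))
  check_days(t_days)
  (model$baseline_pct - model$plateau_pct) * exp(-model$lambda_rate * t_days) +
    model$plateau_pct
}

#' @rdname predict_loss
#' @param t_grid sequence of non-negative durations in days.
#' @export
predict_trajectory <- function(model, t_grid) predict_loss(model, t_grid)

#' Remaining fraction of pre-flight BMD
#'
#' `1 - predict_loss(model, t)/100`: the multiplier applied to a
#' pre-mission BMD to obtain the post-mission value.
#'
#' @inheritParams predict_loss
#' @return fraction in `((100 - P)/100, 1]`.
#' @export
remaining_bmd_fraction <- function(model, t_days) {
  1 - predict_loss(model, t_days) / 100
}

#' First-order kinetics derived from the decay rate
#'
#' @param model a [decay_model()].
#' @return list of class `decay_kinetics` with `half_life_days`
#'   (\eqn{\ln 2/\lambda}) and `time_constant_days` (\eqn{1/\lambda}).
#' @examples
#' derive_kinetics(decay_model(6.371e-4))  # ~1088 d and ~1570 d
#' @export
derive_kinetics <- function(model) {
  stopifnot(inherits(model, "decay_model"))
  structure(list(half_life_days = log(2) / model$lambda_rate,
                 time_constant_days = 1 / model$lambda_rate),
            class = "decay_kinetics")
}

#' Flight duration producing a given loss
#'
#' Algebraic inversion of the decay curve:
#' \eqn{t = -\log((L - P)/(C - P))/\lambda}. Round-trips with
#' [predict_loss()] to relative tolerance 1e-10 on `[C, P)`.
#'
#' @param model a [decay_model()].
#' @param loss_pct target percent loss; must satisfy `C <= loss_pct < P`
#'   (the plateau itself is reached only asymptotically).
#' @return duration in days.
#' @export
invert_time_for_loss <- function(model, loss_pct) {
  stopifnot(inherits(model, "decay_model"), is.numeric(loss_pct))
  if (any(loss_pct < model$baseline_pct))
    stop("'loss_pct' below the launch baseline C")
  if (any(loss_pct >= model$plateau_pct))
    stop("no finite duration reaches the plateau P; require loss_pct < P")
  -log((loss_pct - model$plateau_pct) /
         (model$baseline_pct - model$plateau_pct)) / model$lambda_rate
}

#' Linear loss comparator
#'
#' The constant-rate model used throughout the earlier spaceflight
#' literature: monthly loss of (1.06 +/- 0.63) percent at the femoral
#' neck. Deliberately NOT clamped at 100\%: for multi-year durations it
#' predicts losses exceeding total BMD, which is the physical argument
#' for the plateau model.
#'
#' @param rate_pct_per_month mean monthly percent loss (default 1.06).
#' @param rate_sd_pct_per_month its dispersion (default 0.63); stored,
#'   not used in prediction.
#' @param month_days days per month used for conversion (default 30).
#' @return object of class `linear_model`.
#' @export
linear_model <- function(rate_pct_per_month = 1.06,
                         rate_sd_pct_per_month = 0.63,
                         month_days = 30) {
  if (rate_pct_per_month <= 0 || month_days <= 0)
    stop("rate and month length must be positive")
  structure(list(rate_pct_per_month = rate_pct_per_month,
                 rate_sd_pct_per_month = rate_sd_pct_per_month,
                 month_days = month_days),
            class = "linear_model")
}

#' @rdname linear_model
#' @param lin a `linear_model`.
#' @param t_days non-negative duration(s) in days.
#' @return percent loss `rate * t_days / month_days`, unbounded above.
#' @export
linear_loss <- function(lin, t_days) {
  stopifnot(inherits(lin, "linear_model"))
  check_days(t_days)
  lin$rate_pct_per_month * t_days / lin$month_days
}
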