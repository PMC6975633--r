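# T-score propagation and fracture-risk classification. Predicted losses
# are applied multiplicatively to each demographic group's mean
# pre-mission femoral-neck BMD; the resulting post-mission BMD is scored
# against the young-adult reference and classified under WHO and NASA
# criteria.

#' Young-adult reference for T-scores
#'
#' Mean and SD of femoral-neck BMD for the WHO young-adult reference
#' population (Caucasian women aged 20-29): 0.858 and 0.120 g/cm2.
#'
#' @param mean_bmd reference mean in g/cm2.
#' @param sd_bmd reference SD in g/cm2.
#' @return object of class `ya_reference`.
#' @export
young_adult_reference <- function(mean_bmd = 0.858, sd_bmd = 0.120) {
  if (mean_bmd <= 0 || sd_bmd <= 0) stop("reference mean and SD must be positive")
  structure(list(mean_bmd = mean_bmd, sd_bmd = sd_bmd), class = "ya_reference")
}

#' Post-mission BMD from a percent loss
#'
#' `premission_bmd * (100 - loss_pct)/100`.
#'
#' @param premission_bmd pre-mission femoral-neck BMD in g/cm2 (> 0).
#' @param loss_pct percent loss in `[0, 100]`.
#' @return post-mission BMD in g/cm2. Vectorised.
#' @export
post_mission_bmd <- function(premission_bmd, loss_pct) {
  if (any(premission_bmd <= 0)) stop("'premission_bmd' must be positive")
  if (any(loss_pct < 0 | loss_pct > 100))
    stop("'loss_pct' must lie in [0, 100]")
  premission_bmd * (100 - loss_pct) / 100
}

#' T-score of a femoral-neck BMD
#'
#' Number of reference SDs the BMD lies above (positive) or below
#' (negative) the young-adult reference mean.
#'
#' @param post_bmd BMD in g/cm2 (>= 0).
#' @param ref a [young_adult_reference()].
#' @return T-score in SD units. Vectorised.
#' @examples
#' t_score(0.738)  # exactly one SD below: -1
#' @export
t_score <- function(post_bmd, ref = young_adult_reference()) {
  stopifnot(inherits(ref, "ya_reference"))
  if (any(post_bmd < 0)) stop("'post_bmd' must be non-negative")
  (post_bmd - ref$mean_bmd) / ref$sd_bmd
}

#' Back-solve a pre-mission BMD from an observed T-score
#'
#' Inverts the loss -> post-BMD -> T-score chain:
#' `(mean + sd * t) / ((100 - loss_pct)/100)`. Used to reconstruct
#' unpublished group mean pre-mission BMDs from a printed T-score column;
#' round-trips exactly through [post_mission_bmd()] and [t_score()].
#'
#' @param tscore observed T-score.
#' @param loss_pct percent loss already incurred at the observation time
#'   (< 100).
#' @param ref a [young_adult_reference()].
#' @return pre-mission BMD in g/cm2. Vectorised over `tscore`.
#' @export
backsolve_premission_bmd <- function(tscore, loss_pct,
                                     ref = young_adult_reference()) {
  stopifnot(inherits(ref, "ya_reference"))
  if (any(loss_pct >= 100)) stop("'loss_pct' must be below 100")
  pre <- (ref$mean_bmd + ref$sd_bmd * tscore) / ((100 - loss_pct) / 100)
  if (any(pre <= 0)) stop("back-solved pre-mission BMD is non-positive")
  pre
}

#' WHO classification of a T-score
#'
#' Osteoporosis for T <= -2.5 (boundary inclusive), osteopenia for
#' -2.5 < T < -1, normal for T >= -1. Classification always uses the
#' unrounded T-score.
#'
#' @param tscore finite T-score(s).
#' @return factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @export
classify_who <- function(tscore) {
  if (any(!is.finite(tscore))) stop("'tscore' must be finite")
  cls <- ifelse(tscore <= -2.5, "osteoporosis",
                ifelse(tscore < -1, "osteopenia", "normal"))
  factor(cls, levels = c("normal", "osteopenia", "osteoporosis"))
}

#' NASA permissible-outcome flag
#'
#' NASA crew-health standards set a non-permissible limit at T-score -2;
#' an outcome is permissible iff T > -2 (strict).
#'
#' @param tscore finite T-score(s).
#' @return logical, `TRUE` when permissible.
#' @export
nasa_permissible <- function(tscore) {
  if (any(!is.finite(tscore))) stop("'tscore' must be finite")
  tscore > -2
}

#' Assess mission risk for demographic groups
#'
#' For every (group, duration) pair: predict the percent loss, apply it
#' to the group's pre-mission BMD, compute the T-score and classify
#' under the WHO and NASA criteria.
#'
#' @param model a [decay_model()].
#' @param groups data.frame of reference groups with columns `sex`,
#'   `ethnicity`, `age_min`, `age_max`, `premission_bmd_g_cm2`
#'   (see [read_reference_groups()]).
#' @param durations mission durations in days.
#' @param ref a [young_adult_reference()].
#' @return data.frame with one row per (group, duration):
#'   the group columns plus `mission_days`, `predicted_loss_pct`,
#'   `post_bmd`, `t_score`, `who_class`, `nasa_permissible`.
#' @examples
#' groups <- read_reference_groups(
#'   marsbmd_extdata("reference_groups_synthetic.csv"))
#' assess_mission(decay_model(6.371e-4), groups, c(400, 600, 1000, 1200))
#' @export
assess_mission <- function(model, groups, durations,
                           ref = young_adult_reference()) {
  stopifnot(inherits(model, "decay_model"), inherits(ref, "ya_reference"))
  groups <- as.data.frame(groups)
  if (nrow(groups) == 0L) stop("'groups' must be non-empty")
  check_days(durations)
  if (anyDuplicated(durations)) stop("duplicate durations requested")
  key <- interaction(groups$sex, groups$ethnicity, groups$age_min, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate (sex, ethnicity, age band) group")
  out <- merge(cbind(groups, .k = 1),
               data.frame(.k = 1, mission_days = durations))
  out$.k <- NULL
  out$predicted_loss_pct <- predict_loss(model, out$mission_days)
  out$post_bmd <- post_mission_bmd(out$premission_bmd_g_cm2,
                                   out$predicted_loss_pct)
  out$t_score <- t_score(out$post_bmd, ref)
  out$who_class <- classify_who(out$t_score)
  out$nasa_permissible <- nasa_permissible(out$t_score)
  out[order(out$mission_days, out$sex, out$ethnicity, out$age_min), ,
      drop = FALSE]
}

#' Mission-class scenario
#'
#' @param name scenario label; the canonical Mars profiles are
#'   `"opposition"` (short stay, 400-600 days) and `"conjunction"`
#'   (long stay, 1000-1200 days).
#' @param min_days,max_days bounding durations in days.
#' @return object of class `mission_scenario`.
#' @export
mission_scenario <- function(name = c("opposition", "conjunction"),
                             min_days = NULL, max_days = NULL) {
  name <- match.arg(name)
  if (is.null(min_days))
    min_days <- switch(name, opposition = 400, conjunction = 1000)
  if (is.null(max_days))
    max_days <- switch(name, opposition = 600, conjunction = 1200)
  if (!(min_days > 0 && min_days < max_days))
    stop("require 0 < min_days < max_days")
  structure(list(name = name, min_days = min_days, max_days = max_days),
            class = "mission_scenario")
}

#' Headline classification fractions for a mission scenario
#'
#' Restricts an assessment table to the scenario's two bounding
#' durations and reports the percentage of cells that are
#' NASA-non-permissible (T < -2), osteoporotic (T <= -2.5), and
#' osteopenic or worse (T < -1).
#'
#' @param assessments output of [assess_mission()] (or any data.frame
#'   with `mission_days` and `t_score`).
#' @param scenario a [mission_scenario()].
#' @return list with `n_cells`, counts and `pct_*` percentages.
#' @export
summarize_classifications <- function(assessments, scenario) {
  stopifnot(inherits(scenario, "mission_scenario"))
  a <- assessments[assessments$mission_days %in%
                     c(scenario$min_days, scenario$max_days), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no assessments at the scenario's bounding durations")
  n <- nrow(a)
  np <- sum(!nasa_permissible(a$t_score))
  op <- sum(classify_who(a$t_score) == "osteoporosis")
  pen <- sum(classify_who(a$t_score) != "normal")
  list(scenario = scenario$name, n_cells = n,
       n_non_permissible = np, pct_non_permissible = 100 * np / n,
       n_osteoporosis = op, pct_osteoporosis = 100 * op / n,
       n_osteopenia_or_worse = pen, pct_osteopenia_or_worse = 100 * pen / n)
}

#' Unpaired two-sample t-test
#'
#' Classical unpaired t-test between two groups of values (pooled
#' variance Student form by default; Welch available).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
two_sample_ttest <- function(sample_a, sample_b, welch = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least two values")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("both samples have zero variance; t statistic undefined")
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
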