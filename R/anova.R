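#' Descriptive statistics of the descriptor table
#'
#' Mean and standard error (sd / sqrt(n)) of each feature per group x period
#' cell, plus `Overall` rows pooling the two periods, mirroring the layout of
#' the study's descriptive tables.
#'
#' @param descriptors A descriptor tibble with `group`, `period` and the
#'   feature columns.
#' @param features Character vector of feature columns (default
#'   `c("SM", "LS", "B")`).
#' @return A tibble with columns `group`, `period` (including `"Overall"`),
#'   `feature`, `n`, `mean`, `se`, `se_defined`. Cells with a single value
#'   have `se = NA` and `se_defined = FALSE`; empty cells are absent.
#' @export
descriptive_stats <- function(descriptors, features = c("SM", "LS", "B")) {
  if (!is.data.frame(descriptors) || nrow(descriptors) == 0L) {
    mf_abort("`descriptors` must be a non-empty data frame.", "input")
  }
  missing_cols <- setdiff(c("group", "period", features), names(descriptors))
  if (length(missing_cols) > 0) {
    mf_abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."),
             "input")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(descriptors, "group", "period", dplyr::all_of(features)),
    cols = dplyr::all_of(features), names_to = "feature", values_to = "value")
  cell <- function(d) {
    dplyr::summarise(
      d,
      n = dplyr::n(),
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
  }
  per_period <- cell(dplyr::group_by(long, .data$group, .data$period, .data$feature))
  per_period$period <- as.character(per_period$period)
  overall <- cell(dplyr::group_by(long, .data$group, .data$feature))
  overall$period <- "Overall"
  out <- dplyr::bind_rows(per_period, overall)
  out$se_defined <- !is.na(out$se)
  out$feature <- factor(out$feature, levels = features)
  dplyr::arrange(out, .data$group, .data$feature, .data$period)
}

#' Unbalanced three-way main-effects ANOVA per descriptor
#'
#' Fits the main-effects model `y = mu + group + period + time + error`
#' (no interactions, no subject term) with sum-to-zero contrasts and tests
#' each effect by its Type III F statistic (for a main-effects-only model
#' this equals the Type II statistic). `time` is the day index (Day model,
#' 4 df) or the hour slot (Hour model, 6 df).
#'
#' @param descriptors Descriptor tibble with `group`, `period`, the time
#'   column (`day` or `hour_slot`) and the feature column.
#' @param model `"day"` or `"hour"`.
#' @param feature Name of the response column (e.g. `"SM"`).
#' @return An object of class `mf_anova` with the effect table and the
#'   underlying `lm` fit.
#' @examples
#' d <- simulate_descriptors("day", seed = 1)
#' fit <- fit_threeway_anova(d, "day", "SM")
#' tidy(fit)
#' @export
fit_threeway_anova <- function(descriptors, model = c("day", "hour"), feature) {
  model <- match.arg(model)
  time_col <- if (model == "day") "day" else "hour_slot"
  need <- c("group", "period", time_col, feature)
  missing_cols <- setdiff(need, names(descriptors))
  if (length(missing_cols) > 0) {
    mf_abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."),
             "input")
  }
  as_full_factor <- function(x) {
    factor(x, levels = if (is.factor(x)) levels(x) else sort(unique(x)))
  }
  d <- tibble(
    y = descriptors[[feature]],
    group = as_full_factor(descriptors$group),
    period = as_full_factor(descriptors$period),
    time = as_full_factor(descriptors[[time_col]]))
  if (anyNA(d$y)) mf_abort("The response contains missing values.", "input")
  for (fac in c("group", "period", "time")) {
    tabs <- table(d[[fac]])
    bad <- names(tabs)[tabs < 2]
    if (nlevels(d[[fac]]) < 2 || length(bad) > 0) {
      mf_abort(paste0("Factor `", fac, "` has an empty or singleton level",
                      if (length(bad)) paste0(" (", paste(bad, collapse = ", "), ")"),
                      "."), "input")
    }
  }
  fit <- lm(y ~ group + period + time, data = d,
            contrasts = list(group = "contr.sum", period = "contr.sum",
                             time = "contr.sum"))
  dr <- drop1(fit, scope = ~ group + period + time, test = "F")
  eff <- tibble(
    effect = c("Group", "Depletion/Repletion", "Time"),
    term = c("group", "period", "time"),
    df = dr$Df[-1],
    sum_sq = dr$`Sum of Sq`[-1],
    F = dr$`F value`[-1],
    p = dr$`Pr(>F)`[-1])
  structure(list(effects = eff, fit = fit, model = model, feature = feature,
                 residual_df = fit$df.residual,
                 grand_mean = unname(coef(fit)[1])),
            class = "mf_anova")
}

#' @export
print.mf_anova <- function(x, ...) {
  cat("<mf_anova> ", x$model, " model, feature ", x$feature,
      " (residual df ", x$residual_df, ")\n", sep = "")
  print(as.data.frame(x$effects[, c("effect", "df", "F", "p")]), row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_threeway_anova Effect table (`effect`, `df`, `F`, `p`).
#' @param x,... An `mf_anova`; further arguments ignored.
#' @method tidy mf_anova
#' @export
tidy.mf_anova <- function(x, ...) x$effects

#' @describeIn fit_threeway_anova One-row model summary.
#' @method glance mf_anova
#' @export
glance.mf_anova <- function(x, ...) {
  tibble(model = x$model, feature = x$feature,
         grand_mean = x$grand_mean, residual_df = x$residual_df,
         sigma = summary(x$fit)$sigma,
         r_squared = summary(x$fit)$r.squared)
}

#' Render the p-value table across models and features
#'
#' Fits the three-way ANOVA for every requested feature of one or two
#' descriptor tables and lays the p-values out with effects as rows and
#' features as columns, one block per model.
#'
#' @param day_descriptors,hour_descriptors Descriptor tibbles (either may be
#'   `NULL`).
#' @param features Feature columns to analyse.
#' @return A tibble with columns `model`, `effect` and one p-value column
#'   per feature.
#' @export
anova_table <- function(day_descriptors = NULL, hour_descriptors = NULL,
                        features = c("SM", "LS", "B")) {
  one_model <- function(d, model) {
    cols <- purrr::map(features, function(f) {
      tidy(fit_threeway_anova(d, model, f))$p
    })
    names(cols) <- features
    dplyr::bind_cols(
      tibble(model = model,
             effect = c("Group", "Depletion/Repletion", "Time")),
      tibble::as_tibble(cols))
  }
  out <- list()
  if (!is.null(day_descriptors)) out$day <- one_model(day_descriptors, "day")
  if (!is.null(hour_descriptors)) out$hour <- one_model(hour_descriptors, "hour")
  if (length(out) == 0) mf_abort("Provide at least one descriptor table.", "input")
  dplyr::bind_rows(out)
}
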