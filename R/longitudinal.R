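## Longitudinal change metrics and Fearon cachexia classification.

#' Body mass index
#'
#' @param weight_kg Weight in kilograms (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2 (weight / height^2).
#' @examples
#' compute_bmi(80, 1.79)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' Maximum change relative to baseline
#'
#' For a metric observed at baseline and one or more follow-ups, computes the
#' change versus baseline at every follow-up and returns the one of largest
#' magnitude, keeping its sign (so a dominant loss reports as negative).
#' Absolute mode is used for PDFF (percentage points); relative mode
#' (% of baseline) for volumes and BMI. Ties in magnitude go to the earliest
#' follow-up.
#'
#' @param baseline Metric value at baseline.
#' @param followups Numeric vector of follow-up values, in time order.
#' @param mode `"absolute"` (follow - baseline, metric units) or `"relative"`
#'   (100 * (follow - baseline) / baseline, % of baseline).
#' @param followup_days Optional day offsets of the follow-ups (reported in
#'   the result).
#' @return A list of class `change_record`: `change` (the signed maximum),
#'   `mode`, `at_followup` (index), `followup_day` (or `NA`), and
#'   `all_changes`.
#' @examples
#' max_change(100, c(90, 105), mode = "relative")  # -10
#' @export
max_change <- function(baseline, followups, mode = c("absolute", "relative"),
                       followup_days = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(baseline)) stop("'baseline' must be finite")
  if (length(followups) < 1 || any(!is.finite(followups)))
    stop("need at least one finite follow-up value")
  ch <- followups - baseline
  if (mode == "relative") {
    if (baseline == 0)
      stop("relative change undefined at baseline = 0")
    ch <- 100 * ch / baseline
  }
  k <- which.max(abs(ch))  # earliest on ties
  structure(
    list(change = ch[k], mode = mode, at_followup = k,
         followup_day = if (is.null(followup_days)) NA_real_
                        else followup_days[k],
         all_changes = ch),
    class = "change_record")
}

#' @export
print.change_record <- function(x, ...) {
  cat(sprintf("<change_record> %s max change %.3f%s at follow-up %d\n",
              x$mode, x$change, if (x$mode == "relative") "%" else "",
              x$at_followup))
  invisible(x)
}

#' Fearon consensus cachexia classification
#'
#' A subject is cachectic if, over any 6-month (183-day) window of the weight
#' history, at least one of the consensus criteria holds:
#' \enumerate{
#'   \item unintentional weight loss > 5% of the window's starting weight;
#'   \item weight loss > 2% with BMI < 20 kg/m^2;
#'   \item sarcopenia together with weight loss > 2%.
#' }
#' A self-reported pre-baseline loss (kg over the preceding 6 months) is
#' accepted as an additional baseline-window observation.
#'
#' @param weights Numeric vector of measured weights (kg).
#' @param days Day offsets of the weight measurements (baseline = 0).
#' @param height_m Height in metres, used for the BMI criterion; if missing
#'   (`NA`), that criterion is skipped with a message.
#' @param self_reported_loss_kg Optional weight (kg) lost in the 6 months
#'   before the first measurement; 0 or `NA` for none.
#' @param sarcopenia Logical flag from an external assessment (appendicular
#'   lean-mass indices are not computed here); `NA` skips criterion 3.
#' @return A list of class `cachexia_call`: `cachectic` (logical),
#'   `criterion` (`"weight_loss_5pct"`, `"low_bmi_loss_2pct"`,
#'   `"sarcopenia_loss_2pct"` or `NA`), and `max_loss_pct` over all windows.
#' @examples
#' classify_cachexia(c(80, 75), c(0, 120), height_m = 1.8)
#' @export
classify_cachexia <- function(weights, days, height_m = NA,
                              self_reported_loss_kg = 0,
                              sarcopenia = FALSE) {
  weights <- as.numeric(weights)
  days <- as.numeric(days)
  if (length(weights) != length(days)) stop("'weights' and 'days' lengths differ")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be positive")
  o <- order(days)
  weights <- weights[o]; days <- days[o]
  if (!is.na(self_reported_loss_kg) && self_reported_loss_kg > 0) {
    # pre-baseline observation: weight before the reported loss, half a
    # window before the first measurement
    weights <- c(weights[1] + self_reported_loss_kg, weights)
    days <- c(days[1] - 91, days)
  }
  if (length(weights) < 2)
    stop("need >= 2 weight observations (or a self-reported prior loss)")

  window_days <- 183
  loss_pct <- 0
  for (i in seq_along(weights)) {
    in_win <- which(days > days[i] & days <= days[i] + window_days)
    for (j in in_win)
      loss_pct <- max(loss_pct, 100 * (weights[i] - weights[j]) / weights[i])
  }

  bmi <- if (!is.na(height_m)) compute_bmi(min(weights), height_m) else NA_real_

  if (loss_pct > 5) {
    crit <- "weight_loss_5pct"; cach <- TRUE
  } else if (!is.na(bmi) && bmi < 20 && loss_pct > 2) {
    crit <- "low_bmi_loss_2pct"; cach <- TRUE
  } else if (isTRUE(sarcopenia) && loss_pct > 2) {
    crit <- "sarcopenia_loss_2pct"; cach <- TRUE
  } else {
    if (is.na(height_m) && loss_pct > 2)
      message("height missing: BMI criterion skipped")
    crit <- NA_character_; cach <- FALSE
  }
  structure(list(cachectic = cach, criterion = crit, max_loss_pct = loss_pct),
            class = "cachexia_call")
}

#' @export
print.cachexia_call <- function(x, ...) {
  cat(sprintf("<cachexia_call> %s (max 6-month loss %.1f%%)%s\n",
              if (x$cachectic) "cachectic" else "not cachectic",
              x$max_loss_pct,
              if (x$cachectic) paste0(", criterion: ", x$criterion) else ""))
  invisible(x)
}

#' Maximum-change table for a subject's longitudinal metrics
#'
#' Takes a long-format metrics table for one or more subjects and computes,
#' per subject x muscle x section x metric, the maximum change versus the
#' baseline (day 0) row: absolute change for `mean_pdff_pct` (percentage
#' points), relative change for volumes.
#'
#' @param metrics_long `data.frame` with columns `subject_id`, `day_offset`,
#'   `muscle`, `section`, `metric`, `value`; baseline rows have
#'   `day_offset == 0`.
#' @return `data.frame` with columns `subject_id`, `muscle`, `section`,
#'   `metric`, `mode`, `max_change`, `followup_day`.
#' @export
max_change_table <- function(metrics_long) {
  need <- c("subject_id", "day_offset", "muscle", "section", "metric", "value")
  if (!all(need %in% names(metrics_long)))
    stop("metrics table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(metrics_long$subject_id, metrics_long$muscle,
                     metrics_long$section, metrics_long$metric, drop = TRUE)
  rows <- lapply(split(metrics_long, key), function(g) {
    g <- g[order(g$day_offset), ]
    base <- g$value[g$day_offset == 0]
    fw <- g[g$day_offset > 0, ]
    if (length(base) != 1 || nrow(fw) == 0) return(NULL)
    mode <- if (g$metric[1] == "mean_pdff_pct") "absolute" else "relative"
    mc <- max_change(base, fw$value, mode = mode, followup_days = fw$day_offset)
    data.frame(subject_id = g$subject_id[1], muscle = g$muscle[1],
               section = g$section[1], metric = g$metric[1], mode = mode,
               max_change = mc$change, followup_day = mc$followup_day)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
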