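# Group classification from questionnaire records, demographic and outcome
# comparisons, and the epoch-variability follow-up analysis.

#' Classify a participant by exercise volume
#'
#' Participants whose reported modalities are all strength/flexibility types
#' are excluded (the cohort is biased towards aerobic activity); otherwise
#' MOVE requires at least 150 minutes per week of moderate-to-vigorous
#' exercise sustained for at least 13 consecutive weeks (~ the last three
#' months), per the physical-activity guideline threshold; everyone else is
#' notMOVE.
#'
#' @param minutes_per_week reported exercise minutes per week.
#' @param consecutive_weeks weeks the habit has been sustained.
#' @param modalities character vector (or single `";"`-separated string) of
#'   exercise modalities; may be empty.
#' @param excluded_modalities modalities counting as strength/flexibility.
#' @return `"MOVE"`, `"notMOVE"` or `"excluded"`.
#' @export
classify_group <- function(minutes_per_week, consecutive_weeks,
                           modalities = character(),
                           excluded_modalities = c("weightlifting", "yoga",
                                                   "scuba diving")) {
  if (is.na(minutes_per_week) || is.na(consecutive_weeks))
    stop("minutes_per_week and consecutive_weeks are required", call. = FALSE)
  if (length(modalities) == 1L && grepl(";", modalities))
    modalities <- strsplit(modalities, ";")[[1L]]
  modalities <- trimws(modalities[nzchar(trimws(modalities))])
  if (length(modalities) > 0L && all(modalities %in% excluded_modalities))
    return("excluded")
  if (minutes_per_week >= 150 && consecutive_weeks >= 13) "MOVE" else "notMOVE"
}

#' Classify a whole roster
#'
#' @param records data.frame with `minutes_per_week`, `consecutive_weeks`,
#'   `modalities` columns (as written by [generate_participants()]).
#' @inheritParams classify_group
#' @return The data.frame with a `group` column appended.
#' @export
classify_roster <- function(records,
                            excluded_modalities = c("weightlifting", "yoga",
                                                    "scuba diving")) {
  records$group <- vapply(seq_len(nrow(records)), function(i) {
    classify_group(records$minutes_per_week[i], records$consecutive_weeks[i],
                   records$modalities[i], excluded_modalities)
  }, character(1))
  records
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. If both samples have zero variance and equal
#' means the comparison is vacuous: t = 0, p = 1, flagged.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list: `t`, `df`, `p`, `mean_x`, `mean_y`, `flag`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, mean_x = mean(x),
                  mean_y = mean(y), flag = "zero variance in both samples"))
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_x = mean(x), mean_y = mean(y), flag = NA_character_)
}

#' Pearson chi-squared test with Yates' continuity correction (2 x 2)
#'
#' `X^2 = sum (|O - E| - 0.5)^2 / E`, the correction clamped so each
#' `|O - E| - 0.5` is non-negative; p from the chi-squared distribution with
#' 1 degree of freedom.
#'
#' @param tab 2 x 2 matrix of counts.
#' @return list: `statistic`, `df`, `p`.
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("tab must be a 2 x 2 table", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total", call. = FALSE)
  E <- outer(rs, cs) / sum(tab)
  stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Within-participant variability by adaptation epoch
#'
#' Per participant, the standard deviation of the outcome over the initial,
#' middle (centred) and final `epoch_len` strides, with Student's pooled-
#' variance two-sample t-tests comparing groups within each epoch.
#'
#' @param data long data.frame: `id`, `group`, `index`, `value`.
#' @param epoch_len strides per epoch (default 100).
#' @param groups the two group labels to compare.
#' @return list: `by_participant` (id, group, epoch, sd) and `tests`
#'   (epoch, t, df, p).
#' @export
epoch_variability <- function(data, epoch_len = 100L,
                              groups = c("MOVE", "notMOVE")) {
  per <- lapply(split(data, data$id), function(d) {
    d <- d[order(d$index), ]
    n <- nrow(d)
    if (n < 3L * epoch_len) {
      warning(sprintf("participant %s has %d < %d observations; excluded",
                      d$id[1L], n, 3L * epoch_len), call. = FALSE)
      return(NULL)
    }
    mid0 <- floor((n - epoch_len) / 2)
    data.frame(id = d$id[1L], group = d$group[1L],
               epoch = c("initial", "middle", "final"),
               sd = c(stats::sd(d$value[1:epoch_len]),
                      stats::sd(d$value[(mid0 + 1L):(mid0 + epoch_len)]),
                      stats::sd(d$value[(n - epoch_len + 1L):n])),
               stringsAsFactors = FALSE)
  })
  by_participant <- do.call(rbind, per)
  rownames(by_participant) <- NULL
  tests <- do.call(rbind, lapply(c("initial", "middle", "final"),
                                 function(ep) {
    d <- by_participant[by_participant$epoch == ep, ]
    x <- d$sd[d$group == groups[1L]]
    y <- d$sd[d$group == groups[2L]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(epoch = ep, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(by_participant = by_participant, tests = tests)
}
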