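# Cohort-level evaluation statistics for thickness measures:
# scan-rescan reproducibility error, covariate correction fitted on healthy
# controls, Cohen's d group differences, longitudinal and cross-sectional
# atrophy rates, and method agreement (Pearson r + Bland-Altman).

#' Derive diagnostic group from CDR
#'
#' CDR 0 maps to `HC` (healthy control), 0.5 to `questionable`, >= 1 to
#' `dementia`.
#'
#' @param cdr numeric vector of Clinical Dementia Rating scores.
#' @return character vector of group labels.
#' @export
cdr_group <- function(cdr) {
  ifelse(cdr == 0, "HC", ifelse(cdr < 1, "questionable", "dementia"))
}

#' Scan-rescan reproducibility error
#'
#' For sessions with repeated measures of the same quantity, the mean
#' absolute deviation from the within-session mean, relative to that mean,
#' in percent:
#' \deqn{\epsilon_\mu = \frac{100}{N} \sum_{i=1}^{N} \frac{1}{n(i)}
#'   \sum_{t=1}^{n(i)} \frac{|m_{i,t} - \mu_i|}{\mu_i}}
#' where \eqn{\mu_i} is the within-session mean. Sessions with fewer than two
#' measures are excluded with a warning; a session mean of zero is an error.
#' The statistic is scale-invariant and zero iff all within-session measures
#' are equal.
#'
#' @param values numeric vector of measurements.
#' @param session session identifier per measurement (same length).
#' @return the error, in percent.
#' @export
reproducibility_error <- function(values, session) {
  stopifnot(length(values) == length(session))
  counts <- table(session)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("excluding %d session(s) with fewer than 2 measures",
                    length(small)))
    keep <- !(session %in% small)
    values <- values[keep]; session <- session[keep]
  }
  if (!length(values)) stop("no session with at least 2 measures")
  mu <- tapply(values, session, mean)
  if (any(mu == 0)) stop("within-session mean of zero")
  per_session <- tapply(seq_along(values), session, function(ix) {
    m <- mean(values[ix])
    mean(abs(values[ix] - m) / m)
  })
  100 * mean(per_session)
}

#' Fit the covariate-correction model on healthy controls
#'
#' Ordinary least squares of thickness on standardized covariates (zero
#' mean, unit SD, standardization computed on the HC rows and stored with
#' the model). By default the covariates are `etiv` and `age`; `sex` and
#' `scanner` can be added as categorical dummy-coded covariates.
#'
#' @param data data frame with columns `thickness`, `etiv`, `age`, a group
#'   column (`group`, values as from [cdr_group()]), and optionally `sex`
#'   and `scanner`.
#' @param include_sex,include_scanner add the categorical covariates
#'   (default `FALSE`: both are typically unrelated to thickness once eTIV
#'   and age are in the model).
#' @return object of class `covariate_model`: the `lm` fit, the
#'   standardization parameters, and the age coefficient back-transformed to
#'   mm per year (`age_slope_mm_per_year`).
#' @export
fit_covariate_model <- function(data, include_sex = FALSE,
                                include_scanner = FALSE) {
  stopifnot(all(c("thickness", "etiv", "age", "group") %in% names(data)))
  hc <- data[data$group == "HC" & stats::complete.cases(data[, c("thickness", "etiv", "age")]), ]
  if (nrow(hc) < 3L) stop("need at least 3 HC scans with complete covariates")
  center <- c(etiv = mean(hc$etiv), age = mean(hc$age))
  scale <- c(etiv = stats::sd(hc$etiv), age = stats::sd(hc$age))
  if (any(scale == 0)) stop("rank-deficient design: constant covariate")
  df <- data.frame(thickness = hc$thickness,
                   etiv = (hc$etiv - center["etiv"]) / scale["etiv"],
                   age = (hc$age - center["age"]) / scale["age"])
  form <- thickness ~ etiv + age
  if (include_sex) { df$sex <- factor(hc$sex); form <- stats::update(form, . ~ . + sex) }
  if (include_scanner) { df$scanner <- factor(hc$scanner); form <- stats::update(form, . ~ . + scanner) }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: aliased coefficients")
  structure(list(fit = fit, center = center, scale = scale,
                 include_sex = include_sex, include_scanner = include_scanner,
                 age_slope_mm_per_year = unname(stats::coef(fit)["age"] / scale["age"])),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("<covariate_model> thickness ~ standardized eTIV + age",
      if (x$include_sex) "+ sex", if (x$include_scanner) "+ scanner", "\n")
  print(stats::coef(x$fit))
  cat(sprintf("age slope: %.5f mm/year\n", x$age_slope_mm_per_year))
  invisible(x)
}

#' Apply the covariate correction to all scans
#'
#' Subtracts the fitted covariate contributions using the standardization
#' stored in the model; the intercept is retained, so corrected values stay
#' on the mm scale (on the HC rows the corrected mean equals the observed
#' mean). Rows with missing covariates are dropped with a warning.
#'
#' @param model a [fit_covariate_model()] result.
#' @param data data frame with `thickness`, `etiv`, `age` (plus `sex` /
#'   `scanner` if the model includes them).
#' @return `data` with a `thickness_corrected` column.
#' @export
apply_correction <- function(model, data) {
  stopifnot(inherits(model, "covariate_model"))
  need <- c("thickness", "etiv", "age")
  ok <- stats::complete.cases(data[, need])
  if (any(!ok)) {
    warning(sprintf("dropping %d scan(s) with missing covariates", sum(!ok)))
    data <- data[ok, ]
  }
  b <- stats::coef(model$fit)
  z_etiv <- (data$etiv - model$center["etiv"]) / model$scale["etiv"]
  z_age <- (data$age - model$center["age"]) / model$scale["age"]
  corr <- data$thickness - b["etiv"] * z_etiv - b["age"] * z_age
  if (model$include_sex) {
    mm <- stats::model.matrix(~sex, data.frame(sex = factor(data$sex, levels = levels(model$fit$model$sex))))
    sx <- grep("^sex", names(b), value = TRUE)
    corr <- corr - as.vector(mm[, sx, drop = FALSE] %*% b[sx])
  }
  if (model$include_scanner) {
    mm <- stats::model.matrix(~scanner, data.frame(scanner = factor(data$scanner, levels = levels(model$fit$model$scanner))))
    sc <- grep("^scanner", names(b), value = TRUE)
    corr <- corr - as.vector(mm[, sc, drop = FALSE] %*% b[sc])
  }
  data$thickness_corrected <- as.numeric(corr)
  data
}

#' Cohen's d with a large-sample confidence interval
#'
#' \eqn{d = (\bar a - \bar b) / s_{pooled}} with the pooled SD
#' \eqn{s_{pooled} = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}. The
#' confidence interval uses the large-sample normal approximation
#' \eqn{d \pm z \sqrt{(n_a+n_b)/(n_a n_b) + d^2 / (2(n_a+n_b-2))}}.
#'
#' @param a,b numeric vectors (both of length >= 2).
#' @param conf confidence level (default 0.95).
#' @return list with `d`, `ci` (length 2), `n_a`, `n_b`.
#' @export
cohens_d <- function(a, b, conf = 0.95) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 observations")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  d <- (mean(a) - mean(b)) / sp
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
  list(d = d, ci = c(d - z * se, d + z * se), n_a = na, n_b = nb)
}

#' Longitudinal atrophy rates per subject and group summaries
#'
#' A subject is included iff the time span between their first and last scan
#' is at least `min_span_years` and their group label is constant across
#' scans. The per-subject rate is the OLS slope of the measure against time
#' in years over all of the subject's scans (`method = "first_last"` uses
#' the endpoint difference instead; identical for two-timepoint subjects).
#'
#' @param data data frame with columns `subject`, `time_years` (or `age`,
#'   used as time axis when `time_years` is absent), `value`, `group`.
#' @param min_span_years inclusion threshold on the time span.
#' @param method `"slope"` (default) or `"first_last"`.
#' @return list with `rates` (per included subject), `summary` (per-group
#'   mean, SD, n) and `excluded` (subjects failing inclusion, with reason).
#' @export
longitudinal_atrophy_rates <- function(data, min_span_years = 1,
                                       method = c("slope", "first_last")) {
  method <- match.arg(method)
  if (!"time_years" %in% names(data)) {
    stopifnot("age" %in% names(data))
    data$time_years <- data$age
  }
  stopifnot(all(c("subject", "value", "group") %in% names(data)))
  rates <- list(); excluded <- list()
  for (s in unique(data$subject)) {
    di <- data[data$subject == s, ]
    span <- max(di$time_years) - min(di$time_years)
    if (nrow(di) < 2L || span < min_span_years) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject = s, reason = "span < 1 year or single scan")
      next
    }
    if (length(unique(di$group)) > 1L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject = s, reason = "changed sub-cohort")
      next
    }
    rate <- if (method == "slope") {
      unname(stats::coef(stats::lm(value ~ time_years, data = di))[2])
    } else {
      o <- order(di$time_years)
      (di$value[o[nrow(di)]] - di$value[o[1]]) / span
    }
    rates[[length(rates) + 1L]] <-
      data.frame(subject = s, group = di$group[1], rate_mm_per_year = rate,
                 n_scans = nrow(di), span_years = span)
  }
  rates <- if (length(rates)) do.call(rbind, rates) else
    data.frame(subject = character(), group = character(),
               rate_mm_per_year = numeric(), n_scans = integer(),
               span_years = numeric())
  summary <- if (nrow(rates)) {
    agg <- split(rates$rate_mm_per_year, rates$group)
    do.call(rbind, lapply(names(agg), function(g)
      data.frame(group = g, n = length(agg[[g]]),
                 mean_rate = mean(agg[[g]]), sd_rate = stats::sd(agg[[g]]))))
  } else data.frame(group = character(), n = integer(),
                    mean_rate = numeric(), sd_rate = numeric())
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject = character(), reason = character())
  list(rates = rates, summary = summary, excluded = excluded)
}

#' Paired comparison of per-subject rates between two methods
#'
#' Two-sided paired t-test on the per-subject rate differences. When the
#' differences have zero variance the test statistic is undefined; an
#' all-zero difference vector is reported as "no difference" (p = 1).
#'
#' @param rates_a,rates_b data frames with columns `subject` and
#'   `rate_mm_per_year` (e.g. the `rates` element of
#'   [longitudinal_atrophy_rates()]), matched by subject.
#' @return list with `mean_difference`, `p_value`, `n`.
#' @export
compare_rates_paired <- function(rates_a, rates_b) {
  m <- merge(rates_a[, c("subject", "rate_mm_per_year")],
             rates_b[, c("subject", "rate_mm_per_year")],
             by = "subject", suffixes = c("_a", "_b"))
  if (nrow(m) < 2L) stop("need at least 2 paired subjects")
  diffs <- m$rate_mm_per_year_a - m$rate_mm_per_year_b
  if (stats::sd(diffs) == 0) {
    p <- if (mean(diffs) == 0) 1 else 0
    if (mean(diffs) != 0)
      warning("constant nonzero difference: t statistic undefined, reporting p = 0")
    return(list(mean_difference = mean(diffs), p_value = p, n = nrow(m)))
  }
  tt <- stats::t.test(m$rate_mm_per_year_a, m$rate_mm_per_year_b, paired = TRUE)
  list(mean_difference = unname(tt$estimate), p_value = tt$p.value, n = nrow(m))
}

#' Cross-sectional age slope
#'
#' OLS slope of a thickness measure against age, mm per year.
#'
#' @param data data frame with columns `value` and `age` (healthy controls).
#' @return slope in mm/year.
#' @export
cross_sectional_age_slope <- function(data) {
  stopifnot(all(c("value", "age") %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 scans")
  unname(stats::coef(stats::lm(value ~ age, data = data))[2])
}

#' Agreement between two methods: Pearson r and Bland-Altman summary
#'
#' For each measure (region), across matched scans: Pearson correlation,
#' Bland-Altman bias (mean of a - b) and limits of agreement
#' (bias +/- 1.96 SD of a - b).
#'
#' @param table_a,table_b data frames with columns `scan`, `region`,
#'   `value`; rows are matched on (`scan`, `region`).
#' @return data frame with one row per region: `region`, `n`, `r`, `bias`,
#'   `lower_limit`, `upper_limit`.
#' @export
method_agreement <- function(table_a, table_b) {
  m <- merge(table_a, table_b, by = c("scan", "region"),
             suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no matched scans")
  out <- lapply(split(m, m$region), function(r) {
    if (nrow(r) < 3L) stop("fewer than 3 matched scans for region ", r$region[1])
    diffs <- r$value_a - r$value_b
    sd_d <- stats::sd(diffs)
    rr <- if (stats::sd(r$value_a) == 0 || stats::sd(r$value_b) == 0) NA_real_
          else stats::cor(r$value_a, r$value_b)
    data.frame(region = r$region[1], n = nrow(r), r = rr,
               bias = mean(diffs),
               lower_limit = mean(diffs) - 1.96 * sd_d,
               upper_limit = mean(diffs) + 1.96 * sd_d)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
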