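#' Upper-tertile dichotomization of marker positivity
#'
#' Labels patients whose stain positivity lies strictly above the 2/3
#' quantile (linear-interpolation quantile, R type 7) as `"upper"`, the
#' rest `"lower"`. Labels depend only on the order statistics, so any
#' monotone transform of the input yields the same split.
#'
#' @param stain_pct Numeric vector of percent positive cells (n >= 3).
#' @return Character vector of `"upper"` / `"lower"` labels.
#' @examples
#' tertile_split(1:9)  # 7, 8, 9 are "upper"
#' @export
tertile_split <- function(stain_pct) {
  .check(is.numeric(stain_pct) && length(stain_pct) >= 3,
         "need at least 3 values")
  cut_at <- stats::quantile(stain_pct, 2 / 3, type = 7, names = FALSE)
  labels <- ifelse(stain_pct > cut_at, "upper", "lower")
  if (all(labels == "lower")) {
    warning("no value above the 2/3 quantile; all patients labeled 'lower'")
  }
  labels
}

#' Kaplan-Meier curves and log-rank test between marker groups
#'
#' Product-limit survival estimates per group with a two-sided log-rank
#' test. With a single group, curves are returned and the p-value is `NA`.
#'
#' @param cohort Data frame with time/event columns (see `endpoint`).
#' @param group Grouping vector (e.g. from [tertile_split()]).
#' @param endpoint `"pfi"` or `"os"`; selects `<endpoint>_time` and
#'   `<endpoint>_event` columns.
#' @return List of class `km_result`: `fit` (a `survfit`), `p` (log-rank),
#'   `curves` (data frame of time, survival, group).
#' @export
km_logrank <- function(cohort, group, endpoint = c("pfi", "os")) {
  endpoint <- match.arg(endpoint)
  time <- cohort[[paste0(endpoint, "_time")]]
  event <- cohort[[paste0(endpoint, "_event")]]
  .check(!is.null(time) && !is.null(event),
         sprintf("cohort lacks %s_time/%s_event columns", endpoint, endpoint))
  .check(sum(event) >= 1, "need at least one event")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  p <- if (nlevels(group) < 2) {
    NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  }
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, survival = fit$surv,
                       stringsAsFactors = FALSE)
  structure(list(fit = fit, p = p, curves = curves, endpoint = endpoint),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier (%s): log-rank p = %s\n", toupper(x$endpoint),
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Cox proportional-hazards fit for marker prognosis
#'
#' Fits a partial-likelihood proportional-hazards model of the selected
#' endpoint on the upper-tertile indicator (univariable) or on the
#' indicator plus extent-of-resection and radiotherapy covariates
#' (multivariable). Ties are handled by the Efron approximation.
#' Non-convergence or an infinite coefficient (complete separation) is
#' reported as an error rather than silently returned.
#'
#' @param cohort Data frame with endpoint columns and, for the
#'   multivariable model, `eor` and `rt` covariates.
#' @param group Grouping vector (`"upper"` / `"lower"`).
#' @param endpoint `"pfi"` or `"os"`.
#' @param covariates Character vector of additional covariate columns
#'   (default none = univariable).
#' @return List of class `cox_result`: `hr`, `ci_low`, `ci_high`, `p`
#'   (Wald) for the upper-tertile term, plus `terms` (full coefficient
#'   table) and the underlying `fit`.
#' @export
cox_fit <- function(cohort, group, endpoint = c("pfi", "os"),
                    covariates = character(0)) {
  endpoint <- match.arg(endpoint)
  time <- cohort[[paste0(endpoint, "_time")]]
  event <- cohort[[paste0(endpoint, "_event")]]
  .check(!is.null(time) && !is.null(event),
         sprintf("cohort lacks %s_time/%s_event columns", endpoint, endpoint))
  .check(all(covariates %in% names(cohort)),
         "missing covariate columns in cohort")
  dat <- data.frame(time = time, event = event,
                    upper = as.integer(group == "upper"))
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~ upper",
                                 if (length(covariates)) {
                                   paste("+", paste(covariates, collapse = " + "))
                                 } else ""))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox model did not converge", call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(!is.finite(co[, "coef"])) || any(!is.finite(co[, "se(coef)"])) ||
      any(abs(co[, "coef"]) > 15)) {
    stop("Cox fit is degenerate (possible complete separation)",
         call. = FALSE)
  }
  ci <- sm$conf.int
  structure(list(hr = unname(ci["upper", "exp(coef)"]),
                 ci_low = unname(ci["upper", "lower .95"]),
                 ci_high = unname(ci["upper", "upper .95"]),
                 p = unname(co["upper", "Pr(>|z|)"]),
                 terms = data.frame(term = rownames(co),
                                    hr = unname(ci[, "exp(coef)"]),
                                    ci_low = unname(ci[, "lower .95"]),
                                    ci_high = unname(ci[, "upper .95"]),
                                    p = unname(co[, "Pr(>|z|)"]),
                                    stringsAsFactors = FALSE),
                 endpoint = endpoint, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (%s): upper-tertile HR = %.2f (95%% CI %.2f-%.2f), p = %s\n",
              toupper(x$endpoint), x$hr, x$ci_low, x$ci_high,
              format.pval(x$p, digits = 3)))
  if (nrow(x$terms) > 1) {
    cat(sprintf("  adjusted for: %s\n",
                paste(setdiff(x$terms$term, "upper"), collapse = ", ")))
  }
  invisible(x)
}

#' Compare marker positivity between anatomical sites
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of stain positivity
#' between the two site groups.
#'
#' @param stain_pct Numeric vector of percent positive cells.
#' @param site Two-level grouping vector (e.g. skull base vs spine).
#' @return List: `statistic` (W), `p`.
#' @export
site_compare <- function(stain_pct, site) {
  site <- factor(site)
  .check(nlevels(site) == 2, "exactly two site groups required")
  .check(all(table(site) > 0), "both site groups must be non-empty")
  wt <- stats::wilcox.test(stain_pct ~ site, exact = NULL)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Full prognostic evaluation of a cohort
#'
#' Tertile split, Kaplan-Meier + log-rank per endpoint, univariable and
#' multivariable Cox fits, and the site comparison.
#'
#' @param cohort Cohort data frame (see [generate_survival_cohort()] for
#'   the schema).
#' @param marker_col Column holding marker positivity (default
#'   `"stain_pct"`).
#' @param covariates Multivariable covariates present in the cohort.
#' @return List of class `prognosis_report` with `group`, `km`, `cox_uni`,
#'   `cox_multi` (per endpoint) and `site_test` (NULL when a site column is
#'   absent or one-level).
#' @export
run_prognosis <- function(cohort, marker_col = "stain_pct",
                          covariates = c("eor", "rt")) {
  .check(marker_col %in% names(cohort), "marker column not found")
  group <- tertile_split(cohort[[marker_col]])
  endpoints <- intersect(c("pfi", "os"),
                         c(if ("pfi_time" %in% names(cohort)) "pfi",
                           if ("os_time" %in% names(cohort)) "os"))
  .check(length(endpoints) > 0, "cohort has no recognized endpoint columns")
  covariates <- intersect(covariates, names(cohort))
  km <- lapply(endpoints, function(e) km_logrank(cohort, group, e))
  uni <- lapply(endpoints, function(e) cox_fit(cohort, group, e))
  multi <- lapply(endpoints, function(e) {
    cox_fit(cohort, group, e, covariates = covariates)
  })
  names(km) <- names(uni) <- names(multi) <- endpoints
  site_test <- if ("site" %in% names(cohort) &&
                   length(unique(cohort$site)) == 2) {
    site_compare(cohort[[marker_col]], cohort$site)
  } else {
    NULL
  }
  structure(list(group = group, km = km, cox_uni = uni, cox_multi = multi,
                 site_test = site_test), class = "prognosis_report")
}

#' @export
print.prognosis_report <- function(x, ...) {
  cat(sprintf("Prognostic evaluation (%d patients; %d upper tertile)\n",
              length(x$group), sum(x$group == "upper")))
  for (e in names(x$cox_uni)) {
    cat(sprintf("  %s: log-rank p = %s | univariable HR %.2f (%.2f-%.2f) | multivariable HR %.2f (%.2f-%.2f)\n",
                toupper(e), format.pval(x$km[[e]]$p, digits = 3),
                x$cox_uni[[e]]$hr, x$cox_uni[[e]]$ci_low,
                x$cox_uni[[e]]$ci_high, x$cox_multi[[e]]$hr,
                x$cox_multi[[e]]$ci_low, x$cox_multi[[e]]$ci_high))
  }
  if (!is.null(x$site_test)) {
    cat(sprintf("  site comparison: W = %g, p = %s\n",
                x$site_test$statistic,
                format.pval(x$site_test$p, digits = 3)))
  }
  invisible(x)
}
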