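#' Kaplan-Meier curves and log-rank comparison between two groups
#'
#' Product-limit survival estimates per group with right censoring, and the
#' log-rank test of the group difference (observed vs expected events).
#'
#' @param records Clinical tibble with `patient_id`, `time_months`, `event`
#'   (1 = death).
#' @param groups Tibble `patient_id`, `group` (two groups, each non-empty).
#' @return A list of class `"survival_comparison"`: `km` (tidy step table:
#'   `group`, `time`, `n_risk`, `n_event`, `survival`), `statistic` (log-rank
#'   chi-square), `p_value`, `group_sizes`.
#' @export
survival_compare <- function(records, groups) {
  d <- inner_join(records, groups, by = "patient_id")
  if (length(unique(d$group)) != 2) abort("need exactly two groups")
  if (any(table(d$group) < 1)) abort("a group has zero subjects")
  if (sum(d$event) < 1) abort("need at least one event")
  if (any(d$time_months <= 0)) abort("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ group,
                           data = d)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  km <- tibble(group = sub("^group=", "", strata), time = fit$time,
               n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
  lr <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                           data = d)
  structure(list(km = km, statistic = unname(lr$chisq),
                 p_value = stats::pchisq(lr$chisq, df = 1,
                                         lower.tail = FALSE),
                 group_sizes = table(d$group)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("<survival_comparison> groups:",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("log-rank chi-square = %.4g, p = %.4g\n", x$statistic,
              x$p_value))
  invisible(x)
}

#' @method tidy survival_comparison
#' @export
tidy.survival_comparison <- function(x, ...) x$km

#' @method glance survival_comparison
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n = sum(x$group_sizes))
}

#' Univariable screening plus multivariable Cox proportional-hazards model
#'
#' Fits one univariable Cox model per candidate variable, then enters every
#' variable with univariable `p < screen_p` (default 0.2) into a single
#' multivariable fit by partial-likelihood maximization (Efron tie handling).
#' Hazard ratios are reported with 95% confidence intervals. Suspected
#' complete separation (|log HR| > 15) is flagged.
#'
#' @param records Clinical tibble with `time_months`, `event` and the
#'   candidate variable columns.
#' @param variables Character vector of column names to screen.
#' @param screen_p Univariable screening threshold, default 0.2.
#' @return A list of class `"cox_screen"`: `univariable` (tibble `variable`,
#'   `term`, `hr`, `ci_low`, `ci_high`, `p_value`, `selected`),
#'   `multivariable` (same layout for the joint fit), `selected`, `fit`.
#' @export
cox_model <- function(records, variables, screen_p = 0.2) {
  stopifnot(all(variables %in% names(records)))
  term_table <- function(fit, variable) {
    s <- summary(fit)
    tibble(variable = variable, term = rownames(s$coefficients),
           hr = unname(s$coefficients[, "exp(coef)"]),
           ci_low = unname(s$conf.int[, "lower .95"]),
           ci_high = unname(s$conf.int[, "upper .95"]),
           p_value = unname(s$coefficients[, "Pr(>|z|)"]))
  }
  uni <- purrr::map_dfr(variables, function(v) {
    f <- stats::as.formula(paste("survival::Surv(time_months, event) ~", v))
    fit <- tryCatch(survival::coxph(f, data = records),
                    error = function(e) abort(paste0(
                      "univariable Cox fit failed for ", v, ": ",
                      conditionMessage(e))))
    term_table(fit, v)
  })
  if (any(abs(log(uni$hr)) > 15))
    warn("possible complete separation in a univariable fit")
  sel_tbl <- uni |>
    group_by(.data$variable) |>
    summarise(min_p = min(.data$p_value), .groups = "drop")
  selected <- sel_tbl$variable[sel_tbl$min_p < screen_p]
  uni$selected <- uni$variable %in% selected
  multi <- NULL
  fit <- NULL
  if (length(selected)) {
    if (sum(records$event) < length(selected))
      abort("fewer events than multivariable terms")
    f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(selected, collapse = " + ")))
    fit <- survival::coxph(f, data = records)
    if (!is.null(fit$info) || any(!is.finite(stats::coef(fit))))
      abort("multivariable Cox fit did not converge")
    multi <- term_table(fit, term_var(selected, fit))
  }
  structure(list(univariable = uni, multivariable = multi,
                 selected = selected, fit = fit, screen_p = screen_p),
            class = "cox_screen")
}

# map multivariable coefficient rows back to their source variable
term_var <- function(variables, fit) {
  terms <- rownames(summary(fit)$coefficients)
  hits <- vapply(terms, function(tm) {
    m <- variables[startsWith(tm, variables)]
    m[which.max(nchar(m))]
  }, character(1))
  unname(hits)
}

#' @export
print.cox_screen <- function(x, ...) {
  cat("<cox_screen> screened", nrow(x$univariable), "terms; selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      sprintf("(p < %.2g)\n", x$screen_p))
  if (!is.null(x$multivariable)) {
    print(as.data.frame(x$multivariable), digits = 3)
  }
  invisible(x)
}

#' @method tidy cox_screen
#' @export
tidy.cox_screen <- function(x, ...) {
  bind_rows(mutate(x$univariable, model = "univariable"),
            if (!is.null(x$multivariable))
              mutate(x$multivariable, model = "multivariable",
                     selected = TRUE))
}

#' @method glance cox_screen
#' @export
glance.cox_screen <- function(x, ...) {
  tibble(n_screened = length(unique(x$univariable$variable)),
         n_selected = length(x$selected),
         concordance = if (!is.null(x$fit))
           unname(summary(x$fit)$concordance[1]) else NA_real_)
}

#' Fisher exact test of signature label vs immunotherapy response
#'
#' Dichotomizes mRECIST categories into responders (CR/PR by default;
#' `include_sd` adds SD) and tests the 2x2 label-by-response table with the
#' two-tailed Fisher exact test (probability-mass rule). An empty margin
#' returns `p = 1` with an undefined odds ratio and a `degenerate` flag.
#'
#' @param labels Tibble `sample_id` (or `patient_id`), `label`
#'   (`"good_TiME"`/`"bad_TiME"`).
#' @param records Clinical tibble with `patient_id` and `response` (mRECIST
#'   `CR`/`PR`/`SD`/`PD`).
#' @param include_sd Count stable disease as response, default `FALSE`.
#' @return A list of class `"fisher_response"`: `table` (2x2), `odds_ratio`
#'   (conditional MLE), `p_value`, `degenerate`.
#' @export
fisher_response <- function(labels, records, include_sd = FALSE) {
  if ("sample_id" %in% names(labels))
    labels <- rename(labels, patient_id = "sample_id")
  d <- inner_join(labels, records, by = "patient_id")
  resp_cats <- c("CR", "PR", if (include_sd) "SD")
  tab <- table(factor(d$label, levels = c("good_TiME", "bad_TiME")),
               factor(ifelse(d$response %in% resp_cats, "responder",
                             "non_responder"),
                      levels = c("responder", "non_responder")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warn("empty margin in the response table; p = 1, odds ratio undefined")
    return(structure(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                          degenerate = TRUE), class = "fisher_response"))
  }
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, degenerate = FALSE),
            class = "fisher_response")
}

#' @export
print.fisher_response <- function(x, ...) {
  cat("<fisher_response>\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, two-tailed p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}
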