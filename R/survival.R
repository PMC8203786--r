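ENDPOINTS <- c("cv_death", "scd", "hf_death_tx", "stroke_death", "proc_death")

#' Filter cases for survival analysis
#'
#' Excludes cases with more than one pathogenic/likely pathogenic variant
#' ("complex phenotype") and cases without a last follow-up age (they cannot
#' enter a time-to-event analysis, though they remain usable for phenotype
#' tables). Each exclusion carries its reason.
#'
#' @param cases Case tibble (see [read_cases()]).
#' @return A list with tibbles `kept` and `excluded` (the latter with a
#'   `reason` column).
#' @export
filter_cases <- function(cases) {
  reason <- rep(NA_character_, nrow(cases))
  reason[is.na(cases$last_followup_age)] <- "no follow-up age"
  reason[cases$n_path_variants > 1] <- "complex phenotype"
  list(kept = cases[is.na(reason), , drop = FALSE],
       excluded = dplyr::mutate(cases[!is.na(reason), , drop = FALSE],
                                reason = reason[!is.na(reason)]))
}

surv_input <- function(cases, endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  if (nrow(cases) == 0) stop("no cases supplied")
  if (anyNA(cases$last_followup_age)) {
    stop("cases with missing last_followup_age; run filter_cases() first")
  }
  data.frame(time = cases$last_followup_age,
             status = as.integer(cases[[endpoint]] == 1))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of freedom from an endpoint, with age (from
#' birth) as the time scale: a case is an event at its last follow-up age
#' when the endpoint flag is set, and right-censored there otherwise. For a
#' cause-specific endpoint, deaths from other causes are censored at the
#' death age (their follow-up ends then). At tied times events precede
#' censorings, the standard product-limit convention.
#'
#' @param cases Case tibble with `last_followup_age` and event flag columns.
#' @param endpoint One of `"cv_death"`, `"scd"`, `"hf_death_tx"`,
#'   `"stroke_death"`, `"proc_death"`.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, and attributes `endpoint`, `n`,
#'   `n_events`, `n_censored`.
#' @export
kaplan_meier <- function(cases, endpoint = "cv_death") {
  d <- surv_input(cases, endpoint)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  attr(out, "endpoint") <- endpoint
  attr(out, "n") <- nrow(d)
  attr(out, "n_events") <- sum(d$status)
  attr(out, "n_censored") <- sum(1 - d$status)
  class(out) <- c("km_curve", class(out))
  out
}

#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(endpoint = attr(x, "endpoint"), n = attr(x, "n"),
                 events = attr(x, "n_events"), censored = attr(x, "n_censored"))
}

new_logrank_result <- function(fit, labels, endpoint) {
  obs <- if (is.matrix(fit$obs)) rowSums(fit$obs) else fit$obs
  exp <- if (is.matrix(fit$exp)) rowSums(fit$exp) else fit$exp
  df <- length(obs) - 1L
  structure(list(
    statistic = unname(fit$chisq), df = df,
    p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
    groups = tibble::tibble(group = labels, n = as.integer(fit$n),
                            observed = unname(obs), expected = unname(exp)),
    endpoint = endpoint
  ), class = "logrank_result")
}

#' Log-rank (Mantel-Cox) comparison of survival across groups
#'
#' Standard k-group log-rank test: at each distinct event time the at-risk
#' and event counts are pooled, expected events per group follow the
#' hypergeometric mean, and the statistic is referred to a chi-square
#' distribution with k - 1 degrees of freedom. Empty groups are dropped with
#' a warning.
#'
#' @param cases Case tibble.
#' @param group Grouping: either a column name in `cases` or a vector of
#'   group labels of the same length.
#' @param endpoint Endpoint, as in [kaplan_meier()].
#' @return An object of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, and a per-group tibble with observed and expected events.
#'   [tidy()] returns the per-group table; [glance()] a one-row summary.
#' @export
logrank <- function(cases, group, endpoint = "cv_death") {
  g <- if (length(group) == 1 && is.character(group) && group %in% names(cases)) {
    cases[[group]]
  } else {
    group
  }
  stopifnot(length(g) == nrow(cases))
  keep <- !is.na(g)
  if (!all(keep)) {
    warning(sum(!keep), " case(s) with missing group dropped")
    cases <- cases[keep, , drop = FALSE]
    g <- g[keep]
  }
  g <- factor(g)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least two non-empty groups")
  d <- surv_input(cases, endpoint)
  d$grp <- g
  fit <- survival::survdiff(survival::Surv(time, status) ~ grp, data = d)
  new_logrank_result(fit, levels(g), endpoint)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank (Mantel-Cox) test, endpoint:", x$endpoint, "\n")
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.logrank_result <- function(x, ...) x$groups

#' @export
glance.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 endpoint = x$endpoint, n_groups = nrow(x$groups))
}

#' Pairwise log-rank comparisons
#'
#' All unordered pairs of groups, each compared by [logrank()]. By default
#' the pairwise p values are uncorrected (mirroring how region-wise
#' prognosis contrasts are usually reported); Bonferroni or Holm adjusted
#' values are added on request.
#'
#' @inheritParams logrank
#' @param correction `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A tibble with `group1`, `group2`, `statistic`, `df`, `p_value`
#'   and `p_adj`.
#' @export
pairwise_logrank <- function(cases, group, endpoint = "cv_death",
                             correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  g <- if (length(group) == 1 && is.character(group) && group %in% names(cases)) {
    cases[[group]]
  } else {
    group
  }
  g <- factor(g)
  levs <- levels(droplevels(g[!is.na(g)]))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sel <- !is.na(g) & g %in% pr
    lr <- logrank(cases[sel, , drop = FALSE], as.character(g[sel]), endpoint)
    tibble::tibble(group1 = pr[1], group2 = pr[2], statistic = lr$statistic,
                   df = lr$df, p_value = lr$p_value)
  })
  out$p_adj <- if (correction == "none") out$p_value
               else stats::p.adjust(out$p_value, method = correction)
  out
}

#' Region-stratified survival analysis
#'
#' Assigns each case's variant position to a structural region (or to a
#' high/low risk stratum), then computes per-group Kaplan-Meier curves, the
#' omnibus log-rank test and all pairwise comparisons. Cases falling in an
#' excluded interval or outside every region are dropped, with counts
#' reported as a message.
#'
#' @param cases Case tibble with a `position` column (from the parsed
#'   variant) and survival columns; run [filter_cases()] first.
#' @param scheme A [region_scheme()] (default [tnt_regions()]).
#' @param endpoint Endpoint, as in [kaplan_meier()].
#' @param strata Optional named character vector mapping region labels to
#'   stratum labels (e.g. [tnt_risk_strata()]); when supplied, the analysis
#'   is run on strata instead of regions.
#' @param correction Correction for the pairwise comparisons (see
#'   [pairwise_logrank()]).
#' @return An object of class `region_survival`: list with `curves` (one
#'   `km_curve` tibble per group, bound with a `group` column), `omnibus`
#'   (a `logrank_result`), `pairwise` (a tibble), `dropped` (counts), and
#'   `endpoint`.
#' @export
survival_by_region <- function(cases, scheme = tnt_regions(),
                               endpoint = "cv_death", strata = NULL,
                               correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  grp <- assign_region(scheme, cases$position)
  dropped <- table(grp[grp %in% c("excluded", "outside")])
  keep <- !(grp %in% c("excluded", "outside"))
  if (length(dropped) > 0 && sum(dropped) > 0) {
    message(sum(dropped), " case(s) dropped (",
            paste(names(dropped), dropped, sep = ": ", collapse = ", "), ")")
  }
  cases <- cases[keep, , drop = FALSE]
  grp <- grp[keep]
  if (!is.null(strata)) grp <- unname(strata[grp])
  if (nrow(cases) == 0) stop("no cases assignable to any region")
  if (length(unique(grp)) < 2) stop("all cases in one group")

  curves <- purrr::map_dfr(sort(unique(grp)), function(g) {
    km <- kaplan_meier(cases[grp == g, , drop = FALSE], endpoint)
    dplyr::mutate(tibble::as_tibble(km), group = g, .before = 1)
  })
  structure(list(
    curves = curves,
    omnibus = logrank(cases, grp, endpoint),
    pairwise = pairwise_logrank(cases, grp, endpoint, correction),
    dropped = dropped, endpoint = endpoint
  ), class = "region_survival")
}

#' @export
print.region_survival <- function(x, ...) {
  cat("Region-stratified survival, endpoint:", x$endpoint, "\n\nOmnibus:\n")
  print(x$omnibus)
  cat("\nPairwise:\n")
  print(x$pairwise)
  invisible(x)
}

#' Write survival curves to TSV
#'
#' @param curves `km_curve` tibble or the `curves` element of a
#'   `region_survival`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  readr::write_tsv(tibble::as_tibble(curves), path)
  invisible(path)
}
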