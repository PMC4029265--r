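# Survival separation between phenotypes: product-limit (Kaplan-Meier)
# estimator, two-group log-rank test, and univariate Cox proportional
# hazards on the binary phenotype, fitted by Newton-Raphson on the partial
# likelihood with Breslow tie handling. Censored observations tied with an
# event time remain at risk at that time; p-values are two-sided.

check_surv_input <- function(times, events) {
  if (length(times) != length(events) || length(times) < 1L) {
    stop_cgp("times and events must have equal length >= 1")
  }
  if (anyNA(times) || anyNA(events)) stop_cgp("missing values in survival input")
  if (any(times < 0)) stop_cgp("negative survival time")
  if (!is_binary01(events)) stop_cgp("events must be 0/1")
  invisible(NULL)
}

as_group01 <- function(groups) {
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop_cgp("exactly two groups required; found %d", length(lev))
  list(x = as.integer(as.character(groups) == lev[2L]), levels = lev)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' At each distinct event time t the estimate multiplies by
#' `1 - d_t / n_t`, with `d_t` deaths at t and `n_t` subjects at risk;
#' censored subjects leave the risk set after their censoring time.
#'
#' @param times non-negative survival times (months).
#' @param events 0/1 event indicators (1 = death observed).
#' @param group_label optional label carried into the output (for plotting
#'   several curves together).
#' @return a `cgp_km` data frame with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `survival`, `group`.
#' @export
km_estimate <- function(times, events, group_label = NA_character_) {
  check_surv_input(times, events)
  evt <- sort(unique(times[events == 1]))
  n_risk <- vapply(evt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(evt, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = evt, n_risk = as.integer(n_risk),
                       n_event = as.integer(n_event), survival = surv,
                       group = rep(group_label, length(evt)),
                       stringsAsFactors = FALSE),
            n = length(times), class = c("cgp_km", "data.frame"))
}

# per-distinct-event-time summaries shared by the log-rank and Cox fits:
# d = total deaths, d1 = deaths in group 1, n = at risk, n1 = at risk group 1
risk_table <- function(times, events, x) {
  evt <- sort(unique(times[events == 1]))
  t(vapply(evt, function(tt) {
    at <- times >= tt
    dd <- times == tt & events == 1
    c(time = tt, d = sum(dd), d1 = sum(dd & x == 1L),
      n = sum(at), n1 = sum(at & x == 1L))
  }, numeric(5)))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed deaths in the second group are
#' compared with their expectation under the hypergeometric model for the
#' risk set; the statistic is `(sum(O - E))^2 / sum(V)`, referred to a
#' chi-square distribution with 1 degree of freedom (two-sided).
#'
#' @param times,events as in [km_estimate()].
#' @param groups two-level vector (factor, character or 0/1) of group
#'   membership; both groups must be non-empty.
#' @return a `cgp_survtest` list: `method = "logrank"`, `chi_square`,
#'   `p_value`, `observed` / `expected` deaths per group, `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- as_group01(groups)
  rt <- risk_table(times, events, g$x)
  if (nrow(rt) == 0L) stop_cgp("no events observed; log-rank test undefined")
  e1 <- rt[, "d"] * rt[, "n1"] / rt[, "n"]
  v <- ifelse(rt[, "n"] > 1,
              rt[, "d"] * (rt[, "n1"] / rt[, "n"]) * (1 - rt[, "n1"] / rt[, "n"]) *
                (rt[, "n"] - rt[, "d"]) / (rt[, "n"] - 1),
              0)
  o_minus_e <- sum(rt[, "d1"] - e1)
  vs <- sum(v)
  chi <- if (vs > 0) o_minus_e^2 / vs else 0
  o1 <- sum(rt[, "d1"])
  d_tot <- sum(rt[, "d"])
  structure(list(method = "logrank",
                 chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = c(d_tot - o1, o1),
                 expected = c(d_tot - sum(e1), sum(e1)),
                 group_levels = g$levels,
                 n_per_group = c(sum(g$x == 0L), sum(g$x == 1L))),
            class = "cgp_survtest")
}

cox_breslow_parts <- function(beta_coef, rt) {
  ebx <- exp(beta_coef)
  denom <- (rt[, "n"] - rt[, "n1"]) + rt[, "n1"] * ebx
  p1 <- rt[, "n1"] * ebx / denom
  list(loglik = sum(beta_coef * rt[, "d1"] - rt[, "d"] * log(denom)),
       score = sum(rt[, "d1"] - rt[, "d"] * p1),
       info = sum(rt[, "d"] * p1 * (1 - p1)))
}

#' Univariate Cox proportional-hazards test for a binary phenotype
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling by
#' Newton-Raphson on the single coefficient. Reports the hazard ratio of
#' the second group level relative to the first, its Wald chi-square and
#' p-value, and the score test at coefficient zero (which equals the
#' log-rank statistic in the absence of cross-group ties). A monotone
#' partial likelihood (complete separation of the event orderings) is
#' reported with `infinite_hr = TRUE` rather than an error.
#'
#' @param times,events as in [km_estimate()]; at least one event required.
#' @param groups two-level group membership; the hazard ratio refers to the
#'   lexicographically second level (e.g. `CIMP_positive` vs
#'   `CIMP_negative`).
#' @param max_iter,tol Newton-Raphson iteration cap and convergence
#'   tolerance on the step size.
#' @return a `cgp_survtest` list with `coef`, `hazard_ratio`, `log_hr_se`,
#'   `chi_square` / `p_value` (Wald), `score_chi_square` / `score_p_value`,
#'   `loglik`, `iterations`, `converged`, `infinite_hr`, `n_per_group`.
#' @export
cox_univariate <- function(times, events, groups, max_iter = 100L, tol = 1e-9) {
  check_surv_input(times, events)
  g <- as_group01(groups)
  if (sum(events) < 1) stop_cgp("at least one event is required for the Cox model")
  rt <- risk_table(times, events, g$x)
  p0 <- cox_breslow_parts(0, rt)
  score_chi <- if (p0$info > 0) p0$score^2 / p0$info else 0
  b <- 0
  ll <- p0$loglik
  converged <- FALSE
  infinite_hr <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    parts <- cox_breslow_parts(b, rt)
    if (parts$info <= 1e-12 || abs(b) > 15) {
      infinite_hr <- TRUE
      break
    }
    step <- parts$score / parts$info
    # step-halving keeps the concave partial log-likelihood non-decreasing
    while (cox_breslow_parts(b + step, rt)$loglik < parts$loglik - 1e-12) {
      step <- step / 2
    }
    b <- b + step
    ll <- cox_breslow_parts(b, rt)$loglik
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !infinite_hr) {
    stop_cgp("Cox Newton-Raphson did not converge in %d iterations", max_iter)
  }
  final <- cox_breslow_parts(b, rt)
  se <- if (final$info > 0) 1 / sqrt(final$info) else Inf
  wald_chi <- if (is.finite(se) && !infinite_hr) (b / se)^2 else NA_real_
  structure(list(method = "cox_wald",
                 coef = if (infinite_hr) sign(b) * Inf else b,
                 hazard_ratio = if (infinite_hr) {
                   if (b >= 0) Inf else 0
                 } else exp(b),
                 log_hr_se = se,
                 chi_square = wald_chi,
                 p_value = if (is.na(wald_chi)) NA_real_ else
                   stats::pchisq(wald_chi, df = 1, lower.tail = FALSE),
                 score_chi_square = score_chi,
                 score_p_value = stats::pchisq(score_chi, df = 1, lower.tail = FALSE),
                 loglik = ll,
                 iterations = it,
                 converged = converged,
                 infinite_hr = infinite_hr,
                 group_levels = g$levels,
                 n_per_group = c(sum(g$x == 0L), sum(g$x == 1L))),
            class = "cgp_survtest")
}

#' Kaplan-Meier curves for each phenotype, stacked for export
#'
#' @param times,events as in [km_estimate()].
#' @param groups group membership vector.
#' @return a data frame of per-group product-limit curves
#'   (`time`, `n_risk`, `n_event`, `survival`, `group`).
#' @export
km_by_group <- function(times, events, groups) {
  groups <- as.character(groups)
  out <- lapply(sort(unique(groups)), function(gl) {
    sel <- groups == gl
    km_estimate(times[sel], events[sel], group_label = gl)
  })
  do.call(rbind, lapply(out, as.data.frame))
}

#' @export
print.cgp_survtest <- function(x, ...) {
  if (x$method == "logrank") {
    cat(sprintf("log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
                x$chi_square, x$p_value))
  } else {
    cat(sprintf("Cox PH (%s vs %s): HR = %.4g, Wald chi-square = %.4g, p = %.4g\n",
                x$group_levels[2L], x$group_levels[1L], x$hazard_ratio,
                x$chi_square, x$p_value))
    cat(sprintf("  score test at 0: chi-square = %.4g, p = %.4g\n",
                x$score_chi_square, x$score_p_value))
    if (x$infinite_hr) cat("  note: monotone likelihood, hazard ratio unbounded\n")
  }
  cat(sprintf("  n per group: %s = %d, %s = %d\n", x$group_levels[1L],
              x$n_per_group[1L], x$group_levels[2L], x$n_per_group[2L]))
  invisible(x)
}
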