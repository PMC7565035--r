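# Expression-survival association screen.
#
# Kaplan-Meier estimation and the log-rank test are delegated to the
# `survival` package; the univariate Cox partial-likelihood fit is
# authored here (Newton iteration, Breslow tie handling, gradient
# tolerance 1e-8) and cross-checked against survival::coxph in the test
# suite.

align_survival <- function(expression, survival_df, gene, tumour_type) {
  sv <- survival_df[survival_df$tumour_type == tumour_type, , drop = FALSE]
  sv <- sv[sv$sample %in% colnames(expression), , drop = FALSE]
  sv$expr <- as.numeric(expression[gene, sv$sample])
  sv
}

#' Kaplan-Meier median-split comparison
#'
#' Splits the tumour samples of one type at the median expression of a
#' gene (strictly above the median versus at-or-below), estimates the two
#' product-limit survival curves and runs the two-group log-rank test
#' (1 df).
#'
#' @param expression Genes x samples log2 matrix.
#' @param survival_df Survival table (`sample`, `tumour_type`, `time`,
#'   `event` with event 1 = death observed).
#' @param gene,tumour_type Pair under test.
#' @param min_events Minimum number of observed events (default 2);
#'   below it (e.g. everything censored) the test is not evaluable.
#' @return List: `evaluable`, `n_high`, `n_low`, `logrank_chi2`,
#'   `logrank_p`, `direction` (`"worse_with_high"` /
#'   `"better_with_high"`, from the sign of observed-minus-expected
#'   events in the high group), `km` (data frame `group`, `time`,
#'   `surv`, `n_risk`, `n_event`) and `fit` (the `survfit` object).
#' @export
km_median_split <- function(expression, survival_df, gene, tumour_type,
                            min_events = 2) {
  sv <- align_survival(expression, survival_df, gene, tumour_type)
  out <- list(evaluable = FALSE, n_high = NA_integer_, n_low = NA_integer_,
              logrank_chi2 = NA_real_, logrank_p = NA_real_,
              direction = NA_character_, km = NULL, fit = NULL)
  if (!nrow(sv) || sum(sv$event) < min_events) return(out)
  med <- stats::median(sv$expr)
  sv$group <- factor(ifelse(sv$expr > med, "high", "low"),
                     levels = c("low", "high"))
  if (length(unique(sv$group)) < 2) return(out)
  surv_obj <- survival::Surv(sv$time, sv$event)
  fit <- survival::survfit(surv_obj ~ group, data = sv)
  sd <- survival::survdiff(surv_obj ~ group, data = sv)
  km <- data.frame(
    group = rep(sub("group=", "", names(fit$strata)),
                fit$strata),
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    n_event = fit$n.event, stringsAsFactors = FALSE)
  obs <- sd$obs; expd <- sd$exp
  hi_i <- grep("high", names(sd$n))
  out$evaluable <- TRUE
  out$n_high <- sum(sv$group == "high")
  out$n_low <- sum(sv$group == "low")
  out$logrank_chi2 <- unname(sd$chisq)
  out$logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  out$direction <- if (obs[hi_i] > expd[hi_i]) "worse_with_high"
  else "better_with_high"
  out$km <- km
  out$fit <- fit
  out
}

# Newton-Raphson maximiser of the univariate Cox partial likelihood with
# Breslow handling of tied event times. x must be centred/scaled by the
# caller if per-SD coefficients are wanted.
cox_newton <- function(x, time, event, tol = 1e-8, max_iter = 25) {
  ok <- is.finite(x) & is.finite(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  n <- length(x)
  d <- sum(event)
  fail <- list(coef = NA_real_, se = NA_real_, p = NA_real_, n = n,
               n_events = d, converged = FALSE)
  if (d == 0 || stats::sd(x) == 0) return(fail)
  ord <- order(-time)                # descending: risk sets are prefixes
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  # group tied times so every member of a tie shares the full risk set
  grp <- cumsum(!duplicated(time))
  beta <- 0
  for (it in seq_len(max_iter)) {
    w <- exp(beta * x)
    s0 <- cumsum(w)
    s1 <- cumsum(w * x)
    s2 <- cumsum(w * x^2)
    last <- cumsum(tabulate(grp))    # index of last member of each tie group
    S0 <- s0[last][grp]; S1 <- s1[last][grp]; S2 <- s2[last][grp]
    ev <- event == 1
    U <- sum(x[ev] - S1[ev] / S0[ev])
    I <- sum(S2[ev] / S0[ev] - (S1[ev] / S0[ev])^2)
    if (!is.finite(U) || !is.finite(I) || I <= 0) return(fail)
    step <- U / I
    beta <- beta + step
    if (abs(U) < tol) break
  }
  if (abs(U) >= tol && abs(step) > 1e-6) return(fail)
  se <- 1 / sqrt(I)
  z <- beta / se
  list(coef = beta, se = se, p = 2 * stats::pnorm(-abs(z)), n = n,
       n_events = d, converged = TRUE)
}

#' Univariate Cox proportional-hazards association
#'
#' Fits a single-covariate Cox model of survival on a gene's expression
#' within one tumour type, by Newton maximisation of the Breslow partial
#' likelihood (gradient tolerance 1e-8). With `z_scale = TRUE` (default)
#' expression is standardised within the tumour type, so the coefficient
#' is the log hazard ratio per SD of expression.
#'
#' @inheritParams km_median_split
#' @param min_events Minimum observed events for the fit (default 10).
#' @param z_scale Standardise the covariate within the tumour type.
#' @return List: `gene`, `tumour_type`, `coef`, `se`, `p`, `n`,
#'   `n_events`, `converged`, `evaluable`.
#' @export
cox_association <- function(expression, survival_df, gene, tumour_type,
                            min_events = 10, z_scale = TRUE) {
  sv <- align_survival(expression, survival_df, gene, tumour_type)
  out <- list(gene = gene, tumour_type = tumour_type, coef = NA_real_,
              se = NA_real_, p = NA_real_, n = nrow(sv),
              n_events = sum(sv$event), converged = FALSE,
              evaluable = FALSE)
  if (!nrow(sv) || sum(sv$event) < min_events) return(out)
  xv <- sv$expr
  if (z_scale) {
    if (stats::sd(xv) == 0) return(out)
    xv <- as.numeric(scale(xv))
  }
  fit <- cox_newton(xv, sv$time, sv$event)
  out$coef <- fit$coef; out$se <- fit$se; out$p <- fit$p
  out$converged <- fit$converged
  out$evaluable <- fit$converged
  out
}

#' Expression-survival screen with BH-FDR control
#'
#' Runs [cox_association()] (and the [km_median_split()] log-rank test)
#' for every gene x tumour-type pair, adjusts the Cox p-values by
#' Benjamini-Hochberg across the whole evaluated family (one family for
#' all pairs — the conservative choice), and flags associations with
#' adjusted p below `fdr`.
#'
#' @inheritParams cox_association
#' @param gene_set Genes screened (default: all expression rows).
#' @param tumour_types Tumour types screened (default: all in
#'   `survival_df`).
#' @param fdr FDR threshold (default 0.05).
#' @return Data frame, one row per evaluable pair: `gene`,
#'   `tumour_type`, `cox_coefficient`, `se`, `p`, `fdr_p`,
#'   `logrank_chi2`, `logrank_p`, `direction`, `n`, `n_events`,
#'   `significant`. Non-converged or under-powered pairs are excluded
#'   from the FDR family.
#' @export
survival_screen <- function(expression, survival_df, gene_set = NULL,
                            tumour_types = NULL, min_events = 10,
                            z_scale = TRUE, fdr = 0.05) {
  if (is.null(gene_set)) gene_set <- rownames(expression)
  if (is.null(tumour_types))
    tumour_types <- sort(unique(survival_df$tumour_type))
  rows <- list()
  for (tt in tumour_types) for (g in gene_set) {
    cx <- cox_association(expression, survival_df, g, tt,
                          min_events = min_events, z_scale = z_scale)
    if (!cx$evaluable) next
    km <- km_median_split(expression, survival_df, g, tt)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, tumour_type = tt, cox_coefficient = cx$coef, se = cx$se,
      p = cx$p, logrank_chi2 = km$logrank_chi2, logrank_p = km$logrank_p,
      direction = if (cx$coef > 0) "worse_with_high" else "better_with_high",
      n = cx$n, n_events = cx$n_events, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), tumour_type = character(),
                      cox_coefficient = numeric(), se = numeric(),
                      p = numeric(), fdr_p = numeric(),
                      logrank_chi2 = numeric(), logrank_p = numeric(),
                      direction = character(), n = integer(),
                      n_events = integer(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr_p < fdr
  out <- out[order(out$fdr_p, out$gene, out$tumour_type),
             c("gene", "tumour_type", "cox_coefficient", "se", "p",
               "fdr_p", "logrank_chi2", "logrank_p", "direction", "n",
               "n_events", "significant")]
  rownames(out) <- NULL
  out
}
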