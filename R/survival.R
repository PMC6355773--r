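#' Kaplan-Meier curves and log-rank test across score groups
#'
#' Product-limit survival estimates per group plus the k-group log-rank
#' chi-squared test.  With no events anywhere the test is undefined and
#' the result is flagged.
#'
#' @param groups group labels (e.g. [tertile_groups()] output).
#' @param rfs_time follow-up times (months, >= 0).
#' @param rfs_event event indicators (0/1).
#' @return list with \code{curves} (a [survival::survfit()] object, or
#'   \code{NULL} when degenerate) and \code{test} (an
#'   \code{assoc_result}).
#' @export
km_logrank <- function(groups, rfs_time, rfs_event) {
  keep <- !is.na(groups) & !is.na(rfs_time) & !is.na(rfs_event)
  g <- droplevels(factor(groups[keep]))
  tt <- rfs_time[keep]
  ev <- rfs_event[keep]
  if (nlevels(g) < 2L) stop("log-rank needs at least 2 groups")
  sizes <- as.vector(table(g))
  if (sum(ev) == 0)
    return(list(curves = NULL,
                test = .assoc_result("log_rank", NA_real_, NA_real_,
                                     sizes, "no events")))
  fit <- survival::survfit(survival::Surv(tt, ev) ~ g)
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  list(curves = fit,
       test = .assoc_result("log_rank", unname(sd$chisq), p, sizes))
}

#' Cox proportional-hazards fit of survival on a signature score
#'
#' Partial-likelihood fit reporting the hazard ratio per 1 SD of score
#' (the score is standardized within the analysed samples) with Wald
#' 95\% confidence interval and p-value.  The multivariable model adds
#' age (continuous), tumor size (continuous), grade (ordinal numeric
#' 1-3) and nodal status (binary).  Missing data are handled
#' complete-case on the covariates used; constant covariates are
#' dropped with a warning.
#'
#' @param score named per-sample scores (names matched against
#'   \code{clinical$sample_id}; an unnamed vector must align with the
#'   clinical rows).
#' @param clinical a [clinical_table()] with \code{rfs_time} and
#'   \code{rfs_event}.
#' @param multivariable add the clinical covariates.
#' @param stratum label stored on the result.
#' @param signature label stored on the result.
#' @param min_events minimum number of events required.
#' @return object of class \code{hazard_result}: \code{signature},
#'   \code{stratum}, \code{model}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{n}, \code{n_events}.
#' @export
cox_fit <- function(score, clinical, multivariable = FALSE,
                    stratum = "all", signature = "signature",
                    min_events = 10L) {
  sc <- if (!is.null(names(score)))
    as.vector(score)[match(clinical$sample_id, names(score))]
  else as.vector(score)
  df <- data.frame(time = clinical$rfs_time, event = clinical$rfs_event,
                   score = sc)
  covs <- character()
  if (multivariable) {
    covs <- intersect(c("age", "size", "grade", "nodal_status"),
                      names(clinical))
    for (cv in covs) df[[cv]] <- as.numeric(clinical[[cv]])
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$event) < min_events)
    stop("fewer than ", min_events, " events in stratum '", stratum, "'")
  drop <- covs[vapply(covs, function(cv) stats::sd(df[[cv]]) == 0,
                      logical(1))]
  if (length(drop)) {
    warning("constant covariate(s) dropped: ", paste(drop, collapse = ", "))
    covs <- setdiff(covs, drop)
  }
  if (stats::sd(df$score) == 0)
    stop("score is constant within stratum '", stratum, "'")
  df$score <- as.vector(scale(df$score))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(c("score", covs), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(is.na(stats::coef(fit)["score"])))
    stop("Cox fit failed to estimate the score coefficient")
  s <- summary(fit)
  structure(list(signature = signature, stratum = stratum,
                 model = if (multivariable) "multivariable" else
                   "univariable",
                 hr = unname(s$conf.int["score", "exp(coef)"]),
                 ci_low = unname(s$conf.int["score", "lower .95"]),
                 ci_high = unname(s$conf.int["score", "upper .95"]),
                 p_value = unname(s$coefficients["score", "Pr(>|z|)"]),
                 n = nrow(df), n_events = sum(df$event)),
            class = "hazard_result")
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("%s | %s | %s: HR %.3f (95%% CI %.3f-%.3f), p = %.3g (n = %d, events = %d)\n",
              x$signature, x$stratum, x$model, x$hr, x$ci_low, x$ci_high,
              x$p_value, x$n, x$n_events))
  invisible(x)
}

# built-in stratum filters over a clinical table
.stratum_filter <- function(clinical, stratum) {
  lum <- !is.na(clinical$subtype) & clinical$subtype %in% c("LumA", "LumB")
  switch(stratum,
         luminal = lum,
         lumA = !is.na(clinical$subtype) & clinical$subtype == "LumA",
         lumB = !is.na(clinical$subtype) & clinical$subtype == "LumB",
         endocrine = lum & !is.na(clinical$endocrine_only) &
           clinical$endocrine_only == 1,
         stop("unknown stratum '", stratum, "'"))
}

#' Pooled multi-dataset prognostic analysis (forest table)
#'
#' Each dataset is rescaled per gene ([rescale_dataset()]) and scored
#' for every signature; samples are then pooled at the patient level
#' and uni- and multivariable Cox models of recurrence-free survival
#' are fit per signature and stratum, with the hazard ratio reported
#' per 1 SD of score (standardized within the stratum).  Strata:
#' \code{luminal} (LumA + LumB), \code{lumA}, \code{lumB},
#' \code{endocrine} (luminal treated with endocrine therapy only).
#' Strata with fewer than \code{min_events} events are skipped with a
#' warning.
#'
#' @param datasets list of cohorts; each element is a list (or
#'   \code{sim_cohort}) with \code{expr} and \code{clinical}.
#' @param signatures list of [gene_signature()] objects.
#' @param strata character vector of stratum names.
#' @param models \code{"univariable"}, \code{"multivariable"} or both.
#' @param rescale_q quantile span for per-dataset rescaling.
#' @param min_events minimum events per stratum.
#' @return data.frame of class \code{forest_table}: one row per
#'   signature x stratum x model, columns \code{signature},
#'   \code{stratum}, \code{model}, \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{n}, \code{n_events},
#'   \code{significant} (nominal p < 0.05).
#' @export
pooled_analysis <- function(datasets, signatures,
                            strata = c("luminal", "lumA", "lumB",
                                       "endocrine"),
                            models = c("univariable", "multivariable"),
                            rescale_q = 0.95, min_events = 10L) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  models <- match.arg(models, several.ok = TRUE)
  scored <- lapply(datasets, function(d) {
    resc <- suppressWarnings(rescale_dataset(d$expr, rescale_q))
    sc <- lapply(signatures, function(s) signature_score(resc, s))
    names(sc) <- vapply(signatures, function(s) s$name, character(1))
    list(scores = sc, clinical = d$clinical)
  })
  clin <- do.call(rbind, lapply(seq_along(scored), function(i) {
    cl <- scored[[i]]$clinical
    cl$.dataset <- i
    cl
  }))
  rows <- list()
  for (s in signatures) {
    pooled_score <- unlist(lapply(scored, function(d)
      as.vector(d$scores[[s$name]])), use.names = FALSE)
    for (st in strata) {
      keep <- .stratum_filter(clin, st)
      if (sum(clin$rfs_event[keep], na.rm = TRUE) < min_events) {
        warning("stratum '", st, "' skipped: fewer than ", min_events,
                " events")
        next
      }
      for (md in models) {
        hz <- cox_fit(pooled_score[keep], clin[keep, , drop = FALSE],
                      multivariable = md == "multivariable",
                      stratum = st, signature = s$name,
                      min_events = min_events)
        rows[[length(rows) + 1L]] <-
          data.frame(signature = hz$signature, stratum = hz$stratum,
                     model = hz$model, hr = hz$hr, ci_low = hz$ci_low,
                     ci_high = hz$ci_high, p_value = hz$p_value,
                     n = hz$n, n_events = hz$n_events,
                     significant = hz$p_value < 0.05,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$signature, out$stratum, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("forest_table", "data.frame")
  out
}

#' @export
print.forest_table <- function(x, ...) {
  cat("Pooled proportional-hazards forest table (HR per 1 SD of score)\n")
  df <- as.data.frame(x)
  df$hr <- sprintf("%.3f", df$hr)
  df$ci <- sprintf("[%.3f, %.3f]", x$ci_low, x$ci_high)
  df$p_value <- format(x$p_value, digits = 3)
  print(df[, c("signature", "stratum", "model", "hr", "ci", "p_value",
               "n", "n_events", "significant")], row.names = FALSE)
  invisible(x)
}
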