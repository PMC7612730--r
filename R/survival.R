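## Structure-outcome association: four-category discretization of
## structure connection fractions (absent + tertiles among present
## tumors), Cox proportional-hazards models per structure within ER
## strata adjusted for HER2, and presence/absence log-rank tests with
## Kaplan-Meier curves.

#' Discretize structure connection fractions into four categories
#'
#' Tumors lacking a structure (fraction exactly 0) form the baseline
#' `absent` category; tumors containing it are split into `low`, `mid`
#' and `high` tertiles of the positive fractions. Values tied with a
#' tertile boundary fall in the lower category.
#'
#' @param fractions Output of [structure_connection_fractions()], or a
#'   data.frame with `patient_id` plus one fraction column per structure.
#' @return Long data frame: `patient_id`, `structure`, `category`
#'   (ordered factor absent < low < mid < high), `score` (0-3).
#' @export
discretize_connectivity <- function(fractions) {
  structures <- setdiff(names(fractions),
                        c("patient_id", "total_connections"))
  levs <- c("absent", "low", "mid", "high")
  rows <- lapply(structures, function(s) {
    f <- fractions[[s]]
    if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
    cat <- rep("absent", length(f))
    pos <- f > 0
    if (sum(pos) > 0 && sum(pos) < 3) {
      warning(sprintf("structure %s present in < 3 tumors; all labeled low", s))
      cat[pos] <- "low"
    } else if (any(pos)) {
      q <- quantile(f[pos], probs = c(1/3, 2/3), names = FALSE)
      cat[pos] <- levs[2 + (f[pos] > q[1]) + (f[pos] > q[2])]
    }
    data.frame(patient_id = fractions$patient_id, structure = s,
               category = factor(cat, levels = levs, ordered = TRUE),
               score = match(cat, levs) - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cox models of disease-specific survival per structure
#'
#' Within one ER stratum, fits for each structure a Cox
#' proportional-hazards model of disease-specific survival on the
#' structure's four-category burden, adjusted for HER2 status. The
#' ordered category enters as a numeric 0-3 score by default (one
#' hazard ratio per structure); `coding = "categorical"` fits contrasts
#' of each present tertile against the absent baseline instead.
#'
#' @param categories Output of [discretize_connectivity()].
#' @param clinical Clinical table (see [read_clinical()]).
#' @param er_stratum `"pos"` or `"neg"`.
#' @param coding `"score"` (default) or `"categorical"`.
#' @return Data frame per structure (per contrast when categorical) with
#'   hazard ratio, 95% CI, p, n, and event count.
#' @export
cox_structures <- function(categories, clinical,
                           er_stratum = c("pos", "neg"),
                           coding = c("score", "categorical")) {
  er_stratum <- match.arg(er_stratum)
  coding <- match.arg(coding)
  cl <- clinical[clinical$er_status == er_stratum, ]
  n_events <- sum(cl$dss_event)
  if (n_events == 0) stop("no events in ER stratum ", er_stratum)
  if (n_events < 10)
    warning(sprintf("only %d events in ER stratum %s", n_events, er_stratum))
  her2 <- as.integer(cl$her2_status == "pos")
  rows <- list()
  for (s in unique(categories$structure)) {
    cc <- categories[categories$structure == s, ]
    idx <- match(cl$patient_id, cc$patient_id)
    if (anyNA(idx)) stop("categories missing for some patients")
    surv <- survival::Surv(cl$dss_time_months, cl$dss_event)
    fit <- tryCatch({
      if (coding == "score") {
        survival::coxph(surv ~ cc$score[idx] + her2)
      } else {
        cat3 <- factor(as.character(cc$category[idx]),
                       levels = c("absent", "low", "mid", "high"))
        survival::coxph(surv ~ cat3 + her2)
      }
    }, warning = function(w) {
      structure(suppressWarnings(
        if (coding == "score") survival::coxph(surv ~ cc$score[idx] + her2)
        else survival::coxph(surv ~ factor(as.character(cc$category[idx]),
               levels = c("absent", "low", "mid", "high")) + her2)),
        converged = FALSE)
    })
    converged <- is.null(attr(fit, "converged"))
    sm <- summary(fit)
    terms <- setdiff(rownames(sm$coefficients), "her2")
    for (tm in terms) {
      est <- sm$coefficients[tm, "coef"]
      se <- sm$coefficients[tm, "se(coef)"]
      rows[[paste(s, tm)]] <- data.frame(
        structure = s,
        term = if (coding == "score") "per_tertile_score" else tm,
        er_stratum = er_stratum,
        hr = exp(est), ci_lo = exp(est - 1.96 * se),
        ci_hi = exp(est + 1.96 * se),
        p = sm$coefficients[tm, "Pr(>|z|)"],
        n = nrow(cl), n_events = n_events,
        converged = converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-rank presence test and Kaplan-Meier curves
#'
#' Compares disease-specific survival between tumors with and without a
#' given structure.
#'
#' @param presence Named (by patient id) logical vector.
#' @param clinical Clinical table.
#' @return List with `p` (log-rank p value; `NA` when no events) and
#'   `curves`, a Kaplan-Meier step-function table per group.
#' @export
km_logrank <- function(presence, clinical) {
  pres <- presence[match(clinical$patient_id, names(presence))]
  if (anyNA(pres)) stop("presence missing for some patients")
  if (all(pres) || !any(pres)) stop("one presence group is empty")
  surv <- survival::Surv(clinical$dss_time_months, clinical$dss_event)
  grp <- factor(ifelse(pres, "present", "absent"))
  p <- if (sum(clinical$dss_event) == 0) {
    message("km_logrank: no events; p undefined")
    NA_real_
  } else {
    sd <- survival::survdiff(surv ~ grp)
    1 - pchisq(sd$chisq, df = 1)
  }
  sf <- survival::survfit(surv ~ grp)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^grp=", "", strata),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  list(p = p, curves = curves)
}
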