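#' Read a clinical survival table (columns `sample`, `time`, `event`)
#'
#' `time` is follow-up in days (non-negative); `event` is 1 for an observed
#' death and 0 for censoring.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  clinical_table(df$sample, df$time, df$event)
}

#' Construct a validated clinical table
#' @param sample Sample ids.
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator, 1 = death observed, 0 = censored.
#' @return Data frame of class `ClinicalTable`.
#' @export
clinical_table <- function(sample, time, event) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample ids in clinical table")
  if (anyNA(time) || any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  structure(data.frame(sample = sample, time = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("ClinicalTable", "data.frame"))
}

#' Split samples at the median of a marker
#'
#' Samples at or below the median go to the `"low"` group (deterministic
#' tie handling; flip with `ties`). For even n the median is the average of
#' the two middle order statistics.
#'
#' @param values Numeric vector, length >= 2.
#' @param ties Where values exactly at the median go: `"low"` (default) or
#'   `"high"`.
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
median_split <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(values) < 2) stop("need at least 2 samples")
  if (anyNA(values)) stop("missing values")
  med <- stats::median(values)
  if (all(values == values[1L])) stop("degenerate split: all values identical")
  if (ties == "low") ifelse(values <= med, "low", "high")
  else ifelse(values < med, "low", "high")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate. Censored times reduce the risk set without a
#' step; ties between events and censorings at the same time are resolved
#' by processing events first (the standard convention).
#'
#' @param times Non-negative event/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame `time`, `n_risk`, `n_event`, `n_censor`, `surv` with
#'   one row per distinct observed time; `surv` starts from 1 and is
#'   non-increasing.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and non-negative")
  if (!all(events %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

# restricted mean survival time: area under the KM step curve up to tau
.rmst <- function(times, events, tau) {
  km <- km_curve(times, events)
  t_ev <- c(0, km$time[km$n_event > 0], tau)
  s <- c(1, km$surv[km$n_event > 0], NA)
  t_ev <- pmin(t_ev, tau)
  sum(diff(t_ev) * s[-length(s)])
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank statistic over distinct event times, with
#' p from the chi-square(1) reference. With no events anywhere the test is
#' undefined; by convention chi2 = 0, p = 1 (with a warning).
#'
#' @param timesA,eventsA Times and event indicators of group A.
#' @param timesB,eventsB Likewise for group B.
#' @return List `chi2`, `p`.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chi2 = 0, p = 1))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Median-split survival screen over all features
#'
#' For each feature of the expression matrix, samples shared with the
#' clinical table are split at the median expression and the two groups
#' compared with the log-rank test. Direction is read off the restricted
#' mean survival difference: `high_worse` when the high-expression group
#' has the smaller restricted mean. Features yielding a degenerate split
#' are skipped with a reason.
#'
#' @param em An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param min_group Smallest allowed group after the split, default 2.
#' @return Data frame of class `SurvivalScreen`: `feature`, `n_low`,
#'   `n_high`, `chi2`, `p`, `q` (BH across screened features), `direction`.
#'   Attribute `skipped` lists dropped features.
#' @export
survival_screen <- function(em, clinical, min_group = 2L) {
  shared <- intersect(sample_ids(em), clinical$sample)
  if (length(shared) < 4) stop("fewer than 4 samples shared with the clinical table")
  ci <- match(shared, clinical$sample)
  tt <- clinical$time[ci]; ev <- clinical$event[ci]
  tau <- max(tt)

  rows <- vector("list", nrow(em))
  skipped <- list()
  for (i in seq_len(nrow(em))) {
    f <- feature_ids(em)[i]
    v <- em[i, shared]
    if (all(v == v[1L])) {
      skipped[[f]] <- "constant expression"
      next
    }
    g <- median_split(v)
    lo <- g == "low"
    if (sum(lo) < min_group || sum(!lo) < min_group) {
      skipped[[f]] <- "group below minimum size after split"
      next
    }
    lr <- suppressWarnings(logrank_test(tt[lo], ev[lo], tt[!lo], ev[!lo]))
    d_rmst <- .rmst(tt[!lo], ev[!lo], tau) - .rmst(tt[lo], ev[lo], tau)
    rows[[i]] <- data.frame(
      feature = f, n_low = sum(lo), n_high = sum(!lo),
      chi2 = lr$chi2, p = lr$p,
      direction = if (d_rmst < 0) "high_worse" else if (d_rmst > 0) "high_better" else "none",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no feature survived the screen")
  out$q <- bh_adjust(out$p)
  out <- out[c("feature", "n_low", "n_high", "chi2", "p", "q", "direction")]
  rownames(out) <- NULL
  structure(out,
            skipped = data.frame(feature = names(skipped),
                                 reason = unlist(skipped, use.names = FALSE),
                                 stringsAsFactors = FALSE),
            class = c("SurvivalScreen", "data.frame"))
}
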