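#' Two-group k-means clustering of enrichment scores
#'
#' Lloyd's algorithm with k = 2 and k-means++ seeding, restarted `restarts`
#' times and keeping the solution with the lowest within-cluster sum of
#' squares. Cluster 1 is anchored to the group with the higher mean score in
#' `anchor` (default the `jb2_up` column, or the first score column), so
#' labels are stable across runs.
#'
#' @param scores Tibble of per-patient gene-set scores (identifier column
#'   `sample`/`patient_id` optional) or a numeric matrix.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param seed Integer seed.
#' @param anchor Score column used to anchor cluster 1 (default `"jb2_up"`
#'   if present).
#' @return Integer vector of cluster labels (1 or 2), one per row, with the
#'   chosen within-cluster sum of squares as attribute `tot_withinss`.
#' @export
kmeans2 <- function(scores, restarts = 10, seed = 1L, anchor = NULL) {
  m <- score_matrix(scores)
  if (nrow(m) < 2) stop("need at least two patients", call. = FALSE)
  if (any(!is.finite(m))) stop("scores must be finite", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(m, 2)
    fit <- suppressWarnings(
      stats::kmeans(m, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
    if (length(unique(fit$cluster)) < 2) next   # empty cluster: discard
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    stop("k-means produced an empty cluster in every restart", call. = FALSE)
  }
  lab <- best$cluster
  if (is.null(anchor)) {
    anchor <- if ("jb2_up" %in% colnames(m)) "jb2_up" else 1L
  }
  a <- m[, anchor]
  if (mean(a[lab == 2]) > mean(a[lab == 1])) lab <- 3L - lab
  structure(as.integer(lab), tot_withinss = best$tot.withinss)
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(m, 1, function(x) {
      min(colSums((t(m[idx, , drop = FALSE]) - x)^2))
    })
    if (all(d2 == 0)) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  m[idx, , drop = FALSE]
}

score_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  if (is.numeric(scores)) return(matrix(scores, dimnames = list(NULL, "score")))
  id_cols <- intersect(c("sample", "patient_id", "dataset_id", "class"),
                       names(scores))
  as.matrix(scores[, setdiff(names(scores), id_cols), drop = FALSE])
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (right-continuous, non-increasing, S(0) = 1 implicit).
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each distinct
#' event time.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Two-level grouping vector.
#' @return Tibble with columns `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  if (length(unique(groups)) < 2) {
    stop("need two non-empty groups", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  tibble::tibble(chisq = fit$chisq, df = df,
                 p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow ties by default; Efron available) with
#' Wald confidence intervals and p-values.
#'
#' @param times,events As in [km_estimate()].
#' @param covariates Numeric vector, matrix or data frame of per-patient
#'   covariates.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return Object of class `cox_fit` wrapping the fit; use [tidy.cox_fit()]
#'   / [glance.cox_fit()] for tabular summaries.
#' @export
cox_fit <- function(times, events, covariates, ties = c("breslow", "efron"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  check_surv(times, events)
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
  }
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant covariate", call. = FALSE)
  }
  dat <- data.frame(.time = times, .event = events, x, check.names = FALSE)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", colnames(x)),
                                        collapse = " + ")))
  fit <- survival::coxph(form, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-8,
                                                           iter.max = 50))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    warning("Cox fit may not have converged (diverging coefficient); ",
            "possible monotone likelihood / perfect separation",
            call. = FALSE)
  }
  structure(list(fit = fit, conf_level = conf_level, ties = ties),
            class = "cox_fit")
}

#' Tidy a Cox fit into per-term hazard ratios
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log HR), `hr`, `se`, `statistic`,
#'   `p`, `conf_low`, `conf_high` (on the HR scale).
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  co <- s$coefficients
  z <- stats::qnorm(1 - (1 - x$conf_level) / 2)
  tibble::tibble(term = rownames(co),
                 estimate = co[, "coef"],
                 hr = exp(co[, "coef"]),
                 se = co[, "se(coef)"],
                 statistic = co[, "z"],
                 p = co[, "Pr(>|z|)"],
                 conf_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
                 conf_high = exp(co[, "coef"] + z * co[, "se(coef)"]))
}

#' One-row summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with n, number of events, likelihood-ratio and score test
#'   statistics, iterations and convergence flag.
#' @export
glance.cox_fit <- function(x, ...) {
  f <- x$fit
  lr <- 2 * diff(f$loglik)
  tibble::tibble(n = f$n, n_event = f$nevent,
                 logLik = f$loglik[2], lr_statistic = lr,
                 score_statistic = f$score,
                 iterations = f$iter,
                 converged = f$iter < 50)
}

#' @export
print.cox_fit <- function(x, ...) {
  td <- tidy.cox_fit(x)
  cat("Cox proportional-hazards fit (", x$ties, " ties):\n", sep = "")
  print(as.data.frame(td), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Correlate enrichment scores with ordinal therapy response
#'
#' Encodes response `CR < PR < SD < PD` as 1..4 and reports the Pearson
#' correlation with the scores and its two-sided t-based p-value.
#'
#' @param scores Numeric vector of per-model enrichment scores.
#' @param response Character/factor vector of responses among
#'   `CR`, `PR`, `SD`, `PD`.
#' @return Tibble with columns `r`, `p`, `n`.
#' @export
correlate_with_response <- function(scores, response) {
  lev <- c("CR", "PR", "SD", "PD")
  response <- as.character(response)
  if (!all(response %in% lev)) {
    stop("responses must be among CR, PR, SD, PD", call. = FALSE)
  }
  if (length(scores) < 3) stop("need at least 3 models", call. = FALSE)
  if (length(unique(response)) < 2) {
    stop("need at least two distinct response levels", call. = FALSE)
  }
  if (stats::sd(scores) == 0) stop("constant scores", call. = FALSE)
  num <- match(response, lev)
  ct <- stats::cor.test(scores, num, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

check_surv <- function(times, events) {
  if (length(times) < 1) stop("need at least one subject", call. = FALSE)
  if (any(times < 0)) stop("negative survival times", call. = FALSE)
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  invisible(TRUE)
}
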