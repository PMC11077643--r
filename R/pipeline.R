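#' Run standard treatment contrasts on a dose-gradient experiment
#'
#' Convenience wrapper chaining [filter_low_counts()], [normalize_logcpm()]
#' and [moderated_t_contrast()] for a set of two-group contrasts at one
#' timepoint. Median-of-ratios library normalization is the default here
#' because dose-gradient treatments induce a large fraction of the
#' transcriptome, which biases plain CPM fold changes against the control.
#'
#' @param counts Counts tibble (`gene` column then samples).
#' @param samples Sample table (`sample_id`, `treatment`, `timepoint_h`,
#'   `replicate`).
#' @param timepoint_h Timepoint to analyse.
#' @param contrasts List of length-2 character vectors, each
#'   `c(group1, group2)`.
#' @param min_cpm,min_samples Count filter; `min_samples` defaults to half
#'   the samples of the smallest contrast group at this timepoint.
#' @param prior_count,norm Passed to [normalize_logcpm()].
#' @return Named list of `contrast_result` tibbles (names like
#'   `"JB2-vs-DMSO"`).
#' @export
#' @examples
#' sim <- simulate_dose_experiment(sim_config(n_genes = 400, seed = 3))
#' de <- dose_contrasts(sim$counts, sim$samples, 24,
#'                      list(c("JB2", "DMSO"), c("JB2", "JB6")))
#' names(de)
dose_contrasts <- function(counts, samples, timepoint_h,
                           contrasts = list(c("JB2", "DMSO"),
                                            c("JB6", "DMSO"),
                                            c("JB2", "JB6")),
                           min_cpm = 1, min_samples = NULL,
                           prior_count = 0.5, norm = "median_ratio") {
  keep <- samples$timepoint_h == timepoint_h
  if (!any(keep)) stop("no samples at timepoint ", timepoint_h, call. = FALSE)
  samples <- samples[keep, ]
  counts <- counts[, c("gene", samples$sample_id)]
  if (is.null(min_samples)) {
    groups_used <- unique(unlist(contrasts))
    n_min <- min(table(samples$treatment[samples$treatment %in% groups_used]))
    min_samples <- max(1L, floor(n_min / 2))
  }
  counts <- filter_low_counts(counts, min_cpm, min_samples)
  expr <- normalize_logcpm(counts, prior_count, norm = norm)
  grp <- stats::setNames(samples$treatment, samples$sample_id)
  out <- lapply(contrasts, function(ct) {
    moderated_t_contrast(expr, grp, ct)
  })
  names(out) <- vapply(contrasts, paste, character(1), collapse = "-vs-")
  out
}

#' Derive the Gradient Gene Set and both biomarker panels from raw inputs
#'
#' End-to-end derivation: differential expression at both timepoints, GGS
#' construction from the 24 h contrasts, the gradient-derived selector from
#' the 6 h/24 h between-treatment contrasts, the datasets-derived bootstrap
#' ranking from a labelled perturbation collection, and the combined
#' biomarker panel.
#'
#' @param counts,samples Dose-gradient experiment tables.
#' @param collection Labelled perturbation collection (long tibble).
#' @param alpha FDR threshold (default 0.05).
#' @param k_gradient,k_datasets Panel sizes taken from each source.
#' @param exclusions Genes removed from the final panel.
#' @param n_boot,seed Bootstrap parameters for [rank_datasets_derived()].
#' @return List with `contrasts_24h`, `contrasts_6h`, `ggs`,
#'   `gradient_derived`, `datasets_derived`, `panel`.
#' @export
derive_signatures <- function(counts, samples, collection, alpha = 0.05,
                              k_gradient = 12, k_datasets = 15,
                              exclusions = character(),
                              n_boot = 200, seed = 1L) {
  de24 <- dose_contrasts(counts, samples, 24)
  de6 <- dose_contrasts(counts, samples, 6, contrasts = list(c("JB2", "JB6")))
  ggs <- build_ggs(de24[["JB2-vs-DMSO"]], de24[["JB6-vs-DMSO"]],
                   de24[["JB2-vs-JB6"]], alpha = alpha)
  gradient <- select_gradient_derived(de6[["JB2-vs-JB6"]],
                                      de24[["JB2-vs-JB6"]], alpha = alpha)
  ranked <- rank_datasets_derived(collection, n_boot = n_boot, seed = seed)
  panel <- assemble_panel(gradient, ranked,
                          k_gradient = min(k_gradient, nrow(gradient)),
                          k_datasets = k_datasets, exclusions = exclusions)
  list(contrasts_24h = de24, contrasts_6h = de6, ggs = ggs,
       gradient_derived = gradient, datasets_derived = ranked, panel = panel)
}

#' Stratify a cohort by signature enrichment and quantify prognosis
#'
#' Scores each patient's expression against the signature subsets by ssGSEA,
#' clusters the patients into two groups with [kmeans2()], and reports the
#' Kaplan-Meier curves, the log-rank test and a univariate Cox fit on the
#' anchoring subset's score.
#'
#' @param cohort Cohort tibble (`patient_id`, `time`, `event`, `response`,
#'   then gene columns).
#' @param gene_sets Named list of gene sets (e.g. the four GGS subsets).
#' @param anchor Score column driving the Cox fit and cluster anchoring
#'   (default `"jb2_up"`).
#' @param restarts,seed Passed to [kmeans2()].
#' @return List with `scores`, `clusters`, `km` (per-cluster KM tibbles),
#'   `logrank`, `cox` (a `cox_fit` on the anchor score).
#' @export
stratify_cohort <- function(cohort, gene_sets, anchor = "jb2_up",
                            restarts = 10, seed = 1L) {
  expr <- cohort_expression(cohort)
  scores <- score_collection(expr, gene_sets)
  cl <- kmeans2(scores, restarts = restarts, seed = seed, anchor = anchor)
  km <- lapply(split(seq_len(nrow(cohort)), cl), function(i) {
    km_estimate(cohort$time[i], cohort$event[i])
  })
  lr <- logrank_test(cohort$time, cohort$event, cl)
  cox <- cox_fit(cohort$time, cohort$event,
                 stats::setNames(data.frame(scores[[anchor]]), anchor))
  list(scores = scores, clusters = cl, km = km, logrank = lr, cox = cox)
}
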