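#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Weighted running-sum enrichment of one gene set in one ranked profile.
#' Genes are ranked by profile value, descending, with ties broken by gene
#' identifier; position `i` receives rank weight `r_i = N - i + 1`. Walking
#' down the ranking, the in-set cumulative weight
#' `P_in(i) = sum_{j <= i, g_j in G} r_j^alpha / sum_{g in G} r_g^alpha` is
#' compared with the out-of-set cumulative count
#' `P_out(i) = #\{non-set genes at positions <= i\} / (N - |G|)`, and the
#' score is the sum of the differences over all positions (the integral
#' form); with `normalize = TRUE` it is divided by `N` so scores are
#' comparable across profile sizes.
#'
#' @param profile Named numeric vector (gene -> value, e.g. log2 fold change
#'   or t-statistic). Values must be finite.
#' @param gene_set Character vector of gene identifiers; genes absent from
#'   the profile are ignored (at least one must be present).
#' @param alpha_w Rank-weight exponent (default 0.25).
#' @param normalize Divide the running-sum integral by the profile size
#'   (default `TRUE`).
#' @return A single numeric score.
#' @export
#' @examples
#' prof <- c(a = 3, b = 2, c = 1, d = 0, e = -1)
#' ssgsea_score(prof, c("a", "b")) > ssgsea_score(prof, c("d", "e"))
ssgsea_score <- function(profile, gene_set, alpha_w = 0.25, normalize = TRUE) {
  if (is.null(names(profile))) stop("profile must be named", call. = FALSE)
  if (any(!is.finite(profile))) {
    stop("profile contains non-finite values", call. = FALSE)
  }
  n <- length(profile)
  ord <- order(-profile, names(profile))
  inset <- names(profile)[ord] %in% gene_set
  n_in <- sum(inset)
  if (n_in == 0) {
    stop("gene set does not intersect the profile", call. = FALSE)
  }
  w <- (n:1)^alpha_w * inset
  p_in <- cumsum(w) / sum(w)
  p_out <- if (n_in == n) rep(0, n) else cumsum(!inset) / (n - n_in)
  score <- sum(p_in - p_out)
  if (normalize) score / n else score
}

#' Score a collection of profiles against named gene sets
#'
#' Applies [ssgsea_score()] to every profile x gene-set pair. Profiles may
#' be a long perturbation collection (`dataset_id`, `class`, `gene`,
#' `log2fc`) or an expression tibble (`gene` column then one column per
#' sample/patient).
#'
#' @param profiles Long collection tibble or wide expression tibble.
#' @param gene_sets Named list of character vectors.
#' @param alpha_w,normalize Passed to [ssgsea_score()].
#' @return A tibble with one row per profile: an identifier column
#'   (`dataset_id` plus `class` for collections, `sample` otherwise) and one
#'   score column per gene set. Scoring parameters are attached as the
#'   `params` attribute.
#' @export
score_collection <- function(profiles, gene_sets, alpha_w = 0.25,
                             normalize = TRUE) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (all(c("dataset_id", "gene", "log2fc") %in% names(profiles))) {
    split_profiles <- split(profiles, profiles$dataset_id)
    ids <- names(split_profiles)
    mats <- lapply(split_profiles, function(d) {
      stats::setNames(d$log2fc, d$gene)
    })
    meta <- tibble::tibble(dataset_id = ids)
    if ("class" %in% names(profiles)) {
      lab <- profiles[!duplicated(profiles$dataset_id), ]
      meta$class <- lab$class[match(ids, lab$dataset_id)]
    }
  } else {
    m <- counts_matrix(profiles)
    mats <- lapply(seq_len(ncol(m)), function(j) m[, j])
    meta <- tibble::tibble(sample = colnames(m))
  }
  scores <- purrr::map(gene_sets, function(gs) {
    unname(vapply(mats, function(prof) {
      tryCatch(ssgsea_score(prof, gs, alpha_w, normalize),
               error = function(e) {
                 stop("ssGSEA failed for a profile: ", conditionMessage(e),
                      call. = FALSE)
               })
    }, numeric(1)))
  })
  out <- dplyr::bind_cols(meta, tibble::as_tibble(scores))
  attr(out, "params") <- list(alpha_w = alpha_w, normalize = normalize)
  out
}

#' Ferroptosis/apoptosis landscape coordinates per treatment
#'
#' Places each treatment on a two-axis cell-death landscape: every gene is
#' ranked by its moderated t-statistic for the treatment-vs-control
#' contrast, and the single-sample enrichment of a ferroptosis signature
#' (x-axis) and an apoptosis signature (y-axis) is computed on that ranked
#' profile.
#'
#' @param contrasts Named list of contrast results ([moderated_t_contrast()]),
#'   one per treatment, sharing a gene universe.
#' @param ferro_set,apopt_set Character vectors of signature genes.
#' @param alpha_w,normalize Passed to [ssgsea_score()].
#' @return Tibble with columns `treatment`, `ferro` (x), `apopt` (y).
#' @export
landscape_scores <- function(contrasts, ferro_set, apopt_set,
                             alpha_w = 0.25, normalize = TRUE) {
  stopifnot(is.list(contrasts), !is.null(names(contrasts)))
  do.call(check_same_universe, unname(contrasts))
  purrr::imap(contrasts, function(ct, nm) {
    prof <- stats::setNames(ct$t, ct$gene)
    tibble::tibble(treatment = nm,
                   ferro = ssgsea_score(prof, ferro_set, alpha_w, normalize),
                   apopt = ssgsea_score(prof, apopt_set, alpha_w, normalize))
  }) |> dplyr::bind_rows()
}

#' Fisher exact over-representation analysis
#'
#' One-sided (enrichment) Fisher exact test of a query gene list against
#' each pathway, restricted to a stated gene universe, with
#' Benjamini-Hochberg adjustment across pathways.
#'
#' @param query Character vector of genes; must be a subset of `universe`.
#' @param universe Character vector, the tested gene universe.
#' @param pathway_sets Named list of character vectors; each pathway is
#'   intersected with the universe before testing.
#' @return Tibble with columns `pathway`, `overlap`, `pathway_size`,
#'   `query_size`, `odds_ratio`, `p`, `q`, ordered by `p`.
#' @export
fisher_ora <- function(query, universe, pathway_sets) {
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.list(pathway_sets), !is.null(names(pathway_sets)))
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::imap(pathway_sets, function(pw, nm) {
    pw <- intersect(unique(pw), universe)
    a <- length(intersect(query, pw))
    b <- n_q - a
    cc <- length(pw) - a
    d <- n_u - n_q - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "greater")
    tibble::tibble(pathway = nm, overlap = a, pathway_size = length(pw),
                   query_size = n_q,
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p)
}

#' Integrate a qPCR panel by per-gene z-scores
#'
#' Converts the fold changes (versus control) of a biomarker panel into
#' per-gene z-scores so all genes share a common scale, then averages the
#' z-scores over genes within each condition. With
#' `center = "gene_mean"` (default) each gene is standardized across
#' conditions and shifted so its mean z is 1:
#' `z_g(c) = 1 + (FC_g(c) - mean_c FC_g) / sd_c FC_g`. With
#' `center = "unity"` the deviation is taken from a fold change of 1
#' (no change) instead of the gene's mean. Genes with zero standard
#' deviation across conditions are dropped with a warning.
#'
#' @param fold_changes Tibble with a `gene` column then one numeric column
#'   per condition (at least two conditions).
#' @param center `"gene_mean"` (default) or `"unity"`.
#' @return Tibble with columns `condition`, `mean_z` (mean over panel genes).
#' @export
#' @examples
#' fc <- tibble::tibble(gene = "g1", c1 = 2, c2 = 4, c3 = 6)
#' panel_zscore_summary(fc)
panel_zscore_summary <- function(fold_changes,
                                 center = c("gene_mean", "unity")) {
  center <- match.arg(center)
  m <- counts_matrix(fold_changes)
  if (ncol(m) < 2) stop("need at least two conditions", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  degenerate <- sds == 0
  if (all(degenerate)) {
    stop("all genes have zero fold-change variance across conditions",
         call. = FALSE)
  }
  if (any(degenerate)) {
    warning("dropping gene(s) with zero variance: ",
            paste(rownames(m)[degenerate], collapse = ", "), call. = FALSE)
    m <- m[!degenerate, , drop = FALSE]
    sds <- sds[!degenerate]
  }
  centre <- if (center == "gene_mean") rowMeans(m) else 1
  z <- 1 + (m - centre) / sds
  tibble::tibble(condition = colnames(m), mean_z = unname(colMeans(z)))
}
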