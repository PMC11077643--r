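#' Leave-one-out k-nearest-neighbour FIN scores
#'
#' For each dataset, the score is the fraction of its `k` nearest neighbours
#' (excluding itself) labelled `FIN`. Feature rows are z-scored per dataset
#' before computing distances, and distance ties are broken by dataset order.
#'
#' @param features Numeric matrix (datasets x genes) with rownames, or a
#'   tibble with a `dataset_id` column followed by feature columns.
#' @param labels Character vector (`"FIN"`/`"AIN"`), one per dataset row.
#' @param k Number of neighbours (must be `< n` datasets; default 5).
#' @param metric `"euclidean"` or `"correlation"` (distance = 1 - Pearson r).
#' @return Tibble with columns `dataset_id`, `label`, `score`.
#' @export
knn_loo_scores <- function(features, labels, k = 5,
                           metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (is.data.frame(features)) {
    ids <- features$dataset_id
    m <- as.matrix(features[, setdiff(names(features), "dataset_id")])
    rownames(m) <- ids
  } else {
    m <- as.matrix(features)
    if (is.null(rownames(m))) rownames(m) <- sprintf("D%03d", seq_len(nrow(m)))
  }
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of datasets", call. = FALSE)
  stopifnot(length(labels) == n)
  row_sd <- apply(m, 1, stats::sd)
  if (metric == "correlation" && any(row_sd == 0)) {
    stop("constant feature row under the correlation metric", call. = FALSE)
  }
  zs <- (m - rowMeans(m)) / ifelse(row_sd == 0, 1, row_sd)
  dmat <- if (metric == "euclidean") {
    as.matrix(stats::dist(zs))
  } else {
    1 - stats::cor(t(zs))
  }
  score <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    nb <- order(d, seq_along(d))[seq_len(k)]   # ties by dataset order
    mean(labels[-i][nb] == "FIN")
  }, numeric(1))
  tibble::tibble(dataset_id = rownames(m), label = labels, score = score)
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`, where a
#' pair is one positive (`FIN`) and one negative (`AIN`) score and
#' concordant means the positive scores higher.
#'
#' @param scores Numeric vector.
#' @param labels Vector with two classes; `"FIN"` (or `TRUE`/`1`) is the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2, 0.1),
#'         c("FIN", "FIN", "FIN", "AIN", "AIN", "AIN", "AIN"))
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  # midrank formulation == concordant + 0.5 * tied pairs
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  labels == if ("FIN" %in% labels) "FIN" else sort(unique(labels))[1]
}

#' Score and evaluate a gene set as a FIN-vs-AIN classifier
#'
#' Computes the single-sample enrichment of `gene_set` in every profile of a
#' labelled perturbation collection, then summarizes classification power:
#' ROC-AUC of FIN vs AIN, a two-sample Welch t-test comparing class score
#' means, and per-class one-sample t-tests against zero (a non-significant
#' one-sample p indicates the set is not enriched in that class at all).
#' Genes absent from a profile are scored on the intersection and recorded.
#'
#' @param collection Long tibble (`dataset_id`, `class`, `gene`, `log2fc`).
#' @param gene_set Character vector of genes.
#' @param alpha_w,normalize Passed to [ssgsea_score()].
#' @return Object of class `classification_report`: list with `scores`
#'   (tibble `dataset_id`, `class`, `score`), `auc`, `p_two_sample`,
#'   `p_one_sample` (named, per class), `class_means`, `params`.
#' @export
evaluate_signature <- function(collection, gene_set, alpha_w = 0.25,
                               normalize = TRUE) {
  sc <- score_collection(collection, list(set = gene_set),
                         alpha_w = alpha_w, normalize = normalize)
  missing <- setdiff(gene_set, unique(collection$gene))
  scores <- tibble::tibble(dataset_id = sc$dataset_id, class = sc$class,
                           score = sc$set)
  fin <- scores$score[scores$class == "FIN"]
  ain <- scores$score[scores$class == "AIN"]
  structure(list(
    scores = scores,
    auc = roc_auc(scores$score, scores$class),
    p_two_sample = stats::t.test(fin, ain)$p.value,
    p_one_sample = c(FIN = stats::t.test(fin, mu = 0)$p.value,
                     AIN = stats::t.test(ain, mu = 0)$p.value),
    class_means = c(FIN = mean(fin), AIN = mean(ain)),
    missing_genes = missing,
    params = list(n_genes = length(gene_set), alpha_w = alpha_w,
                  normalize = normalize)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("FIN-vs-AIN classification:", nrow(x$scores), "profiles,",
      x$params$n_genes, "signature genes\n")
  cat("  ROC-AUC:", round(x$auc, 3),
      " two-sample t p:", signif(x$p_two_sample, 3), "\n")
  cat("  mean scores: FIN", signif(x$class_means[["FIN"]], 3),
      "/ AIN", signif(x$class_means[["AIN"]], 3), "\n")
  if (length(x$missing_genes)) {
    cat("  ", length(x$missing_genes), "signature gene(s) absent from profiles\n")
  }
  invisible(x)
}

#' Tidy per-dataset scores of a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return The per-dataset score tibble.
#' @export
tidy.classification_report <- function(x, ...) x$scores

#' One-row summary of a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return Tibble with AUC, test p-values and class means.
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_two_sample = x$p_two_sample,
                 p_one_sample_fin = x$p_one_sample[["FIN"]],
                 p_one_sample_ain = x$p_one_sample[["AIN"]],
                 mean_fin = x$class_means[["FIN"]],
                 mean_ain = x$class_means[["AIN"]],
                 n_genes = x$params$n_genes)
}
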