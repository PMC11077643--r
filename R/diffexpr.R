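#' Filter genes with insufficient counts
#'
#' Keeps genes whose counts-per-million reach `min_cpm` in at least
#' `min_samples` samples, preserving gene order. CPM is computed against each
#' sample's total count.
#'
#' @param counts Tibble with a `gene` column followed by one numeric column
#'   per sample.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum number of samples reaching the threshold.
#' @return The filtered counts tibble.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("A", "B"), s1 = c(0, 100), s2 = c(0, 50))
#' filter_low_counts(counts, min_cpm = 1, min_samples = 1)
filter_low_counts <- function(counts, min_cpm = 1, min_samples = 1) {
  m <- counts_matrix(counts)
  if (min_samples > ncol(m)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  lib <- colSums(m)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) {
    stop("no genes pass the count filter (min_cpm = ", min_cpm,
         ", min_samples = ", min_samples, ")", call. = FALSE)
  }
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`, the standard
#' moderated log-CPM transform. With `norm = "median_ratio"` the library
#' size is replaced by a median-of-ratios effective library size (each
#' sample's median count ratio to the per-gene geometric-mean reference,
#' rescaled to the mean raw depth). This compensates the composition bias
#' that arises when a treatment induces a large fraction of the
#' transcriptome — without it, fold changes against an uninduced control are
#' systematically shrunk because the induced genes inflate the library
#' total.
#'
#' @param counts Tibble with a `gene` column then sample columns.
#' @param prior_count Non-negative prior added to each count.
#' @param norm `"none"` (raw column totals, default) or `"median_ratio"`.
#' @return Tibble of class `expression_matrix`: `gene` column then log2-CPM
#'   sample columns.
#' @export
normalize_logcpm <- function(counts, prior_count = 0.5,
                             norm = c("none", "median_ratio")) {
  norm <- match.arg(norm)
  if (prior_count < 0) stop("prior_count must be >= 0", call. = FALSE)
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  if (norm == "median_ratio") lib <- median_ratio_libsize(m)
  logcpm <- log2(sweep(m + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
  out <- dplyr::bind_cols(tibble::tibble(gene = counts$gene),
                          tibble::as_tibble(logcpm))
  class(out) <- c("expression_matrix", class(out))
  out
}

#' Empirical-Bayes moderated two-group t contrast
#'
#' Computes, per gene, the difference of group means on log-CPM (the log2
#' fold change), a residual variance pooled across the two groups, and a
#' moderated t-statistic in which the gene-wise variance is shrunk toward a
#' prior variance `s0^2` with prior degrees of freedom `d0`. The prior is
#' estimated by the method of moments on `log(s^2)`: with residual df `d`,
#' `E[log s^2] = log s0^2 + digamma(d/2) - log(d/2)` and
#' `Var[log s^2] = trigamma(d/2) + trigamma(d0/2)`, so `d0` is obtained by
#' inverting the trigamma function on the excess variance (infinite `d0`,
#' i.e. complete shrinkage, when there is no excess). The moderated
#' statistic is `t = log2FC / (s_tilde * sqrt(1/n1 + 1/n2))` with
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, referred to a t distribution
#' on `d + d0` degrees of freedom; q-values are Benjamini-Hochberg adjusted
#' within the contrast.
#'
#' @param expr Expression tibble from [normalize_logcpm()] (`gene` column
#'   then sample columns).
#' @param groups Character vector of group labels, one per sample column of
#'   `expr` (in column order), or a named vector keyed by sample name.
#' @param contrast Length-2 character vector `c(group1, group2)`; fold
#'   changes are `group1 - group2`.
#' @param prior_df Optional override of the estimated prior df `d0` (0
#'   recovers the ordinary two-sample t with pooled variance).
#' @return A tibble of class `contrast_result` with columns `gene`,
#'   `log2fc`, `t`, `df`, `p`, `q`, `contrast`.
#' @export
moderated_t_contrast <- function(expr, groups, contrast, prior_df = NULL) {
  m <- counts_matrix(expr)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) {
    stop("groups must label every sample column", call. = FALSE)
  }
  stopifnot(length(contrast) == 2)
  i1 <- which(groups == contrast[1])
  i2 <- which(groups == contrast[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) {
    stop("each contrast group needs at least 2 samples (got ", n1, " and ",
         n2, ")", call. = FALSE)
  }
  d <- n1 + n2 - 2
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  lfc <- m1 - m2
  rss <- rowSums((m[, i1, drop = FALSE] - m1)^2) +
    rowSums((m[, i2, drop = FALSE] - m2)^2)
  s2 <- pmax(rss / d, .Machine$double.eps)

  if (is.null(prior_df)) {
    fit <- fit_s2_prior(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(gene = expr$gene, log2fc = unname(lfc),
                        t = unname(tstat),
                        df = df_total, p = unname(p), q = bh_adjust(unname(p)),
                        contrast = paste(contrast, collapse = "-vs-"))
  attr(out, "prior") <- list(d0 = d0, s02 = s02, n1 = n1, n2 = n2)
  class(out) <- c("contrast_result", class(out))
  out
}

# Method-of-moments fit of the scaled inverse-chi-square prior on gene
# variances (on the log scale, following the standard empirical-Bayes
# derivation). Returns prior df d0 (possibly Inf) and prior variance s02.
fit_s2_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma; x > 0, returns y with trigamma(y) = x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i} m p_(j)/j`
#' clipped at 1, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

# Median-of-ratios effective library sizes: per-sample median ratio to the
# geometric-mean reference over genes observed in every sample, rescaled so
# the mean matches the mean raw depth.
median_ratio_libsize <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  if (sum(pos) < 10) {
    stop("too few genes observed in every sample for median-ratio ",
         "normalization", call. = FALSE)
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
  sf / mean(sf) * mean(colSums(m))
}

# Coerce a gene-first tibble (or matrix with rownames) to a numeric matrix.
counts_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x), "gene" %in% names(x))
  if (anyDuplicated(x$gene)) stop("duplicated gene identifiers", call. = FALSE)
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric sample columns", call. = FALSE)
  rownames(m) <- x$gene
  m
}
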