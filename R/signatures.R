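#' Build the Gradient Gene Set (GGS)
#'
#' Splits genes into four disjoint subsets defined by exclusive significance
#' in one treatment and a significant between-treatment difference, all at
#' FDR threshold `alpha`:
#'
#' * `jb2_up`: significantly up in JB2 vs control, not significant in JB6 vs
#'   control, and significantly higher in JB2 than JB6;
#' * `jb2_down`: the mirrored down version;
#' * `jb6_up` / `jb6_down`: the same with the roles of the two treatments
#'   swapped (the between-treatment difference must follow JB6's direction,
#'   i.e. be negative on the JB2-minus-JB6 scale for `jb6_up`).
#'
#' The four subsets are pairwise disjoint by construction; their union is the
#' Gradient Gene Set, the most differential transcriptomic response between
#' the ferroptotic and apoptotic arms of the dose gradient.
#'
#' @param de_jb2 Contrast result for JB2 vs control ([moderated_t_contrast()]).
#' @param de_jb6 Contrast result for JB6 vs control.
#' @param de_jb2_vs_jb6 Contrast result for JB2 vs JB6 (fold changes on the
#'   JB2-minus-JB6 scale).
#' @param alpha FDR threshold in (0, 1), default 0.05.
#' @return An object of class `signature_set`: a named list of the four gene
#'   vectors with `provenance` (contrast labels and alpha) attached.
#' @export
build_ggs <- function(de_jb2, de_jb6, de_jb2_vs_jb6, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  check_same_universe(de_jb2, de_jb6, de_jb2_vs_jb6)
  g <- de_jb2$gene
  d2 <- de_jb2[match(g, de_jb2$gene), ]
  d6 <- de_jb6[match(g, de_jb6$gene), ]
  dd <- de_jb2_vs_jb6[match(g, de_jb2_vs_jb6$gene), ]

  sig2_up <- d2$q < alpha & d2$log2fc > 0
  sig2_dn <- d2$q < alpha & d2$log2fc < 0
  sig6_up <- d6$q < alpha & d6$log2fc > 0
  sig6_dn <- d6$q < alpha & d6$log2fc < 0
  diff_up <- dd$q < alpha & dd$log2fc > 0   # higher in JB2
  diff_dn <- dd$q < alpha & dd$log2fc < 0   # higher in JB6

  sets <- list(
    jb2_up   = g[sig2_up & d6$q >= alpha & diff_up],
    jb2_down = g[sig2_dn & d6$q >= alpha & diff_dn],
    jb6_up   = g[sig6_up & d2$q >= alpha & diff_dn],
    jb6_down = g[sig6_dn & d2$q >= alpha & diff_up]
  )
  structure(sets,
            provenance = list(contrasts = c(jb2 = d2$contrast[1],
                                            jb6 = d6$contrast[1],
                                            diff = dd$contrast[1]),
                              alpha = alpha),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  sizes <- lengths(x)
  cat("Gradient Gene Set:", sum(sizes), "genes\n")
  for (nm in names(x)) cat(" ", nm, ":", sizes[[nm]], "\n")
  invisible(x)
}

#' Tidy a signature set into a gene/subset tibble
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `subset`.
#' @export
tidy.signature_set <- function(x, ...) {
  tibble::tibble(subset = rep(names(x), lengths(x)),
                 gene = unlist(x, use.names = FALSE))[, c("gene", "subset")]
}

#' @export
glance.signature_set <- function(x, ...) {
  s <- lengths(x)
  tibble::tibble(n_total = sum(s), n_jb2_up = s[["jb2_up"]],
                 n_jb2_down = s[["jb2_down"]], n_jb6_up = s[["jb6_up"]],
                 n_jb6_down = s[["jb6_down"]],
                 alpha = attr(x, "provenance")$alpha)
}

#' Select gradient-derived biomarker genes
#'
#' Genes whose expression is significantly lower in JB2 than JB6 at the early
#' timepoint but significantly higher at the late timepoint — a reversal
#' interpreted as an early permissive drop followed by a compensatory
#' protective rise during ferroptosis. Output is ordered by the late-timepoint
#' fold change, descending.
#'
#' @param de_6h,de_24h JB2-vs-JB6 contrast results at 6 h and 24 h on the
#'   same gene universe.
#' @param alpha FDR threshold, default 0.05.
#' @return Tibble with columns `gene`, `log2fc_6h`, `log2fc_24h`, `q_6h`,
#'   `q_24h`, ordered by `log2fc_24h` descending.
#' @export
select_gradient_derived <- function(de_6h, de_24h, alpha = 0.05) {
  check_same_universe(de_6h, de_24h)
  g <- de_6h$gene
  a <- de_6h[match(g, de_6h$gene), ]
  b <- de_24h[match(g, de_24h$gene), ]
  keep <- a$q < alpha & a$log2fc < 0 & b$q < alpha & b$log2fc > 0
  out <- tibble::tibble(gene = g[keep],
                        log2fc_6h = a$log2fc[keep],
                        log2fc_24h = b$log2fc[keep],
                        q_6h = a$q[keep], q_24h = b$q[keep])
  dplyr::arrange(out, dplyr::desc(.data$log2fc_24h))
}

#' Rank genes by FIN-vs-AIN differential expression with bootstrap aggregation
#'
#' Ranks every gene in a perturbation collection by its relative expression
#' in ferroptosis-inducer (FIN) versus apoptosis-inducer (AIN) datasets.
#' Each dataset's profile is first z-scored across genes (neutralising
#' dataset-scale differences); for each of `n_boot` stratified bootstrap
#' resamples of datasets (within class, with replacement) genes are ranked by
#' the Welch t-statistic of FIN vs AIN standardized fold changes, and the
#' final order is the ascending mean rank across resamples (ties broken by
#' gene identifier). The selection frequency is the fraction of resamples in
#' which a gene lands in the top `top_n`.
#'
#' @param collection Long tibble (`dataset_id`, `class`, `gene`, `log2fc`),
#'   e.g. from [simulate_perturbation_collection()].
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Integer seed for the resampling.
#' @param top_n Panel size used for the selection frequency (default 15).
#' @param identity_resample If `TRUE`, use the full collection as the
#'   single "resample" instead of drawing bootstrap samples (requires
#'   `n_boot = 1`); the result is then the plain Welch-t ranking.
#' @return Tibble with columns `gene`, `mean_rank`, `sel_freq`, `t_full`
#'   (the Welch t on the full collection), ordered by `mean_rank`.
#' @export
rank_datasets_derived <- function(collection, n_boot = 200, seed = 1L,
                                  top_n = 15, identity_resample = FALSE) {
  if (identity_resample && n_boot != 1) {
    stop("identity_resample requires n_boot = 1", call. = FALSE)
  }
  stopifnot(n_boot >= 1)
  mats <- collection_matrix(collection)
  z <- mats$z; cls <- mats$class
  if (sum(cls == "FIN") < 2 || sum(cls == "AIN") < 2) {
    stop("need at least two datasets per class", call. = FALSE)
  }
  fin_idx <- which(cls == "FIN"); ain_idx <- which(cls == "AIN")
  n_genes <- nrow(z)

  set.seed(seed)
  rank_sum <- numeric(n_genes)
  top_count <- numeric(n_genes)
  for (b in seq_len(n_boot)) {
    if (identity_resample) {
      fi <- fin_idx; ai <- ain_idx
    } else {
      fi <- sample(fin_idx, length(fin_idx), replace = TRUE)
      ai <- sample(ain_idx, length(ain_idx), replace = TRUE)
    }
    tstat <- welch_t_rows(z[, fi, drop = FALSE], z[, ai, drop = FALSE])
    # rank 1 = most FIN-high; ties by gene identifier for reproducibility
    r <- order(order(-tstat, rownames(z)))
    rank_sum <- rank_sum + r
    top_count <- top_count + (r <= top_n)
  }
  out <- tibble::tibble(gene = rownames(z),
                        mean_rank = rank_sum / n_boot,
                        sel_freq = top_count / n_boot,
                        t_full = welch_t_rows(z[, fin_idx, drop = FALSE],
                                              z[, ain_idx, drop = FALSE]))
  dplyr::arrange(out, .data$mean_rank, .data$gene)
}

# Row-wise Welch t between two column blocks; degenerate variances floored.
welch_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se <- sqrt(pmax(v1 / n1 + v2 / n2, .Machine$double.eps))
  (m1 - m2) / se
}

# Long collection -> list(z = gene x dataset z-scored matrix, class labels).
# Genes absent from a dataset are 0 after standardization.
collection_matrix <- function(collection) {
  stopifnot(all(c("dataset_id", "class", "gene", "log2fc") %in%
                  names(collection)))
  wide <- tidyr::pivot_wider(collection, id_cols = "gene",
                             names_from = "dataset_id",
                             values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  z <- scale(m)                       # per-dataset (column) standardization
  z[is.na(z)] <- 0                    # missing genes contribute nothing
  lab <- collection[!duplicated(collection$dataset_id),
                    c("dataset_id", "class")]
  cls <- lab$class[match(colnames(z), lab$dataset_id)]
  if (!all(cls %in% c("FIN", "AIN"))) {
    stop("dataset classes must be FIN or AIN", call. = FALSE)
  }
  list(z = z, class = cls)
}

#' Assemble a compact biomarker panel from two ranked sources
#'
#' Takes the top `k_gradient` gradient-derived genes and the top `k_datasets`
#' datasets-derived genes, unions them (recording genes supported by both
#' sources) and removes any `exclusions` (e.g. genes that proved unreliable
#' in qPCR validation).
#'
#' @param gradient_genes Character vector or tibble (with a `gene` column)
#'   of gradient-derived genes, best first.
#' @param datasets_ranked Character vector or tibble (with a `gene` column)
#'   of datasets-derived genes, best first.
#' @param k_gradient,k_datasets How many genes to take from each source
#'   (defaults 12 and 15).
#' @param exclusions Genes to drop from the combined panel.
#' @return A tibble of class `biomarker_panel` with columns `gene`, `source`
#'   (`"gradient_derived"`, `"datasets_derived"` or `"both"`); excluded genes
#'   are recorded in the `exclusions` attribute.
#' @export
#' @examples
#' assemble_panel(paste0("g", 1:12), paste0("h", 1:15))
assemble_panel <- function(gradient_genes, datasets_ranked,
                           k_gradient = 12, k_datasets = 15,
                           exclusions = character()) {
  gg <- panel_genes(gradient_genes)
  dd <- panel_genes(datasets_ranked)
  if (k_gradient > length(gg) || k_datasets > length(dd)) {
    stop("k exceeds the length of a source gene list", call. = FALSE)
  }
  gg <- gg[seq_len(k_gradient)]
  dd <- dd[seq_len(k_datasets)]
  genes <- union(dd, gg)
  source <- dplyr::case_when(
    genes %in% gg & genes %in% dd ~ "both",
    genes %in% gg ~ "gradient_derived",
    TRUE ~ "datasets_derived"
  )
  missing_excl <- setdiff(exclusions, genes)
  if (length(missing_excl)) {
    warning("exclusion(s) not in panel: ",
            paste(missing_excl, collapse = ", "), call. = FALSE)
  }
  keep <- !genes %in% exclusions
  out <- tibble::tibble(gene = genes[keep], source = source[keep])
  attr(out, "exclusions") <- intersect(exclusions, genes)
  attr(out, "overlap") <- intersect(gg, dd)
  class(out) <- c("biomarker_panel", class(out))
  out
}

panel_genes <- function(x) {
  g <- if (is.data.frame(x)) x$gene else as.character(x)
  if (anyDuplicated(g)) stop("duplicated genes in source list", call. = FALSE)
  g
}

check_same_universe <- function(...) {
  contrasts <- list(...)
  g <- sort(contrasts[[1]]$gene)
  for (ct in contrasts[-1]) {
    if (!identical(sort(ct$gene), g)) {
      stop("contrast results are not on the same gene universe", call. = FALSE)
    }
  }
  invisible(TRUE)
}
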