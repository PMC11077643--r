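#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character gene vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields, got ", length(fields), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", fields[1],
              "' de-duplicated", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    descs[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (a `signature_set` works).
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts matrix and its sample table
#'
#' @param path Gene x sample TSV with a `gene` column.
#' @param samples_path Sample table TSV with columns `sample_id`,
#'   `treatment`, `timepoint_h`, `replicate`.
#' @return List with `counts` and `samples` tibbles.
#' @export
read_counts <- function(path, samples_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene" %in% names(counts)) stop("counts file lacks a 'gene' column",
                                       call. = FALSE)
  if (anyDuplicated(counts$gene)) {
    stop("duplicated gene id(s) in counts file: ",
         paste(utils::head(unique(counts$gene[duplicated(counts$gene)]), 5),
               collapse = ", "), call. = FALSE)
  }
  m <- counts[, -1, drop = FALSE]
  if (!all(vapply(m, is.numeric, logical(1)))) {
    stop("non-numeric count column(s)", call. = FALSE)
  }
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  need <- c("sample_id", "treatment", "timepoint_h", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(samples$sample_id, setdiff(names(counts), "gene"))) {
    stop("sample table does not match count matrix columns", call. = FALSE)
  }
  list(counts = counts, samples = samples)
}

#' Write a counts matrix and sample table as TSV
#'
#' @param sim A `sim_experiment` (or list with `counts` and `samples`).
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(sim, counts_path, samples_path) {
  readr::write_tsv(sim$counts, counts_path)
  readr::write_tsv(sim$samples, samples_path)
  invisible(c(counts_path, samples_path))
}

#' Read a labelled perturbation collection (long TSV)
#'
#' @param path TSV with columns `dataset_id`, `class`, `gene`, `log2fc`.
#' @return A `perturbation_collection` tibble.
#' @export
read_collection <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("dataset_id", "class", "gene", "log2fc")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("collection missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!x$class %in% c("FIN", "AIN"))
  if (length(bad)) {
    stop("invalid class '", x$class[bad[1]], "' at row ", bad[1],
         " (must be FIN or AIN)", call. = FALSE)
  }
  if (!is.numeric(x$log2fc)) stop("log2fc must be numeric", call. = FALSE)
  class(x) <- c("perturbation_collection", class(x))
  x
}

#' Write a perturbation collection as long TSV
#'
#' @param collection The collection tibble.
#' @param path Output path.
#' @export
write_collection <- function(collection, path) {
  readr::write_tsv(collection, path)
  invisible(path)
}

#' Read a survival cohort table
#'
#' @param path TSV with columns `patient_id`, `time`, `event`, `response`,
#'   then one column per gene.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$time < 0)) stop("negative survival times", call. = FALSE)
  if (!all(x$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  x
}

#' Write a cohort table as TSV
#'
#' @param cohort A `sim_cohort` or cohort tibble.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  if (inherits(cohort, "sim_cohort")) cohort <- cohort$data
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Extract the expression sub-table of a cohort as gene x patient
#'
#' @param cohort Cohort tibble (as from [read_cohort()] or
#'   `simulate_cohort()$data`).
#' @return Tibble with `gene` column then one column per patient, suitable
#'   for [score_collection()].
#' @export
cohort_expression <- function(cohort) {
  meta <- intersect(c("patient_id", "time", "event", "response"),
                    names(cohort))
  genes <- setdiff(names(cohort), meta)
  m <- t(as.matrix(cohort[, genes, drop = FALSE]))
  colnames(m) <- cohort$patient_id
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}

#' Write a reproducibility manifest
#'
#' Records the seed, parameters, package version and input checksums of a
#' run so deterministic stages can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used.
#' @param params Named list of parameters.
#' @param inputs Character vector of input file paths (checksummed if they
#'   exist).
#' @export
write_manifest <- function(path, seed, params = list(), inputs = character()) {
  checksums <- vapply(inputs, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "gradientsig",
    version = as.character(utils::packageVersion("gradientsig")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    params = params,
    inputs = as.list(checksums)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
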