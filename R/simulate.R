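#' Configuration for the synthetic dose-gradient experiment
#'
#' Builds the configuration object consumed by [simulate_dose_experiment()],
#' [simulate_perturbation_collection()] and [simulate_cohort()]. The defaults
#' emulate the structure of a drug dose-gradient RNA-seq experiment in which
#' two drugs are combined at a fixed dose of the first and increasing doses of
#' the second (combinations `JB2`, `JB3`, `JB6`), programming a transition
#' from ferroptotic to apoptotic cell death:
#'
#' * a large **shared** stress-response module, induced by all three
#'   combinations, so that the combinations share the large majority
#'   (roughly 80%) of their differentially expressed genes;
#' * a **ferro** module maximal under `JB2`, intermediate under `JB3` and
#'   absent under `JB6`;
#' * an **apopt** module with the mirrored dose profile;
#' * a **flip** module whose `JB2`-vs-`JB6` effect is negative at 6 h and
#'   positive (equal magnitude) at 24 h — the target of the gradient-derived
#'   biomarker selector;
#' * a **null** remainder with no planted effect.
#'
#' @param n_genes Total number of genes simulated.
#' @param module_sizes Named integer vector with elements `shared`, `ferro`,
#'   `apopt`, `flip`. The remainder of the genes form the null module. Sizes
#'   must sum to at most `n_genes`.
#' @param baseline_log2_range Range (log2 counts) from which per-gene baseline
#'   abundances are drawn uniformly.
#' @param dispersion Negative-binomial dispersion `phi` (> 0); the count
#'   variance is `mu + phi * mu^2`.
#' @param effect_size Named numeric vector of per-module log2 effect sizes
#'   (`shared`, `ferro`, `apopt`, `flip`).
#' @param dose_weights Data frame mapping each treatment to the fraction of
#'   each module's effect it receives (columns `treatment`, `shared`, `ferro`,
#'   `apopt`, `flip`, values in `[0, 1]`). Defaults to
#'   [default_dose_weights()].
#' @param n_replicates Replicates per treatment/timepoint combination.
#' @param timepoints Timepoints in hours.
#' @param lib_size_meanlog,lib_size_sdlog Log-normal parameters for library
#'   sizes (defaults centre libraries near 1e7 reads).
#' @param seed Integer seed; identical configurations give bit-identical data.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$module_sizes
sim_config <- function(n_genes = 6000,
                       module_sizes = c(shared = 1200, ferro = 150,
                                        apopt = 160, flip = 30),
                       baseline_log2_range = c(6, 12),
                       dispersion = 0.1,
                       effect_size = c(shared = 2.5, ferro = 4,
                                       apopt = 4, flip = 4),
                       dose_weights = default_dose_weights(),
                       n_replicates = 2,
                       timepoints = c(6, 24),
                       lib_size_meanlog = log(1e7),
                       lib_size_sdlog = 0.15,
                       seed = 1L) {
  mods <- c("shared", "ferro", "apopt", "flip")
  stopifnot(all(mods %in% names(module_sizes)),
            all(mods %in% names(effect_size)))
  module_sizes <- module_sizes[mods]
  if (sum(module_sizes) > n_genes) {
    stop("module sizes (", sum(module_sizes), ") exceed n_genes (",
         n_genes, ")", call. = FALSE)
  }
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  w <- as.matrix(dose_weights[, mods])
  if (any(w < 0 | w > 1)) {
    stop("dose weights must lie in [0, 1]", call. = FALSE)
  }
  # synergy: each combination must receive at least its singles' weight
  singles <- list(JB2 = c("J", "B2"), JB3 = c("J", "B3"), JB6 = c("J", "B6"))
  tr <- dose_weights$treatment
  for (combo in names(singles)) {
    if (!combo %in% tr) next
    sing <- singles[[combo]][singles[[combo]] %in% tr]
    if (!length(sing)) next
    wmax <- apply(dose_weights[match(sing, tr), mods, drop = FALSE], 2, max)
    if (any(dose_weights[match(combo, tr), mods] < wmax - 1e-12)) {
      stop("combination ", combo,
           " has a module weight below one of its single treatments",
           call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 module_sizes = module_sizes,
                 baseline_log2_range = baseline_log2_range,
                 dispersion = dispersion,
                 effect_size = effect_size,
                 dose_weights = tibble::as_tibble(dose_weights),
                 n_replicates = as.integer(n_replicates),
                 timepoints = timepoints,
                 lib_size_meanlog = lib_size_meanlog,
                 lib_size_sdlog = lib_size_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default treatment-to-module dose weights
#'
#' Fraction of each planted module's effect applied under each treatment.
#' The ferro module is maximal under `JB2` (weight 1), intermediate under
#' `JB3` (0.5) and absent under `JB6`; the apopt module is mirrored; the
#' shared stress module is fully induced by all three combinations; single
#' drugs receive weight 0.2 on the modules they touch. The flip module rides
#' the `JB2` arm (its sign is handled by the timepoint, see
#' [simulate_dose_experiment()]).
#'
#' @return A tibble with columns `treatment`, `shared`, `ferro`, `apopt`,
#'   `flip`.
#' @export
default_dose_weights <- function() {
  tibble::tribble(
    ~treatment, ~shared, ~ferro, ~apopt, ~flip,
    "DMSO",     0,       0,      0,      0,
    "J",        0.2,     0,      0,      0,
    "B2",       0.2,     0.2,    0,      0,
    "B3",       0.2,     0.1,    0.1,    0,
    "B6",       0.2,     0,      0.2,    0,
    "JB2",      1,       1,      0,      1,
    "JB3",      1,       0.5,    0.5,    0.5,
    "JB6",      1,       0,      1,      0
  )
}

#' Simulate a dose-gradient count experiment with planted modules
#'
#' Draws negative-binomial counts for every treatment/timepoint/replicate
#' combination in `config`. Counts are
#' `NB(mean = libfactor * 2^(baseline + effect), size = 1/phi)` where the
#' per-gene effect is the module effect size scaled by the treatment's dose
#' weight. The flip module's effect is negative at 6 h and positive with
#' equal magnitude at 24 h, so its `JB2`-vs-`JB6` contrast changes sign
#' between the timepoints; all other module effects are constant in time.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_experiment` with elements
#'   * `counts`: tibble, `gene` column then one integer column per sample;
#'   * `samples`: tibble with `sample_id`, `treatment`, `timepoint_h`,
#'     `replicate`, `lib_size`;
#'   * `truth`: list with `modules` (tibble `gene`, `module`), `effects`
#'     (tibble `module`, `treatment`, `timepoint_h`, `log2_effect`) and the
#'     `config`.
#' @export
#' @examples
#' sim <- simulate_dose_experiment(sim_config(n_genes = 300, seed = 7))
#' dim(sim$counts)
simulate_dose_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n_genes))
  sizes <- config$module_sizes
  module <- rep("null", n_genes)
  idx <- 0L
  for (m in names(sizes)) {
    if (sizes[[m]] > 0) module[idx + seq_len(sizes[[m]])] <- m
    idx <- idx + sizes[[m]]
  }
  baseline <- stats::runif(n_genes, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])

  samples <- tidyr::expand_grid(
    timepoint_h = config$timepoints,
    treatment = config$dose_weights$treatment,
    replicate = seq_len(config$n_replicates)
  )
  samples$sample_id <- sprintf("%s_%dh_r%d", samples$treatment,
                               samples$timepoint_h, samples$replicate)
  samples$lib_size <- stats::rlnorm(nrow(samples), config$lib_size_meanlog,
                                    config$lib_size_sdlog)
  lib_factor <- samples$lib_size / exp(config$lib_size_meanlog)

  # per-gene per-treatment effect, by module; flip flips sign with time
  w <- config$dose_weights
  eff_for <- function(treatment, timepoint) {
    row <- w[match(treatment, w$treatment), ]
    e <- numeric(n_genes)
    for (m in c("shared", "ferro", "apopt")) {
      e[module == m] <- config$effect_size[[m]] * row[[m]]
    }
    flip_sign <- if (timepoint == min(config$timepoints)) -1 else 1
    e[module == "flip"] <- flip_sign * config$effect_size[["flip"]] * row[["flip"]]
    e
  }

  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    eff <- eff_for(samples$treatment[j], samples$timepoint_h[j])
    mu <- lib_factor[j] * 2^(baseline + eff)
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / config$dispersion)
  }

  effects <- tidyr::expand_grid(module = c("shared", "ferro", "apopt", "flip", "null"),
                                treatment = w$treatment,
                                timepoint_h = config$timepoints)
  effects$log2_effect <- purrr::pmap_dbl(effects, function(module, treatment, timepoint_h) {
    if (module == "null") return(0)
    row <- w[match(treatment, w$treatment), ]
    s <- if (module == "flip" && timepoint_h == min(config$timepoints)) -1 else 1
    s * config$effect_size[[module]] * row[[module]]
  })

  structure(list(
    counts = dplyr::bind_cols(tibble::tibble(gene = genes),
                              tibble::as_tibble(counts)),
    samples = samples[, c("sample_id", "treatment", "timepoint_h",
                          "replicate", "lib_size")],
    truth = list(modules = tibble::tibble(gene = genes, module = module),
                 effects = effects,
                 config = config)
  ), class = "sim_experiment")
}

#' Simulate a labelled collection of perturbation fold-change profiles
#'
#' Emulates a panel of public perturbation datasets: each dataset is a
#' genome-wide log2 fold-change profile labelled as a ferroptosis inducer
#' (`FIN`) or apoptosis inducer (`AIN`). FIN profiles load on the planted
#' ferro, flip (late-timepoint direction) and shared modules, AIN profiles
#' on the apopt and shared modules;
#' each dataset gets a multiplicative scale, an additive offset and i.i.d.
#' Gaussian noise, emulating platform and potency differences between
#' studies.
#'
#' @param config A [sim_config()]; module effect sizes are reused as the
#'   class-specific loadings.
#' @param truth The `truth` element of a [simulate_dose_experiment()] result
#'   (defines the gene universe and module labels).
#' @param n_fin,n_ain Number of FIN and AIN datasets (defaults 19 and 26,
#'   the sizes of the emulated public panel).
#' @param scale_sdlog Log-normal sd of the per-dataset scale.
#' @param offset_sd Sd of the per-dataset additive offset.
#' @param noise_sd Sd of per-gene noise within a dataset.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble of class `perturbation_collection` in long form:
#'   `dataset_id`, `class` (`"FIN"`/`"AIN"`), `gene`, `log2fc`.
#' @export
simulate_perturbation_collection <- function(config, truth,
                                             n_fin = 19, n_ain = 26,
                                             scale_sdlog = 0.25,
                                             offset_sd = 0.2,
                                             noise_sd = 0.5,
                                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_fin + n_ain < 2) stop("need at least two datasets", call. = FALSE)
  set.seed(seed)
  genes <- truth$modules$gene
  module <- truth$modules$module
  n_genes <- length(genes)

  base_fin <- numeric(n_genes)
  base_fin[module == "ferro"] <- config$effect_size[["ferro"]]
  base_fin[module == "shared"] <- config$effect_size[["shared"]]
  # the flip module is part of the late ferroptosis response (positive at
  # the late timepoint), so FIN perturbation profiles carry it too
  base_fin[module == "flip"] <- config$effect_size[["flip"]]
  base_ain <- numeric(n_genes)
  base_ain[module == "apopt"] <- config$effect_size[["apopt"]]
  base_ain[module == "shared"] <- config$effect_size[["shared"]]

  ids <- c(sprintf("FIN%02d", seq_len(n_fin)), sprintf("AIN%02d", seq_len(n_ain)))
  classes <- rep(c("FIN", "AIN"), c(n_fin, n_ain))
  out <- purrr::map2(ids, classes, function(id, cl) {
    base <- if (cl == "FIN") base_fin else base_ain
    sc <- stats::rlnorm(1, 0, scale_sdlog)
    off <- stats::rnorm(1, 0, offset_sd)
    tibble::tibble(dataset_id = id, class = cl, gene = genes,
                   log2fc = base * sc + off + stats::rnorm(n_genes, 0, noise_sd))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("perturbation_collection", class(out))
  out
}

#' Simulate a survival cohort driven by a latent signature activity
#'
#' Each patient receives a standard-normal latent activity `a`. Expression of
#' the ferro-module genes (the analogue of the signature's "JB2 Up" subset in
#' a tumour cohort) is `baseline + beta * a + noise`; all other genes are
#' baseline plus noise. Event times are exponential with hazard
#' `lambda0 * exp(gamma * a)`; censoring is independent uniform on
#' `(0, c_max)` with `c_max` solved so the expected censored fraction is
#' `censor_frac`. An ordinal therapy response (`CR` < `PR` < `SD` < `PD`) is
#' derived by binning a noisy copy of the activity, so higher signature
#' activity tends toward progressive disease.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_dose_experiment()].
#' @param n_patients Cohort size (default 299, the emulated TNBC cohort).
#' @param gamma True log-hazard coefficient on the latent activity.
#' @param censor_frac Target fraction of censored patients in `[0, 1)`.
#' @param beta Expression loading of the latent activity.
#' @param noise_sd Residual expression noise sd.
#' @param lambda0 Baseline hazard (per month).
#' @param response_noise_sd Noise added to the activity before binning into
#'   response categories.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `sim_cohort`: `data` (tibble with `patient_id`,
#'   `time` in months, `event`, `response`, then one column per gene),
#'   `activity` (latent activity per patient) and `gamma`.
#' @export
simulate_cohort <- function(config, truth, n_patients = 299,
                            gamma = log(2), censor_frac = 0.3,
                            beta = 1, noise_sd = 1, lambda0 = 0.01,
                            response_noise_sd = 1,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(gamma)) stop("gamma must be finite", call. = FALSE)
  if (censor_frac < 0 || censor_frac >= 1) {
    stop("censor_frac must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  genes <- truth$modules$gene
  module <- truth$modules$module
  n_genes <- length(genes)
  a <- stats::rnorm(n_patients)

  baseline <- stats::runif(n_genes, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  loading <- ifelse(module == "ferro", beta, 0)
  expr <- outer(baseline, rep(1, n_patients)) + outer(loading, a) +
    matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd), n_genes)
  dimnames(expr) <- list(genes, sprintf("P%03d", seq_len(n_patients)))

  t_event <- stats::rexp(n_patients, rate = lambda0 * exp(gamma * a))
  if (censor_frac > 0) {
    # E[censored] given event times T: mean(min(T / c_max, 1)); monotone in c_max
    f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_frac
    cmax <- stats::uniroot(f, c(min(t_event) * 1e-6, max(t_event) * 1e6))$root
    cens <- stats::runif(n_patients, 0, cmax)
  } else {
    cens <- rep(Inf, n_patients)
  }
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  resp_latent <- a + stats::rnorm(n_patients, 0, response_noise_sd)
  qs <- stats::quantile(resp_latent, c(0.25, 0.5, 0.75))
  response <- cut(resp_latent, c(-Inf, qs, Inf),
                  labels = c("CR", "PR", "SD", "PD"))

  data <- dplyr::bind_cols(
    tibble::tibble(patient_id = colnames(expr), time = time,
                   event = event, response = as.character(response)),
    tibble::as_tibble(t(expr))
  )
  structure(list(data = data, activity = a, gamma = gamma),
            class = "sim_cohort")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Simulated dose-gradient experiment:",
      nrow(x$counts), "genes x", nrow(x$samples), "samples\n")
  cat("Module sizes:",
      paste(names(x$truth$config$module_sizes),
            x$truth$config$module_sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$data), "patients,",
      sum(x$data$event), "events; true log-hazard", signif(x$gamma, 3), "\n")
  invisible(x)
}
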