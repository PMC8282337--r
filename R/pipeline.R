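#' Pipeline run configuration
#'
#' Collects everything a reproducible run needs: which stages to execute,
#' acquisition constants, fit options and seeds. A configuration can also be
#' loaded from YAML with [read_run_config()]. With no input paths the
#' pipeline runs on synthetic data generated from the condition specs.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of `c("recoil", "linescan", "morphometry")`.
#' @param seed Integer master seed, recorded in every output.
#' @param tracks_csv Optional path to a vertex-track CSV per condition
#'   (named list/character vector); if `NULL`, tracks are simulated.
#' @param conditions For synthetic recoil runs: a named list of
#'   [ensemble_spec()] argument lists (the name is the condition label). The
#'   default mirrors a two-condition ablation experiment (n = 17 control
#'   vs n = 12 perturbed with halved recoil amplitude).
#' @param frame_interval Seconds between frames.
#' @param include_t0,L_ref Fit options passed to [kelvin_voigt()].
#' @param sd_denominator Heterogeneity s.d. denominator, `"n-1"` or `"n"`.
#' @param linescan_length Linescan length in micrometres (default 20).
#' @param n_embryos_per_condition Embryos per condition for the synthetic
#'   linescan stage.
#' @param punctateness Punctateness of the two linescan conditions
#'   (named numeric vector of length 2).
#' @param n_cohort_units Units per condition for the synthetic morphometry
#'   stage.
#' @param constriction_factor Programmed clone width effect.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("recoil", "linescan", "morphometry"),
                       seed = 1L, tracks_csv = NULL,
                       conditions = list(
                         control = list(n_replicates = 17L),
                         perturbed = list(
                           n_replicates = 12L, tau_mean = 12,
                           # amplitude chosen so the programmed mean initial
                           # velocity is 49% below control at tau = 12 s
                           D_mean = 0.51 * 1.2 * (1 - exp(-4 / 10)) / (1 - exp(-4 / 12))
                         )
                       ),
                       frame_interval = 4, include_t0 = FALSE,
                       L_ref = "last", sd_denominator = "n-1",
                       linescan_length = 20, n_embryos_per_condition = 7L,
                       punctateness = c(uniform = 0, punctate = 0.5),
                       n_cohort_units = 15L, constriction_factor = 0.6) {
  stages <- match.arg(stages, several.ok = TRUE)
  check_positive(frame_interval, "frame_interval")
  check_positive(linescan_length, "linescan_length")
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 tracks_csv = tracks_csv, conditions = conditions,
                 frame_interval = frame_interval, include_t0 = include_t0,
                 L_ref = L_ref, sd_denominator = sd_denominator,
                 linescan_length = linescan_length,
                 n_embryos_per_condition = n_embryos_per_condition,
                 punctateness = punctateness,
                 n_cohort_units = n_cohort_units,
                 constriction_factor = constriction_factor),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @param out_dir Output directory (overrides any `out_dir` key).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  args <- yaml::read_yaml(path)
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) stop("config must provide 'out_dir'", call. = FALSE)
  if (!is.null(args$punctateness)) args$punctateness <- unlist(args$punctateness)
  do.call(run_config, args)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages and writes per-stage CSV/JSON results plus a
#' `manifest.json` (configuration echo, seed, package version, per-stage
#' counts, warnings). Identical configuration and seed give identical numeric
#' outputs.
#'
#' Stages:
#' \describe{
#'   \item{recoil}{Per-condition vertex tracks (read from `tracks_csv` or
#'     simulated from `conditions`) are analysed into retraction velocities
#'     and Kelvin-Voigt fits (`recoil_results.csv`), and consecutive
#'     condition pairs are compared with percent change and Mann-Whitney U
#'     (`recoil_comparison.json`).}
#'   \item{linescan}{Synthetic epithelia per condition (uniform vs punctate
#'     junctions), per-embryo linescan summaries
#'     (`linescan_summary.csv`) and a Mann-Whitney comparison of
#'     heterogeneities (`linescan_comparison.json`).}
#'   \item{morphometry}{Synthetic clone cohorts, per-unit clone/control
#'     ratios (`morphometry_ratios.csv`) and their summary
#'     (`morphometry_summary.json`).}
#' }
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory results per stage and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("'config' must be a run_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = "recoilr-manifest-1",
                   package_version = as.character(utils::packageVersion("recoilr")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list(), warnings = character())
  results <- list()

  if ("recoil" %in% config$stages) {
    res <- pipeline_recoil_stage(config)
    results$recoil <- res
    utils::write.csv(cbind(schema = "recoilr-recoil-1", seed = config$seed,
                           res$table),
                     file.path(config$out_dir, "recoil_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(list(schema = "recoilr-comparison-1", seed = config$seed),
                           res$comparison),
                         file.path(config$out_dir, "recoil_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$recoil <- list(
      n_tracks = nrow(res$table),
      n_excluded = sum(!res$table$converged),
      conditions = as.list(table(res$table$condition)))
    if (any(!res$table$converged)) {
      manifest$warnings <- c(manifest$warnings, sprintf(
        "recoil: %d non-converged fit(s) excluded from tau summaries",
        sum(!res$table$converged)))
    }
  }

  if ("linescan" %in% config$stages) {
    res <- pipeline_linescan_stage(config)
    results$linescan <- res
    utils::write.csv(cbind(schema = "recoilr-linescan-1", seed = config$seed,
                           res$summary),
                     file.path(config$out_dir, "linescan_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(list(schema = "recoilr-comparison-1", seed = config$seed),
                           res$comparison),
                         file.path(config$out_dir, "linescan_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$linescan <- list(n_embryos = nrow(res$summary))
  }

  if ("morphometry" %in% config$stages) {
    res <- pipeline_morphometry_stage(config)
    results$morphometry <- res
    utils::write.csv(cbind(schema = "recoilr-morphometry-1", seed = config$seed,
                           res$ratios),
                     file.path(config$out_dir, "morphometry_ratios.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(list(schema = "recoilr-morphometry-1", seed = config$seed),
                           res$summary),
                         file.path(config$out_dir, "morphometry_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$morphometry <- list(n_units = nrow(res$ratios))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (w in manifest$warnings) message(w)
  invisible(c(results, list(manifest = manifest)))
}

pipeline_recoil_stage <- function(config) {
  cond_names <- if (!is.null(config$tracks_csv)) {
    names(config$tracks_csv) %||% paste0("condition", seq_along(config$tracks_csv))
  } else {
    names(config$conditions) %||% paste0("condition", seq_along(config$conditions))
  }
  tracks_by_cond <- if (!is.null(config$tracks_csv)) {
    lapply(config$tracks_csv, read_vertex_tracks)
  } else {
    lapply(seq_along(config$conditions), function(i) {
      args <- config$conditions[[i]]
      args$seed <- replicate_seed(config$seed, i * 1000L)
      args$frame_interval <- args$frame_interval %||% config$frame_interval
      simulate_condition_ensemble(do.call(ensemble_spec, args),
                                  id_prefix = paste0(cond_names[i], "_"))
    })
  }
  names(tracks_by_cond) <- cond_names[seq_along(tracks_by_cond)]
  tabs <- lapply(names(tracks_by_cond), function(cn) {
    tab <- analyze_tracks(tracks_by_cond[[cn]], L_ref = config$L_ref,
                          include_t0 = config$include_t0)
    cbind(condition = cn, tab)
  })
  table <- do.call(rbind, tabs)
  comparison <- NULL
  if (length(tabs) >= 2L) {
    v1 <- tabs[[1]]$velocity_um_s
    v2 <- tabs[[2]]$velocity_um_s
    cmp <- compare_groups(v1, v2, labels = names(tracks_by_cond)[1:2],
                          test = "mann-whitney")
    tau1 <- tabs[[1]]$tau_s[tabs[[1]]$converged]
    tau2 <- tabs[[2]]$tau_s[tabs[[2]]$converged]
    comparison <- list(
      labels = cmp$labels, velocity_means = cmp$means, velocity_sds = cmp$sds,
      ns = cmp$ns, velocity_percent_change = cmp$percent_change,
      mann_whitney_U = cmp$statistic, p_value = cmp$p_value, stars = cmp$stars,
      tau_mean = c(mean(tau1), mean(tau2)),
      tau_sd = c(sample_sd(tau1), sample_sd(tau2)),
      tau_sem = c(sample_sd(tau1) / sqrt(length(tau1)),
                  sample_sd(tau2) / sqrt(length(tau2))),
      tau_median = c(stats::median(tau1), stats::median(tau2)))
  }
  list(table = table, comparison = comparison, tracks = tracks_by_cond)
}

pipeline_linescan_stage <- function(config) {
  cond_names <- names(config$punctateness) %||%
    paste0("condition", seq_along(config$punctateness))
  summaries <- lapply(seq_along(config$punctateness), function(i) {
    profs <- lapply(seq_len(config$n_embryos_per_condition), function(e) {
      epi <- synth_epithelium_image(
        punctateness = config$punctateness[[i]],
        seed = replicate_seed(config$seed, i * 500L + e))
      img <- max_project(epi$stack)
      ends <- junction_linescan_endpoints(epi)
      extract_linescan(img, ends$p0, ends$p1, epi$stack$pixel_size)
    })
    cbind(condition = cond_names[i],
          condition_linescan_summary(profs, sd_denominator = config$sd_denominator))
  })
  summary <- do.call(rbind, summaries)
  h1 <- summaries[[1]]$heterogeneity
  h2 <- summaries[[2]]$heterogeneity
  cmp <- compare_groups(h1, h2, labels = cond_names[1:2], test = "mann-whitney")
  list(summary = summary,
       comparison = list(labels = cmp$labels, heterogeneity_means = cmp$means,
                         heterogeneity_sds = cmp$sds, ns = cmp$ns,
                         percent_change = cmp$percent_change,
                         mann_whitney_U = cmp$statistic, p_value = cmp$p_value,
                         stars = cmp$stars))
}

pipeline_morphometry_stage <- function(config) {
  sets <- lapply(seq_len(config$n_cohort_units), function(u) {
    synth_clone_widths(constriction_factor = config$constriction_factor,
                       unit_id = sprintf("unit%02d", u),
                       seed = replicate_seed(config$seed, 9000L + u))
  })
  ratios <- cohort_ratios(sets)
  s <- summarize_sample(ratios$ratio)
  list(ratios = ratios,
       summary = list(mean_ratio = s$mean, sd_ratio = s$sd, n_units = s$n,
                      programmed_constriction = config$constriction_factor))
}
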