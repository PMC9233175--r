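#' Run configuration for the CI analysis pipeline
#'
#' A run configuration is a plain nested list (serializable to YAML) that
#' makes every pipeline command reproducible from the config and seed alone.
#' Recognised blocks and their defaults:
#' * `seed` (1), `output_dir` (`"ci-run"`), `strict` (FALSE — abort when a
#'   fit fails convergence flags);
#' * `records`: path to an input record file, or `NULL` to simulate;
#' * `simulate`: `kind` (`"diallel"` or `"inheritance"`) plus any scalar
#'   arguments of [diallel_params()] / [inheritance_params()];
#' * `mcmc`: `chains` (2), `iterations` (5000), `warmup` (1000);
#' * `model`: `fixed` (`"inf*mgeno*fgeno"`), `day_intercepts` (TRUE);
#' * `diagnostics`: `rhat_max` (1.01), `ess_min` (400).
#'
#' @param path Path to a YAML config file.
#' @param overrides Named list merged over the file contents (e.g. from
#'   command-line flags).
#' @return The validated config list (class `"ci_run_config"`).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L, output_dir = "ci-run", strict = FALSE, records = NULL,
    simulate = list(kind = "diallel"),
    mcmc = list(chains = 2L, iterations = 5000L, warmup = 1000L),
    model = list(fixed = "inf*mgeno*fgeno", day_intercepts = TRUE),
    diagnostics = list(rhat_max = 1.01, ess_min = 400)
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  config <- modifyList(modifyList(defaults, from_file), overrides)
  if (!config$simulate$kind %in% c("diallel", "inheritance")) {
    abort("simulate$kind must be 'diallel' or 'inheritance'.")
  }
  structure(config, class = c("ci_run_config", "list"))
}

write_manifest <- function(config, out_dir, command, outputs) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("cibrood")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, paste0("manifest-", command, ".json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

config_sim_params <- function(config) {
  sim <- config$simulate
  args <- sim[setdiff(names(sim), "kind")]
  if (is.null(args$seed)) args$seed <- config$seed
  if (sim$kind == "diallel") {
    if (!is.null(args$genotypes)) args$genotypes <- unlist(args$genotypes)
    do.call(diallel_params, args)
  } else {
    do.call(inheritance_params, args)
  }
}

pipeline_records <- function(config) {
  if (!is.null(config$records)) {
    read_brood_records(config$records)
  } else {
    params <- config_sim_params(config)
    if (config$simulate$kind == "diallel") {
      simulate_diallel(params)
    } else {
      simulate_inheritance(params)
    }
  }
}

check_strict <- function(config, flagged, what) {
  if (isTRUE(config$strict) && flagged) {
    abort(paste0(
      "Convergence diagnostics failed for ", what,
      " and strict mode is on."
    ))
  }
}

#' Pipeline commands
#'
#' Thin orchestration layer over the package functions; each command writes
#' its outputs plus a manifest (config hash, seed, versions, timestamp) into
#' `config$output_dir` and returns its main result invisibly. In strict mode
#' a fit that fails the convergence flags aborts (the CLI maps this to a
#' nonzero exit status).
#'
#' * `pipeline_simulate()` — simulate records and write `records.csv`;
#' * `pipeline_fit()` — fit the three response models, write tidy posterior
#'   summaries and draw tables;
#' * `pipeline_indexes()` — corrected-index posteriors per cross pair;
#' * `pipeline_compare()` — WAIC comparison of the four fixed-effect
#'   variants plus finite-population SDs of the full model;
#' * `pipeline_mixture()` — ordered binomial mixture on incompatible F2
#'   broods (separately per maternal origin when annotated, plus pooled);
#' * `pipeline_all()` — simulate (or read), then indexes, comparison and,
#'   for inheritance data, the mixture.
#'
#' @param config A [read_run_config()] list.
#' @param records Optional records tibble (defaults to `config$records` or a
#'   fresh simulation).
#' @return See above; invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_sim_params(config)
  records <- if (config$simulate$kind == "diallel") {
    simulate_diallel(params)
  } else {
    simulate_inheritance(params)
  }
  path <- file.path(out_dir, "records.csv")
  write_brood_records(records, path)
  write_manifest(config, out_dir, "simulate", "records.csv")
  invisible(records)
}

#' @rdname pipeline
#' @export
pipeline_fit <- function(config, records = NULL) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- records %||% pipeline_records(config)
  fits <- purrr::map(c("F", "MD", "FM"), function(resp) {
    fit_ci_model(
      records,
      ci_model_spec(resp, config$model$fixed, config$model$day_intercepts),
      chains = config$mcmc$chains, iter = config$mcmc$iterations,
      warmup = config$mcmc$warmup, seed = config$seed
    )
  })
  names(fits) <- c("F", "MD", "FM")
  for (resp in names(fits)) {
    check_strict(config, fits[[resp]]$flagged, paste("response", resp))
    readr::write_csv(
      tidy(fits[[resp]]),
      file.path(out_dir, paste0("posterior-", resp, ".csv"))
    )
  }
  write_manifest(
    config, out_dir, "fit", paste0("posterior-", names(fits), ".csv")
  )
  invisible(fits)
}

#' @rdname pipeline
#' @export
pipeline_indexes <- function(config, records = NULL) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- records %||% pipeline_records(config)
  idx <- estimate_ci_indexes(
    records,
    fixed = config$model$fixed, day_intercepts = config$model$day_intercepts,
    chains = config$mcmc$chains, iter = config$mcmc$iterations,
    warmup = config$mcmc$warmup, seed = config$seed
  )
  readr::write_csv(idx$summary, file.path(out_dir, "index-summary.csv"))
  write_manifest(config, out_dir, "indexes", "index-summary.csv")
  invisible(idx)
}

#' @rdname pipeline
#' @export
pipeline_compare <- function(config, records = NULL) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- records %||% pipeline_records(config)
  comparison <- compare_ci_models(
    records, ci_model_variants("F", config$model$day_intercepts),
    chains = config$mcmc$chains, iter = config$mcmc$iterations,
    warmup = config$mcmc$warmup, seed = config$seed
  )
  readr::write_csv(as_tibble(comparison), file.path(out_dir, "waic.csv"))
  full_fit <- attr(comparison, "fits")[["inf*mgeno*fgeno"]]
  sds <- finite_population_sd(full_fit)
  readr::write_csv(sds$summary, file.path(out_dir, "group-sd.csv"))
  report <- c(
    paste0("Best model by WAIC: ", comparison$model[1]),
    paste0(
      "Finite-population SD ordering (posterior median, descending): ",
      paste(sds$summary$group, collapse = " > ")
    )
  )
  writeLines(report, file.path(out_dir, "selection-report.txt"))
  write_manifest(
    config, out_dir, "compare",
    c("waic.csv", "group-sd.csv", "selection-report.txt")
  )
  invisible(list(comparison = comparison, group_sd = sds))
}

#' @rdname pipeline
#' @export
pipeline_mixture <- function(config, records = NULL) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- records %||% pipeline_records(config)
  f2 <- records |> filter(.data$cross_class == "incompatible")
  if ("generation" %in% names(records)) {
    f2 <- f2 |> filter(.data$generation == "F2")
  }
  if (!nrow(f2)) abort("No incompatible F2 broods to fit the mixture to.")
  subsets <- list(pooled = f2)
  if ("maternal_origin" %in% names(f2)) {
    subsets <- c(subsets, split(f2, f2$maternal_origin))
  }
  results <- purrr::imap(subsets, function(broods, origin) {
    fit <- fit_binomial_mixture(
      broods,
      chains = config$mcmc$chains, iter = config$mcmc$iterations,
      warmup = config$mcmc$warmup, seed = config$seed
    )
    check_strict(config, fit$flagged, paste("mixture", origin))
    list(fit = fit, report = test_monogenic(fit))
  })
  summary <- purrr::imap(results, function(r, origin) {
    r$report$w_summary |>
      mutate(
        maternal_origin = origin,
        n_broods = nrow(r$fit$data),
        monogenic_supported = r$report$monogenic_supported,
        closest_k = r$report$closest_k,
        .before = 1
      )
  }) |>
    purrr::list_rbind()
  readr::write_csv(summary, file.path(out_dir, "mixture-summary.csv"))
  write_manifest(config, out_dir, "mixture", "mixture-summary.csv")
  invisible(results)
}

#' @rdname pipeline
#' @export
pipeline_all <- function(config) {
  records <- pipeline_simulate(config)
  out <- list(records = records)
  if (config$simulate$kind == "diallel" || !is.null(config$records)) {
    out$indexes <- pipeline_indexes(config, records)
    out$selection <- pipeline_compare(config, records)
  }
  if (config$simulate$kind == "inheritance") {
    out$indexes <- pipeline_indexes(config, records)
    out$mixture <- pipeline_mixture(config, records)
  }
  write_manifest(config, config$output_dir, "all", "see per-command manifests")
  invisible(out)
}
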