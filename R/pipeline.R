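#' Default pipeline configuration
#'
#' @param output_dir Directory for run artifacts.
#' @param trait_table_csv Optional path to an existing trait table; when
#'   `NULL` a synthetic panel is generated from
#'   [default_synthetic_spec()].
#' @param n_genotypes Synthetic panel size used when no input is given.
#' @param seed Integer seed governing every stochastic stage.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(output_dir, trait_table_csv = NULL,
                                    n_genotypes = 100L, seed = 1L) {
  list(output_dir = output_dir,
       trait_table_csv = trait_table_csv,
       directions_yaml = NULL,
       n_genotypes = as.integer(n_genotypes),
       clustering = list(cut_height = 0.12, linkage = "complete"),
       model = list(mode = "fixed_predictors",
                    predictors = c("SNC", "RNIL", "RWC", "RGR", "RKC",
                                   "Sen", "RNC")),
       core = list(fraction = 0.20, weights = c(0.5, 0.5),
                   replicas = 4L, patience = 500L),
       seed = as.integer(seed))
}

#' Run the salt-tolerance evaluation and core-selection pipeline
#'
#' Executes the full workflow on a trait table (loaded from CSV or
#' simulated): membership scoring, comprehensive D values, tolerance
#' classification, predictive-model fit, Gower-distance core selection and
#' core-representativeness validation. Writes all artifacts plus a manifest
#' of input/output checksums; a rerun with the same config and seed is
#' bit-identical.
#'
#' @param config List as produced by [default_pipeline_config()], or the
#'   path of a YAML file holding one.
#' @return The manifest, invisibly: list with `seed`, `package_version`,
#'   `inputs`, `artifacts` (name, path, md5), `n_genotypes`, `core_size`
#'   and aggregated `warnings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config(output_dir = config$output_dir %||% ".")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$output_dir)) stop("config error: output_dir is required")
  fr <- config$core$fraction
  if (!is.numeric(fr) || fr <= 0 || fr > 1)
    stop("config error: core fraction must lie in (0, 1]")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  warn <- character(0)
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  out_path <- function(f) file.path(config$output_dir, f)
  prov <- sprintf("salttol %s seed=%d",
                  as.character(utils::packageVersion("salttol")), seed)
  artifacts <- list()
  add_artifact <- function(name, path) {
    artifacts[[name]] <<- list(name = name, path = path,
                               md5 = unname(tools::md5sum(path)))
  }

  directions <- if (!is.null(config$directions_yaml))
    load_trait_directions(config$directions_yaml) else default_trait_directions()

  inputs <- list()
  if (!is.null(config$trait_table_csv)) {
    table <- load_trait_table(config$trait_table_csv, directions = directions)
    inputs$trait_table_csv <- list(path = config$trait_table_csv,
                                   md5 = unname(tools::md5sum(config$trait_table_csv)))
  } else {
    spec <- default_synthetic_spec(n_genotypes = config$n_genotypes)
    table <- catch_warn(simulate_trait_table(spec, seed = seed))
    attr(table, "directions") <- directions
    write_trait_table(table, out_path("trait_table.csv"), provenance = prov)
    add_artifact("trait_table", out_path("trait_table.csv"))
  }

  # scoring
  mfv <- catch_warn(membership_matrix(table))
  d <- comprehensive_d(mfv)
  mfv_df <- data.frame(genotype_id = table$genotype_id,
                       as.data.frame(mfv$F, check.names = FALSE),
                       check.names = FALSE)
  utils::write.csv(mfv_df, out_path("mfv.csv"), row.names = FALSE)
  add_artifact("mfv", out_path("mfv.csv"))
  utils::write.csv(data.frame(genotype_id = table$genotype_id, D = d),
                   out_path("d_values.csv"), row.names = FALSE)
  add_artifact("d_values", out_path("d_values.csv"))

  # classification
  names(d) <- table$genotype_id
  classes <- catch_warn(classify_tolerance(
    d, cut_height = config$clustering$cut_height,
    linkage = config$clustering$linkage))
  utils::write.csv(data.frame(genotype_id = names(classes$labels),
                              D = unname(d),
                              grade = as.character(classes$labels)),
                   out_path("classes.csv"), row.names = FALSE)
  add_artifact("classes", out_path("classes.csv"))

  # predictive model
  model <- catch_warn(fit_tolerance_model(
    table, d, mode = config$model$mode,
    predictors = config$model$predictors))
  write_tolerance_model(model, out_path("model.yaml"))
  add_artifact("model", out_path("model.yaml"))

  # core selection
  dist <- catch_warn(gower_matrix(table))
  core <- select_core(dist, fraction = fr,
                      weights = config$core$weights, seed = seed,
                      replicas = config$core$replicas,
                      patience = config$core$patience)
  writeLines(core$genotype_ids, out_path("core_ids.txt"))
  add_artifact("core_ids", out_path("core_ids.txt"))

  # validation
  core_table <- trait_table(
    as.data.frame(table)[core$selected, , drop = FALSE],
    directions = directions)
  report <- catch_warn(representativeness_metrics(table, core_table))
  utils::write.csv(report$per_trait, out_path("validation_report.csv"),
                   row.names = FALSE)
  add_artifact("validation_csv", out_path("validation_report.csv"))
  jsonlite::write_json(
    list(per_trait = report$per_trait, summary = report$summary,
         verdict = report$verdict,
         core = list(size = core$core_size, E_NE = core$E_NE,
                     A_NE = core$A_NE, combined = core$combined)),
    out_path("validation_report.json"), auto_unbox = TRUE, digits = NA)
  add_artifact("validation_json", out_path("validation_report.json"))

  manifest <- list(seed = seed,
                   package_version =
                     as.character(utils::packageVersion("salttol")),
                   inputs = inputs,
                   artifacts = unname(artifacts),
                   n_genotypes = nrow(table),
                   core_size = core$core_size,
                   warnings = warn)
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
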