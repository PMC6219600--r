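# End-to-end orchestration: filter -> specificity -> (homoeology ->
# analyzer selection) -> retention -> progenitor calls -> chromosome
# profiles -> clustering, with every table written to an output directory
# and a JSON run log.

#' Pipeline configuration
#'
#' Inputs may be given as file paths (`markers`, `snp`, `panel`) or as
#' in-memory objects (`marker_matrix`, `snp_matrix`, `sample_panel`).
#'
#' @param markers SilicoDArT CSV path or a `marker_matrix`.
#' @param snp SNP CSV path or a `snp_matrix`; optional (`NULL` skips the
#'   clustering stage).
#' @param panel panel CSV path or a [sample_panel()].
#' @param out_dir output directory.
#' @param silico_call_rate call-rate threshold for presence/absence
#'   markers (strict `>`), default 0.7.
#' @param snp_call_rate call-rate threshold for SNPs, default 0.9.
#' @param homoeology_percent analyzer-selection threshold, default 10.
#' @param margin progenitor-call retention margin, default 0.10.
#' @param n_min minimum markers per chromosome bucket, default 20.
#' @param reference_species optional reference species for the homoeology
#'   screen; when `NULL`, all diploid analyzers are used directly.
#' @param missing_policy missing-call policy for absence judgements.
#' @param seed recorded in the run log (the pipeline itself draws no
#'   random numbers).
#' @return a `run_config` list.
#' @export
run_config <- function(markers, panel, snp = NULL, out_dir = "dartpoly_out",
                       silico_call_rate = 0.7, snp_call_rate = 0.9,
                       homoeology_percent = 10, margin = 0.10, n_min = 20,
                       reference_species = NULL, missing_policy = "lenient",
                       seed = NULL) {
  stopifnot(silico_call_rate >= 0, silico_call_rate <= 1,
            snp_call_rate >= 0, snp_call_rate <= 1,
            homoeology_percent > 0, margin >= 0, n_min >= 1)
  structure(list(markers = markers, snp = snp, panel = panel,
                 out_dir = out_dir, silico_call_rate = silico_call_rate,
                 snp_call_rate = snp_call_rate,
                 homoeology_percent = homoeology_percent, margin = margin,
                 n_min = n_min, reference_species = reference_species,
                 missing_policy = missing_policy, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_ctx("the yaml package is required to read YAML configs")
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_ctx("pipeline stage \"%s\" failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes call-rate filtering, diploid and polyploid specificity
#' reports, the homoeology screen and analyzer selection (when a reference
#' species is configured; otherwise every diploid analyzer is used),
#' retention scoring, progenitor calls, per-chromosome profiles for the
#' resolved calls, and UPGMA clustering of the diploid and polyploid
#' panels on the SNP correlation distance. All tables are written under
#' `config$out_dir`, together with `run_log.json` recording versions, seed
#' and thresholds. Any stage error aborts with the stage name; the log is
#' then marked failed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate result (`markers`,
#'   `snp`, `panel`, `diploid_specificity`, `polyploid_specificity`,
#'   `homoeology`, `analyzers`, `retention`, `calls`, `profiles`, `trees`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = "dartpoly",
              version = as.character(packageVersion("dartpoly")),
              seed = config$seed,
              thresholds = config[c("silico_call_rate", "snp_call_rate",
                                    "homoeology_percent", "margin", "n_min")],
              missing_policy = config$missing_policy,
              status = "failed")
  log_path <- file.path(config$out_dir, "run_log.json")
  on.exit(jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                               null = "null"))
  panel <- stage("panel", if (inherits(config$panel, "sample_panel"))
    config$panel else read_panel(config$panel))
  mm <- stage("read_markers", if (inherits(config$markers, "marker_matrix"))
    config$markers else read_silicodart(config$markers, panel))
  sm <- stage("read_snp", if (is.null(config$snp) ||
                              inherits(config$snp, "snp_matrix"))
    config$snp else read_snp(config$snp, panel))
  mm <- stage("filter_markers", filter_call_rate(mm, config$silico_call_rate))
  if (!is.null(sm)) sm <- stage("filter_snp",
                                filter_call_rate(sm, config$snp_call_rate))
  pol <- check_policy(config$missing_policy)

  diploids <- panel_species(panel[panel$ploidy == 2L, , drop = FALSE])
  targets <- panel_species(panel[panel$ploidy > 2L &
                                   panel$role != "reference", , drop = FALSE])
  if (length(diploids) < 2L) stop_ctx("pipeline needs >= 2 diploid species")

  dip_rep <- stage("diploid_specificity",
                   specificity_report(mm, diploids, missing_policy = pol))
  write_specificity_report(dip_rep,
                           file.path(config$out_dir, "diploid_specificity.csv"),
                           ids_dir = file.path(config$out_dir, "specific_markers"))

  pol_rep <- NULL
  if (length(targets) >= 2L) {
    pol_rep <- stage("polyploid_specificity",
                     polyploid_specific_markers(mm, targets,
                                                missing_policy = pol))
    write_specificity_report(pol_rep,
                             file.path(config$out_dir, "polyploid_specificity.csv"))
  }

  ht <- NULL
  analyzers <- diploids
  if (!is.null(config$reference_species)) {
    ht <- stage("homoeology",
                homoeology_table(mm, setdiff(diploids, config$reference_species),
                                 config$reference_species, missing_policy = pol))
    write.csv(as.data.frame(ht), file.path(config$out_dir, "homoeology.csv"),
              row.names = FALSE)
    sel <- stage("select_analyzers",
                 select_analyzers(ht, config$homoeology_percent))
    analyzers <- sel$union
    log$analyzers <- analyzers
  }

  rt <- NULL; calls <- list(); profiles <- NULL
  if (length(targets)) {
    rt <- stage("retention",
                retention_table(mm, analyzers, targets, missing_policy = pol))
    write.csv(data.frame(analyzer = rownames(rt),
                         unclass(rt)[, , drop = FALSE], check.names = FALSE),
              file.path(config$out_dir, "retention.csv"), row.names = FALSE)
    calls <- stage("call_progenitors",
                   lapply(setNames(targets, targets), function(t)
                     call_progenitors(rt, panel, t, margin = config$margin)))
    jsonlite::write_json(
      lapply(calls, function(cl)
        list(target = cl$target, ploidy = cl$ploidy, margin = cl$margin,
             ranking = as.list(cl$ranking), slots = cl$slots)),
      file.path(config$out_dir, "progenitor_calls.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    profiles <- stage("chromosome_profiles", {
      rows <- list()
      letters_present <- setdiff(unique(subgenome_of(mm$markers$chromosome)),
                                 NA_character_)
      for (t in targets) for (a in resolved_progenitors(calls[[t]])) {
        set <- select_species_specific(mm, a, setdiff(analyzers, a),
                                       missing_policy = pol)
        for (g in letters_present) {
          pr <- tryCatch(chromosome_profile(mm, set, t, g,
                                            n_min = config$n_min,
                                            missing_policy = pol),
                         error = function(e) NULL)
          if (!is.null(pr)) {
            pr$analyzer <- a; pr$target <- t
            rows[[length(rows) + 1L]] <- as.data.frame(pr)
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(profiles))
      write.csv(profiles, file.path(config$out_dir, "chromosome_profiles.csv"),
                row.names = FALSE)
  }

  trees <- list()
  if (!is.null(sm)) {
    trees <- stage("clustering", {
      out <- list()
      for (set in list(list(name = "diploid", species = diploids),
                       list(name = "polyploid", species = targets))) {
        ids <- panel$sample_id[panel$species %in% set$species]
        if (length(ids) >= 3L) {
          dm <- correlation_distance(sm, ids)
          tr <- upgma(dm)
          write_distance_csv(dm, file.path(config$out_dir,
                                           paste0(set$name, "_distance.csv")))
          write_newick(tr, file.path(config$out_dir,
                                     paste0(set$name, "_upgma.nwk")))
          out[[set$name]] <- list(distance = dm, tree = tr)
        }
      }
      out
    })
  }
  log$status <- "ok"
  invisible(list(markers = mm, snp = sm, panel = panel,
                 diploid_specificity = dip_rep,
                 polyploid_specificity = pol_rep, homoeology = ht,
                 analyzers = analyzers, retention = rt, calls = calls,
                 profiles = profiles, trees = trees, log = log))
}
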