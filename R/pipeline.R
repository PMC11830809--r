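# Orchestration: one reactor bundle -> trace summary + electron budget + HER
# verdict; a dataset -> per-reactor report, activity scores, and normalized
# community tables. File-based entry points (run_analyze / run_simulate) wrap
# the in-memory path for shell use.

#' Pipeline options with documented defaults
#'
#' @param thio_tolerance relative tolerance on the 1:2 thiosulfate:sulfate
#'   stoichiometry (default 0.5).
#' @param overpotential_V HER kinetic overpotential in V (default 0.2).
#' @param target_depth,min_depth amplicon depth normalization (default
#'   100000 reads each).
#' @param depth_method `"proportional"` or `"subsample"`.
#' @param subsample_seed seed for `"subsample"` mode.
#' @param aggregation_rank taxonomic rank for the community table.
#' @param min_percent legend threshold in percent for taxon pooling.
#' @return Named list of options.
#' @export
pipeline_options <- function(thio_tolerance = 0.5, overpotential_V = 0.2,
                             target_depth = 1e5, min_depth = target_depth,
                             depth_method = "proportional",
                             subsample_seed = NULL,
                             aggregation_rank = "class", min_percent = 1) {
  stopifnot(thio_tolerance >= 0, overpotential_V >= 0, target_depth > 0,
            min_depth >= 0, min_percent >= 0)
  list(thio_tolerance = thio_tolerance, overpotential_V = overpotential_V,
       target_depth = target_depth, min_depth = min_depth,
       depth_method = depth_method, subsample_seed = subsample_seed,
       aggregation_rank = aggregation_rank, min_percent = min_percent)
}

#' Analyze one reactor bundle
#'
#' Runs the full per-reactor chain: trace statistics, metabolite deltas,
#' donor coulombs (formate, thiosulfate with stoichiometric check, yeast
#' extract via COD bookkeeping), the multi-donor electron budget with
#' coulombic efficiencies and classification, and the HER feasibility
#' verdict.
#'
#' @param bundle list with `record` ([reactor_record()]), `trace`
#'   ([current_trace()]), `metabolites` (named list of
#'   [metabolite_series()]), and optionally `cod`, `qpcr`, `biofilm`.
#' @param registry compound registry.
#' @param options [pipeline_options()].
#' @return List with `summary` (one-row tibble) and `budget`
#'   (the `electron_budget`).
#' @export
analyze_reactor <- function(bundle, registry = compound_registry(),
                            options = pipeline_options()) {
  rec <- bundle$record
  V <- rec$catholyte_volume_L
  ts <- trace_summary(bundle$trace)
  deltas <- vapply(bundle$metabolites, series_delta_mM, numeric(1))
  names(deltas) <- vapply(bundle$metabolites, `[[`, character(1),
                          "compound_name")

  # product side: registered organics with net production
  organics <- registry$name[registry$role %in% c("product", "both")]
  prod_names <- intersect(names(deltas)[deltas > 0], organics)
  prod_deltas <- deltas[prod_names]
  prod_ne <- vapply(prod_names, compound_ne, numeric(1), registry = registry)

  # donor side
  q_formate <- if ("formic acid" %in% names(deltas))
    formate_coulombs(deltas[["formic acid"]], V) else 0
  thio <- list(is_donor = FALSE, q_thiosulfate_C = 0)
  if (all(c("thiosulfate", "sulfate") %in% names(deltas)))
    thio <- thiosulfate_donor_check(deltas[["thiosulfate"]],
                                    deltas[["sulfate"]], V,
                                    options$thio_tolerance)
  carbon_fixation <- FALSE
  q_ye <- 0
  if (!is.null(bundle$cod)) {
    prod_cod <- organic_acid_cod_correction(prod_deltas, prod_ne, V)
    ye <- yeast_extract_coulombs(bundle$cod, prod_cod, V)
    q_ye <- ye$coulombs_C
    carbon_fixation <- ye$carbon_fixation_flag
  } else {
    q_ye <- NA_real_
  }

  budget <- build_donor_budget(
    q_cathode_C = ts$total_coulombs_C,
    product_deltas_mM = prod_deltas, product_ne = prod_ne, volume_L = V,
    q_formate_C = q_formate, q_thiosulfate_C = thio$q_thiosulfate_C,
    q_yeast_extract_C = q_ye, carbon_fixation_flag = carbon_fixation)
  her <- her_verdict(rec, options$overpotential_V)

  summary <- dplyr::bind_cols(
    tibble::tibble(reactor_id = rec$reactor_id, inoculum = rec$inoculum,
                   temperature_C = rec$temperature_C, ph = rec$ph,
                   electron_acceptor = rec$electron_acceptor),
    ts[, -1],
    tibble::tibble(
      q_cathode_C = budget$q_cathode_C,
      q_formate_C = budget$q_formate_C,
      q_thiosulfate_C = budget$q_thiosulfate_C,
      thiosulfate_is_donor = thio$is_donor,
      q_yeast_extract_C = budget$q_yeast_extract_C,
      q_products_C = budget$q_products_C,
      ce_total_percent = budget$ce_total_percent,
      ce_over_100 = budget$ce_over_100,
      carbon_fixation_flag = budget$carbon_fixation_flag,
      classification = budget$classification,
      organic_acids_mM = sum(prod_deltas),
      e_her_V = her$e_her_V, her_feasible = her$her_feasible,
      bacterial_copies_per_cm2 = bundle$qpcr$bacterial_copies_per_cm2 %||% NA_real_,
      archaeal_copies_per_cm2 = bundle$qpcr$archaeal_copies_per_cm2 %||% NA_real_,
      biofilm = bundle$biofilm$score %||% NA_integer_,
      error = NA_character_))
  list(summary = summary, budget = budget)
}

failed_reactor_row <- function(id, msg) {
  tibble::tibble(reactor_id = id, error = conditionMessage(msg))
}

#' Analyze a full dataset
#'
#' Per-reactor analysis (a failing reactor is reported with its error and
#' does not abort the others), cumulative activity scores across reactors,
#' and the community tables: depth normalization with exclusions, rank
#' aggregation with the legend filter, and qPCR bacteria/archaea projection.
#'
#' @param dataset list with `reactors` (named bundles, see
#'   [analyze_reactor()]) and optional `amplicon` (an [amplicon_table()]
#'   whose samples are reactor ids).
#' @param registry compound registry.
#' @param options [pipeline_options()].
#' @return List: `summary` (tibble, one row per reactor), `activity`,
#'   `budgets`, `community` (`displayed` long tibble + `exclusions`).
#' @export
analyze_dataset <- function(dataset, registry = compound_registry(),
                            options = pipeline_options()) {
  results <- lapply(names(dataset$reactors), function(id) {
    tryCatch(analyze_reactor(dataset$reactors[[id]], registry, options),
             error = function(e) list(summary = failed_reactor_row(id, e),
                                      budget = NULL))
  })
  names(results) <- names(dataset$reactors)
  summary <- dplyr::bind_rows(lapply(results, `[[`, "summary"))

  activity <- NULL
  ok <- is.na(summary$error)
  if (any(ok)) {
    ind <- tibble::tibble(
      reactor_id = summary$reactor_id[ok],
      biofilm = ifelse(is.na(summary$biofilm[ok]), 0L, summary$biofilm[ok]),
      bacterial_qpcr = ifelse(is.na(summary$bacterial_copies_per_cm2[ok]), 0,
                              summary$bacterial_copies_per_cm2[ok]),
      archaeal_qpcr = ifelse(is.na(summary$archaeal_copies_per_cm2[ok]), 0,
                             summary$archaeal_copies_per_cm2[ok]),
      organic_acids = summary$organic_acids_mM[ok],
      biocoulombs = summary$biocoulombs_C[ok])
    activity <- activity_scores(ind)
  }

  community <- NULL
  if (!is.null(dataset$amplicon)) {
    norm <- depth_normalize(dataset$amplicon, options$target_depth,
                            options$min_depth, options$depth_method,
                            options$subsample_seed)
    displayed <- NULL
    if (ncol(norm$table$counts)) {
      agg <- aggregate_taxa(norm$table, options$aggregation_rank,
                            options$min_percent)
      samples <- setdiff(names(agg), "taxon")
      rows <- lapply(samples, function(s) {
        rel <- agg[[s]] / sum(agg[[s]]) * 100
        names(rel) <- agg$taxon
        b <- dataset$reactors[[s]]
        if (is.null(b$qpcr)) {
          return(tibble::tibble(sample_id = s, taxon = names(rel),
                                displayed_percent = rel,
                                qpcr_projected = FALSE))
        }
        proj <- qpcr_domain_normalize(rel, b$qpcr)
        if (proj$excluded)
          return(tibble::tibble(sample_id = s, taxon = names(rel),
                                displayed_percent = rel,
                                qpcr_projected = FALSE))
        tibble::tibble(
          sample_id = s,
          taxon = c(names(proj$displayed_percent), "Archaea (qPCR)"),
          displayed_percent = c(unname(proj$displayed_percent),
                                proj$archaeal_block_percent),
          qpcr_projected = TRUE)
      })
      displayed <- dplyr::bind_rows(rows)
    }
    community <- list(displayed = displayed %||%
                        tibble::tibble(sample_id = character(),
                                       taxon = character(),
                                       displayed_percent = numeric(),
                                       qpcr_projected = logical()),
                      exclusions = norm$exclusions)
  }

  list(summary = summary, activity = activity,
       budgets = lapply(results, `[[`, "budget"), community = community)
}

#' Run the analysis pipeline from a configuration file
#'
#' Reads the YAML configuration, loads every bound file, analyzes all
#' reactors (per-reactor errors are recorded in the summary's `error`
#' column without aborting the run), and optionally writes the report.
#' Deterministic given identical inputs and options.
#'
#' @param config_path YAML configuration (see [read_reactor_config()]).
#' @param out_dir optional report directory for [write_report()].
#' @param options [pipeline_options()].
#' @return The [analyze_dataset()] report, invisibly when `out_dir` is set.
#' @export
run_analyze <- function(config_path, out_dir = NULL,
                        options = pipeline_options()) {
  cfg <- read_reactor_config(config_path)
  bundles <- lapply(names(cfg$records), function(id) {
    rec <- cfg$records[[id]]
    d <- cfg$data[[id]]
    b <- list(record = rec)
    if (!is.null(d$trace))
      b$trace <- read_trace(d$trace, rec$cathode_area_cm2,
                            reactor_id = id)
    b$metabolites <- if (!is.null(d$metabolites))
      read_metabolites(d$metabolites, reactor_id = id) else list()
    if (!is.null(d$cod_initial) && !is.null(d$cod_final))
      b$cod <- cod_measurement(id, d$cod_initial, d$cod_final)
    if (!is.null(d$qpcr_bacterial) && !is.null(d$qpcr_archaeal))
      b$qpcr <- qpcr_result(id, d$qpcr_bacterial, d$qpcr_archaeal)
    if (!is.null(d$biofilm)) b$biofilm <- biofilm_score(id, d$biofilm)
    b
  })
  names(bundles) <- names(cfg$records)
  amplicon <- NULL
  if (!is.null(cfg$amplicon))
    amplicon <- read_amplicon(cfg$amplicon$counts, cfg$amplicon$taxonomy)
  report <- analyze_dataset(list(reactors = bundles, amplicon = amplicon),
                            options = options)
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}

#' Generate and write a synthetic experiment
#'
#' @param out_dir output directory.
#' @param master_seed integer master seed.
#' @param scenarios preset labels or [scenario()] list.
#' @param noise_scale noise multiplier for presets (0 = noiseless).
#' @return Invisibly, the written config path.
#' @export
run_simulate <- function(out_dir, master_seed = 1L,
                         scenarios = SCENARIO_LABELS, noise_scale = 1) {
  dataset <- generate_experiment(scenarios, master_seed, noise_scale)
  write_experiment(dataset, out_dir)
}
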