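# File boundary: delimited text in (comma or tab, auto-detected from the
# extension), YAML run configuration, JSON + TSV reports out. All unit
# conversion to SI happens here; the rest of the package never sees hours,
# days, or mA.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_auto <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}

TIME_UNIT_S <- c(s = 1, min = 60, h = 3600, d = 86400)
CURRENT_UNIT_A <- c(A = 1, mA = 1e-3, uA = 1e-6)

#' Read a chronoamperometry trace file
#'
#' Delimited text (comma for `.csv`, tab otherwise) with a header and columns
#' `time` and `current` (any further columns are ignored). Units are declared
#' by the caller, not guessed; rows must be strictly increasing in time
#' (duplicate timestamps are rejected, naming the first offending row).
#'
#' @param path file path.
#' @param area_cm2 cathode geometric area in cm2.
#' @param polarity `"cathodic_negative"` or `"magnitude"`.
#' @param reactor_id label; defaults to the file name.
#' @param time_unit one of `r paste(names(TIME_UNIT_S), collapse = ", ")`.
#' @param current_unit one of `r paste(names(CURRENT_UNIT_A), collapse = ", ")`.
#' @return A [current_trace()] in s and A.
#' @export
read_trace <- function(path, area_cm2,
                       polarity = c("cathodic_negative", "magnitude"),
                       reactor_id = sub("\\.[^.]*$", "", basename(path)),
                       time_unit = "s", current_unit = "A") {
  polarity <- match.arg(polarity)
  time_unit <- match.arg(time_unit, names(TIME_UNIT_S))
  current_unit <- match.arg(current_unit, names(CURRENT_UNIT_A))
  tab <- read_delim_auto(path)
  if (!all(c("time", "current") %in% names(tab)))
    stop(sprintf("'%s' must have columns 'time' and 'current'", path),
         call. = FALSE)
  tt <- tab$time * TIME_UNIT_S[[time_unit]]
  bad <- which(diff(tt) <= 0)
  if (length(bad))
    stop(sprintf("time not increasing in '%s' at row %d", path, bad[1] + 1L),
         call. = FALSE)
  current_trace(reactor_id, tt, tab$current * CURRENT_UNIT_A[[current_unit]],
                area_cm2, polarity)
}

#' Read a metabolite concentration table
#'
#' Long-format delimited file with columns `compound`, `time_s`,
#' `concentration_mM` (one HPLC/IC export per reactor).
#'
#' @param path file path.
#' @param reactor_id label; defaults to the file name.
#' @return Named list of [metabolite_series()], one per compound.
#' @export
read_metabolites <- function(path,
                             reactor_id = sub("\\.[^.]*$", "",
                                              basename(path))) {
  tab <- read_delim_auto(path)
  need <- c("compound", "time_s", "concentration_mM")
  if (!all(need %in% names(tab)))
    stop(sprintf("'%s' must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  out <- lapply(split(tab, tab$compound), function(d) {
    d <- d[order(d$time_s), ]
    metabolite_series(reactor_id, d$compound[1], d$time_s, d$concentration_mM)
  })
  out[unique(tab$compound)]
}

#' Read an amplicon count table and its taxonomy
#'
#' `counts_path`: delimited, column `asv_id` plus one integer column per
#' sample. `taxonomy_path`: delimited with `asv_id` and the six rank columns.
#'
#' @param counts_path,taxonomy_path file paths.
#' @return An [amplicon_table()].
#' @export
read_amplicon <- function(counts_path, taxonomy_path) {
  counts <- read_delim_auto(counts_path)
  taxonomy <- read_delim_auto(taxonomy_path)
  m <- as.matrix(counts[, setdiff(names(counts), "asv_id")])
  rownames(m) <- counts$asv_id
  amplicon_table(m, taxonomy)
}

#' Read a reactor run configuration
#'
#' YAML file with a `reactors` list (one mapping per reactor: the
#' [reactor_record()] fields plus per-reactor data: `trace`/`metabolites`
#' file paths and inline `qpcr_bacterial`, `qpcr_archaeal`, `biofilm`,
#' `cod_initial`, `cod_final`), optional top-level `defaults` (merged into
#' every reactor) and `amplicon` (`counts`/`taxonomy` paths). Relative paths
#' are resolved against the config file's directory. Omitted record fields
#' take the package defaults (0.25 L, 6 days, 2.25 cm2, -0.6 V vs SHE);
#' unknown electron-acceptor tokens are rejected listing the allowed values.
#'
#' @param path YAML file.
#' @return List with `records` (named list of [reactor_record()]), `data`
#'   (named list of per-reactor file bindings and inline measurements), and
#'   `amplicon` (paths or `NULL`).
#' @export
read_reactor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reactors) || !length(cfg$reactors))
    stop("config must list at least one reactor", call. = FALSE)
  root <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    ifelse(grepl("^/", p), p, file.path(root, p))
  defaults <- cfg$defaults %||% list()
  records <- list()
  data <- list()
  for (r in cfg$reactors) {
    r <- utils::modifyList(defaults, r)
    rec <- reactor_record(
      reactor_id = r$reactor_id,
      inoculum = r$inoculum,
      temperature_C = r$temperature_C,
      ph = r$ph,
      electron_acceptor = r$electron_acceptor,
      catholyte_volume_L = r$catholyte_volume_L %||% 0.25,
      duration_s = r$duration_s %||% (6 * 86400),
      cathode_area_cm2 = r$cathode_area_cm2 %||% 2.25,
      cathode_potential_V_SHE = r$cathode_potential_V_SHE %||% -0.6)
    records[[rec$reactor_id]] <- rec
    data[[rec$reactor_id]] <- list(
      trace = resolve(r$trace), metabolites = resolve(r$metabolites),
      qpcr_bacterial = r$qpcr_bacterial, qpcr_archaeal = r$qpcr_archaeal,
      biofilm = r$biofilm,
      cod_initial = r$cod_initial, cod_final = r$cod_final)
  }
  amplicon <- NULL
  if (!is.null(cfg$amplicon))
    amplicon <- list(counts = resolve(cfg$amplicon$counts),
                     taxonomy = resolve(cfg$amplicon$taxonomy))
  list(records = records, data = data, amplicon = amplicon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-reactor analysis report
#'
#' Emits a machine-readable summary (`summary.tsv` and `summary.json`) plus
#' the activity-score table, the normalized community long table, and the
#' depth-exclusion list. Tables round-trip: re-reading `summary.tsv`
#' reproduces the in-memory values at full precision.
#'
#' @param report output of [analyze_dataset()] or [run_analyze()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0)
    stop(sprintf("cannot write to '%s'", dir), call. = FALSE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p)
    paths <<- c(paths, p)
  }
  wr(report$summary, "summary.tsv")
  if (!is.null(report$activity)) wr(report$activity, "activity.tsv")
  if (!is.null(report$community)) {
    wr(report$community$displayed, "community.tsv")
    wr(report$community$exclusions, "community_exclusions.tsv")
  }
  pj <- file.path(dir, "summary.json")
  jsonlite::write_json(report$summary, pj, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, pj))
}

#' Read back a written summary table
#' @param dir report directory.
#' @return The summary tibble.
#' @export
read_report_summary <- function(dir) {
  readr::read_tsv(file.path(dir, "summary.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a synthetic experiment to pipeline input files
#'
#' Emits, under `dir`: `traces/<id>.csv` (time_s, current_A),
#' `metabolites/<id>.tsv` (compound, time_s, concentration_mM), a joint
#' `amplicon_counts.tsv` + `taxonomy.tsv`, the ground-truth `truth.tsv`, and
#' a `config.yaml` binding everything, loadable by [run_analyze()] without
#' edits.
#'
#' @param dataset output of [generate_experiment()].
#' @param dir output directory.
#' @return Invisibly, the config path.
#' @export
write_experiment <- function(dataset, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "metabolites"), showWarnings = FALSE)
  reactors_cfg <- list()
  for (id in names(dataset$reactors)) {
    b <- dataset$reactors[[id]]
    readr::write_csv(
      tibble::tibble(time = b$trace$time_s, current = b$trace$current_A),
      file.path(dir, "traces", paste0(id, ".csv")))
    schema <- tibble::tibble(compound = character(), time_s = numeric(),
                             concentration_mM = numeric())
    long <- dplyr::bind_rows(c(list(schema), unname(
      lapply(b$metabolites, function(s)
        tibble::tibble(compound = s$compound_name, time_s = s$timepoints_s,
                       concentration_mM = s$concentrations_mM)))))
    readr::write_tsv(long, file.path(dir, "metabolites", paste0(id, ".tsv")))
    rec <- b$record
    reactors_cfg[[length(reactors_cfg) + 1]] <- list(
      reactor_id = id, inoculum = rec$inoculum,
      temperature_C = rec$temperature_C, ph = rec$ph,
      electron_acceptor = rec$electron_acceptor,
      catholyte_volume_L = rec$catholyte_volume_L,
      duration_s = rec$duration_s,
      cathode_area_cm2 = rec$cathode_area_cm2,
      cathode_potential_V_SHE = rec$cathode_potential_V_SHE,
      trace = file.path("traces", paste0(id, ".csv")),
      metabolites = file.path("metabolites", paste0(id, ".tsv")),
      qpcr_bacterial = b$qpcr$bacterial_copies_per_cm2,
      qpcr_archaeal = b$qpcr$archaeal_copies_per_cm2,
      biofilm = b$biofilm$score,
      cod_initial = b$cod$cod_initial_gO2_per_L,
      cod_final = b$cod$cod_final_gO2_per_L)
  }
  counts <- tibble::as_tibble(dataset$amplicon$counts, rownames = "asv_id")
  readr::write_tsv(counts, file.path(dir, "amplicon_counts.tsv"))
  readr::write_tsv(dataset$amplicon$taxonomy, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(reactors = reactors_cfg,
                        amplicon = list(counts = "amplicon_counts.tsv",
                                        taxonomy = "taxonomy.tsv")),
                   cfg_path)
  invisible(cfg_path)
}
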