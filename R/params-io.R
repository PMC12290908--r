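# bundle serialization: one YAML config for scalars + CSV side tables, so the
# age tables stay diff-able.

bundle_top_keys <- function() {
  c("meta", "config", "risk", "tables", "strategy", "disease", "costs",
    "utilities", "impact", "wtp")
}

matrix_csv_names <- function() {
  c("bc_death_screened", "bc_death_general", "bc_death_post_rrm",
    "recurrence_local", "recurrence_distant",
    "recurrence_local_post_rrm", "recurrence_distant_post_rrm")
}

write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = ~paste0("y", 1:20))
  df <- dplyr::mutate(df, stage = bc_stages(), .before = 1)
  readr::write_csv(df, path)
}

read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    stage = readr::col_character(), .default = readr::col_double()))
  if (!identical(df$stage, bc_stages())) {
    abort_rrmcea(sprintf("%s: stage rows must be %s", basename(path),
                         paste(bc_stages(), collapse = ", ")),
                 "rrmcea_io_error")
  }
  m <- as.matrix(df[paste0("y", 1:20)])
  dimnames(m) <- list(stage = bc_stages(), ysd = 1:20)
  m
}

#' Write / read a parameter bundle
#'
#' A bundle is stored as a directory: `params.yml` for scalar structure and
#' one CSV per age table, survival/recurrence matrix and ancillary table.
#' Doubles are written with 17 significant digits so a write-read round trip
#' reproduces the bundle exactly. Reading validates the schema version,
#' rejects unknown top-level keys by name, and runs [validate_params()].
#'
#' @param bundle A `bc_params` bundle.
#' @param dir Directory path (created if needed).
#' @return `write_params()` returns `dir` invisibly; `read_params()` returns
#'   a validated `bc_params` bundle.
#' @export
write_params <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) readr::write_csv(tbl, file.path(dir, name))

  w(bundle$tables$incidence, "incidence.csv")
  w(bundle$tables$mortality, "mortality.csv")
  w(bundle$tables$utility_norms, "utility_norms.csv")
  for (nm in matrix_csv_names()) {
    write_matrix_csv(bundle$disease[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  w(bundle$costs$treatment, "treatment_costs.csv")
  w(bundle$utilities$state, "state_utilities.csv")
  w(bundle$impact$subgroups, "impact_subgroups.csv")

  named_to_list <- function(x) as.list(x)
  scalars <- list(
    meta = bundle$meta,
    config = bundle$config,
    risk = bundle$risk,
    strategy = bundle$strategy,
    disease = list(
      stage_dist_screened = named_to_list(bundle$disease$stage_dist_screened),
      stage_dist_general = named_to_list(bundle$disease$stage_dist_general),
      distant_death_annual = bundle$disease$distant_death_annual,
      pathology_screened = named_to_list(bundle$disease$pathology_screened),
      pathology_general = named_to_list(bundle$disease$pathology_general),
      survivor_cutoff = bundle$disease$survivor_cutoff
    ),
    costs = bundle$costs[setdiff(names(bundle$costs), "treatment")],
    utilities = list(
      distant_recurrence = bundle$utilities$distant_recurrence,
      survivor = bundle$utilities$survivor,
      decrements = bundle$utilities$decrements
    ),
    impact = bundle$impact[setdiff(names(bundle$impact), "subgroups")],
    wtp = bundle$wtp
  )
  yaml::write_yaml(scalars, file.path(dir, "params.yml"), precision = 17)
  invisible(dir)
}

#' @rdname write_params
#' @export
read_params <- function(dir) {
  cfg_path <- file.path(dir, "params.yml")
  if (!file.exists(cfg_path)) {
    abort_rrmcea(sprintf("missing config file: %s", cfg_path),
                 "rrmcea_io_error")
  }
  scalars <- yaml::read_yaml(cfg_path)
  known <- setdiff(bundle_top_keys(), c("tables"))
  unknown <- setdiff(names(scalars), known)
  if (length(unknown) > 0) {
    abort_rrmcea(sprintf("unknown key(s) in params.yml: %s",
                         paste(unknown, collapse = ", ")),
                 "rrmcea_io_error")
  }
  if (!identical(scalars$meta$schema_version, "1.0")) {
    abort_rrmcea("unsupported schema_version (expected \"1.0\")",
                 "rrmcea_io_error")
  }
  rt <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      abort_rrmcea(sprintf("missing table file: %s", path), "rrmcea_io_error")
    }
    read_age_rate_table(path)
  }
  rcsv <- function(name, col_types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      abort_rrmcea(sprintf("missing table file: %s", path), "rrmcea_io_error")
    }
    out <- readr::read_csv(path, col_types = col_types)
    attr(out, "spec") <- NULL
    attr(out, "problems") <- NULL
    class(out) <- c("tbl_df", "tbl", "data.frame")
    out
  }
  as_named <- function(x) unlist(x)

  disease <- list(
    stage_dist_screened = as_named(scalars$disease$stage_dist_screened),
    stage_dist_general = as_named(scalars$disease$stage_dist_general)
  )
  for (nm in matrix_csv_names()) {
    disease[[nm]] <- read_matrix_csv(file.path(dir, paste0(nm, ".csv")))
  }
  disease$distant_death_annual <- scalars$disease$distant_death_annual
  disease$pathology_screened <- as_named(scalars$disease$pathology_screened)
  disease$pathology_general <- as_named(scalars$disease$pathology_general)
  disease$survivor_cutoff <- as.integer(scalars$disease$survivor_cutoff)

  strategy <- scalars$strategy
  strategy$prevention_duration <- as.integer(strategy$prevention_duration)
  strategy$prevention_carryover <- as.integer(strategy$prevention_carryover)
  config <- scalars$config
  for (nm in c("start_age", "horizon_age", "menopause_age")) {
    config[[nm]] <- as.integer(config[[nm]])
  }

  bundle <- list(
    meta = list(schema_version = scalars$meta$schema_version,
                realism = scalars$meta$realism,
                seed = as.integer(scalars$meta$seed)),
    config = config,
    risk = scalars$risk,
    tables = list(
      incidence = rt("incidence.csv"),
      mortality = rt("mortality.csv"),
      utility_norms = rt("utility_norms.csv")
    ),
    strategy = strategy,
    disease = disease,
    costs = c(scalars$costs,
              list(treatment = rcsv("treatment_costs.csv", readr::cols(
                stage = readr::col_character(),
                .default = readr::col_double())))),
    utilities = list(
      norms = rt("utility_norms.csv"),
      state = rcsv("state_utilities.csv", readr::cols(
        stage = readr::col_character(), .default = readr::col_double())),
      distant_recurrence = scalars$utilities$distant_recurrence,
      survivor = scalars$utilities$survivor,
      decrements = scalars$utilities$decrements
    ),
    impact = c(scalars$impact,
               list(subgroups = rcsv("impact_subgroups.csv", readr::cols(
                 name = readr::col_character(),
                 .default = readr::col_double())))),
    wtp = scalars$wtp
  )
  bundle$impact$annual_cases <- as.integer(bundle$impact$annual_cases)
  # keep the block order stable for round-trip identity
  bundle$costs <- bundle$costs[c(setdiff(names(bundle$costs), "treatment"),
                                 "treatment")]
  bundle$impact <- bundle$impact[c(setdiff(names(bundle$impact), "subgroups"),
                                   "subgroups")]
  class(bundle) <- "bc_params"
  report <- validate_params(bundle)
  if (nrow(report) > 0) {
    abort_rrmcea(paste0("bundle fails validation:\n",
                        paste(report$path, report$message, sep = ": ",
                              collapse = "\n")),
                 "rrmcea_validation_error")
  }
  bundle
}
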