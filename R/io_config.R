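# Run configuration: sample manifest plus analysis parameters.  Serialised
# as YAML; unknown keys are rejected so that typos fail loudly.

config_keys <- c("manifest", "params", "reference_c_value_pg", "pg_per_mb",
                 "seed")
manifest_keys <- c("sample_id", "species", "tissue", "replicate", "role",
                   "group", "template", "path", "expect_haploid", "n_events")
param_keys <- c("n_events", "n_bins", "gate_k", "max_gate_fraction",
                "bw_factor", "min_prominence_fraction",
                "min_separation_ratio", "ladder_window", "window_sd",
                "valley_fraction")

#' Default analysis parameters
#'
#' Defaults used by [ploidy_fit()] and [run_pipeline()]: 20,000 events per
#' synthetic sample, 512 histogram bins over the log-fluorescence range,
#' debris gate at Q3 + 3 IQR of side scatter capped at 20% of events, peak
#' prominence floor of 0.5% of events, minimum peak separation 1.25x,
#' ladder acceptance window \[1.6, 2.3\], 3-SD attribution windows and a
#' 20% valley fraction for chain detection.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(n_events = 20000L, n_bins = 512L, gate_k = 3,
       max_gate_fraction = 0.2, bw_factor = 0.5,
       min_prominence_fraction = 0.005, min_separation_ratio = 1.25,
       ladder_window = c(1.6, 2.3), window_sd = 3, valley_fraction = 0.2)
}

#' Construct a run configuration
#'
#' @param manifest Data frame with one row per sample: `sample_id`,
#'   `species`, `tissue`, `replicate`, `role` (`"sample"` or
#'   `"reference"`), and either `template` (a [template_library()] name) or
#'   `path` (an event-table file).  Optional: `group` (calibration group,
#'   default `"default"`), `expect_haploid`, `n_events`.
#' @param params Named list overriding [default_params()].
#' @param reference_c_value_pg C-value of the internal reference standard
#'   in pg (default 0.18, the *D. melanogaster* reference).
#' @param pg_per_mb Unit conversion constant (default 978 Mb per pg).
#' @param seed Master seed for all synthetic samples.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(manifest, params = list(),
                       reference_c_value_pg = 0.18, pg_per_mb = 978,
                       seed = 1L) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "tissue", "replicate", "role")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop_fmt("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  unknown <- setdiff(names(manifest), manifest_keys)
  if (length(unknown))
    stop_fmt("unknown manifest column(s): %s", paste(unknown, collapse = ", "))
  if (!all(manifest$role %in% c("sample", "reference")))
    stop_fmt("manifest$role must be 'sample' or 'reference'")
  if (is.null(manifest$group)) manifest$group <- "default"
  if (is.null(manifest$expect_haploid)) manifest$expect_haploid <- FALSE
  manifest$expect_haploid[is.na(manifest$expect_haploid)] <- FALSE
  if (is.null(manifest$template)) manifest$template <- NA_character_
  if (is.null(manifest$path)) manifest$path <- NA_character_
  if (is.null(manifest$n_events)) manifest$n_events <- NA_integer_
  if (anyDuplicated(manifest$sample_id))
    stop_fmt("manifest sample_id values must be unique")
  no_src <- is.na(manifest$template) & is.na(manifest$path)
  if (any(no_src))
    stop_fmt("manifest rows without template or path: %s",
             paste(manifest$sample_id[no_src], collapse = ", "))
  for (g in unique(manifest$group)) {
    refs <- manifest[manifest$group == g & manifest$role == "reference", ]
    nset <- nrow(unique(refs[, c("species", "tissue")]))
    if (nset > 1L)
      stop_fmt("calibration group '%s' has %d reference sample sets; exactly one is allowed",
               g, nset)
  }
  unknown <- setdiff(names(params), param_keys)
  if (length(unknown))
    stop_fmt("unknown config key(s): %s",
             paste(paste0("params$", unknown), collapse = ", "))
  if (!is.numeric(reference_c_value_pg) || reference_c_value_pg <= 0)
    stop_fmt("reference_c_value_pg must be positive")
  if (!is.numeric(pg_per_mb) || pg_per_mb <= 0)
    stop_fmt("pg_per_mb must be positive")
  structure(list(
    manifest = manifest,
    params = utils::modifyList(default_params(), params),
    reference_c_value_pg = as.numeric(reference_c_value_pg),
    pg_per_mb = as.numeric(pg_per_mb),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected with the offending key path; absent analysis
#' parameters are filled from [default_params()], the reference C-value
#' defaults to 0.18 pg and the conversion constant to 978 Mb/pg.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), config_keys)
  if (length(unknown))
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(y$manifest) || !length(y$manifest))
    stop_fmt("config must contain a non-empty manifest")
  rows <- lapply(y$manifest, function(entry) {
    unknown <- setdiff(names(entry), manifest_keys)
    if (length(unknown))
      stop_fmt("unknown config key(s): %s",
               paste(paste0("manifest$", unknown), collapse = ", "))
    defaults <- list(sample_id = NA_character_, species = NA_character_,
                     tissue = NA_character_, replicate = NA_integer_,
                     role = "sample", group = "default",
                     template = NA_character_, path = NA_character_,
                     expect_haploid = FALSE, n_events = NA_integer_)
    as.data.frame(utils::modifyList(defaults, entry),
                  stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  params <- y$params %||% list()
  if (!is.null(params$ladder_window))
    params$ladder_window <- as.numeric(unlist(params$ladder_window))
  run_config(manifest, params,
             reference_c_value_pg = y$reference_c_value_pg %||% 0.18,
             pg_per_mb = y$pg_per_mb %||% 978,
             seed = y$seed %||% 1L)
}

#' Write a run configuration to YAML
#'
#' Inverse of [read_run_config()]; a read-write-read round trip is the
#' identity.
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  man <- lapply(seq_len(nrow(config$manifest)), function(i) {
    row <- as.list(config$manifest[i, , drop = FALSE])
    row <- lapply(row, function(v) if (is.factor(v)) as.character(v) else v)
    row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
  })
  out <- list(manifest = man,
              params = config$params,
              reference_c_value_pg = config$reference_c_value_pg,
              pg_per_mb = config$pg_per_mb,
              seed = config$seed)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: %d samples in %d group(s); reference %.3g pg; %g Mb/pg; seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$group)),
              x$reference_c_value_pg, x$pg_per_mb, x$seed))
  print(x$manifest[, c("sample_id", "species", "tissue", "replicate",
                       "role", "group")], row.names = FALSE)
  invisible(x)
}
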