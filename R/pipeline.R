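#' Build a pipeline run manifest
#'
#' A run manifest describes one end-to-end analysis: where recordings come
#' from (`"simulate"` a synthetic study or load `"files"` via cohort
#' manifests), which bands and window length to use, where outputs go, and the
#' base seed. Exactly one input mode is allowed.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param generator A [generator_config()] (simulate mode; default
#'   `generator_config(base_seed = base_seed)`).
#' @param treatments Simulate mode: list of `list(name =, modulation =)`
#'   entries, one synthetic cohort each. The default emulates a two-treatment
#'   host-presentation study: a `"host"` cohort whose low-band power triples
#'   20 min into the after phase, and an unmodulated `"control"` cohort.
#' @param cohort_manifests Files mode: character vector of cohort manifest
#'   paths (see [write_cohort()]).
#' @param bands Bands table, bands JSON path, or `NULL` for the defaults.
#' @param seg_seconds Analysis window length in seconds.
#' @param out_dir Output directory.
#' @param base_seed Integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @param make_figures Write per-feature TDAF figures (PNG) as well as tables.
#' @return An `epg_run_manifest` record.
#' @export
run_manifest <- function(mode = c("simulate", "files"), generator = NULL,
                         treatments = NULL, cohort_manifests = NULL,
                         bands = NULL, seg_seconds = 60, out_dir = NULL,
                         base_seed = 1L, log_level = c("info", "quiet"),
                         make_figures = FALSE) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  check_number(seg_seconds, "seg_seconds", lower = 0, allow_equal_lower = FALSE)
  check_number(base_seed, "base_seed")
  if (mode == "simulate") {
    if (!is.null(cohort_manifests)) {
      stop_electrome("simulate mode must not set `cohort_manifests`", "manifest")
    }
    generator <- generator %||% generator_config(base_seed = base_seed)
    if (!inherits(generator, "epg_generator_config")) {
      stop_electrome("`generator` must be a generator_config()", "manifest")
    }
    treatments <- treatments %||% list(
      list(name = "host", modulation = step_modulation()),
      list(name = "control", modulation = NULL)
    )
    if (length(treatments) == 0L) {
      stop_electrome("simulate mode needs at least one treatment", "manifest")
    }
  } else {
    if (is.null(cohort_manifests) || length(cohort_manifests) == 0L) {
      stop_electrome("files mode needs a non-empty `cohort_manifests` list",
                     "manifest")
    }
    if (!is.null(generator) || !is.null(treatments)) {
      stop_electrome("files mode must not set `generator` or `treatments`",
                     "manifest")
    }
  }
  bands_tbl <- if (is.null(bands)) {
    default_bands()
  } else if (is.character(bands)) {
    read_bands(bands)
  } else {
    validate_bands(bands)
  }
  structure(
    list(mode = mode, generator = generator, treatments = treatments,
         cohort_manifests = cohort_manifests, bands = bands_tbl,
         seg_seconds = seg_seconds, out_dir = out_dir,
         base_seed = as.integer(base_seed), log_level = log_level,
         make_figures = isTRUE(make_figures)),
    class = "epg_run_manifest"
  )
}

#' Read a run manifest from JSON
#'
#' @param path Path to a run manifest JSON file. Recognised fields: `mode`,
#'   `generator` (inline generator config object or path), `treatments`
#'   (array of `{name, modulation: {onset_s, band_gains}}`),
#'   `cohort_manifests`, `bands` (path), `seg_seconds`, `out_dir`,
#'   `base_seed`, `log_level`, `make_figures`. Relative paths are resolved
#'   against the manifest's directory.
#' @return An `epg_run_manifest`.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_electrome(sprintf("run manifest not found: %s", path), "missing_file")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  base_seed <- raw$base_seed %||% 1L
  generator <- NULL
  if (!is.null(raw$generator)) {
    generator <- if (is.character(raw$generator)) {
      read_generator_config(resolve(raw$generator))
    } else {
      cfg_path <- tempfile(fileext = ".json")
      on.exit(unlink(cfg_path), add = TRUE)
      jsonlite::write_json(raw$generator, cfg_path, auto_unbox = TRUE, digits = NA)
      read_generator_config(cfg_path)
    }
  }
  treatments <- NULL
  if (!is.null(raw$treatments)) {
    treatments <- map(raw$treatments, function(tr) {
      modulation <- NULL
      if (!is.null(tr$modulation)) {
        modulation <- step_modulation(
          onset_s = tr$modulation$onset_s %||% 1200,
          band_gains = unlist(tr$modulation$band_gains)
        )
      }
      list(name = tr$name, modulation = modulation)
    })
  }
  run_manifest(
    mode = raw$mode %||% "simulate",
    generator = generator,
    treatments = treatments,
    cohort_manifests = if (!is.null(raw$cohort_manifests)) {
      vapply(raw$cohort_manifests, resolve, character(1))
    },
    bands = if (!is.null(raw$bands)) resolve(raw$bands),
    seg_seconds = raw$seg_seconds %||% 60,
    out_dir = raw$out_dir %||% NULL,
    base_seed = base_seed,
    log_level = raw$log_level %||% "info",
    make_figures = isTRUE(raw$make_figures)
  )
}

run_stage <- function(stage, input_desc, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      if (inherits(e, "electrome_stage_error")) return()
      abort(sprintf("pipeline stage `%s` failed on %s", stage, input_desc),
            class = c("electrome_stage_error", "electrome_error"), parent = e)
    }
  )
}

#' Run the full analysis pipeline
#'
#' simulate/load -> per-minute features -> TDAF -> phase comparison. Writes
#' tidy CSV tables (`features.csv`, `tdaf.csv`, `phase_comparisons.csv`), a
#' machine-readable `run_log.json` recording every analysis convention in
#' effect (taper, overlap, quartile convention, seeds, warnings including
#' Nyquist clipping), and optionally per-feature figures. Identical manifest
#' and seed give byte-identical tables.
#'
#' @param manifest An `epg_run_manifest` from [run_manifest()] or
#'   [read_run_manifest()].
#' @param out_dir Output directory; overrides the manifest's `out_dir`.
#' @return Invisibly, an `epg_run` list: `features`, `tdaf`, `comparisons`,
#'   `log`, `paths`.
#' @examples
#' \donttest{
#' cfg <- generator_config(duration_s = 180, n_replicates = 2, base_seed = 3)
#' m <- run_manifest("simulate", generator = cfg, out_dir = tempfile())
#' run <- run_pipeline(m)
#' glance(run$comparisons)
#' }
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  if (!inherits(manifest, "epg_run_manifest")) {
    stop_electrome("`manifest` must come from run_manifest() or read_run_manifest()",
                   "manifest")
  }
  out_dir <- out_dir %||% manifest$out_dir
  if (is.null(out_dir)) {
    stop_electrome("no output directory: set `out_dir`", "manifest")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_warnings <- character(0)
  note <- function(msg) {
    if (identical(manifest$log_level, "info")) inform(paste0("electrome: ", msg))
  }
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      log_warnings <<- c(log_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # stage 1: obtain cohorts
  cohorts <- run_stage("input", paste0("mode=", manifest$mode), {
    if (manifest$mode == "simulate") {
      gen <- manifest$generator
      list_rbind(imap(manifest$treatments, function(tr, i) {
        cfg <- generator_config(
          fs = gen$fs, duration_s = gen$duration_s,
          n_replicates = gen$n_replicates,
          background_exponent = gen$background_exponent,
          background_rms = gen$background_rms,
          components = gen$components,
          modulation = tr$modulation,
          base_seed = gen$base_seed + 299993L * (i - 1L)
        )
        note(sprintf("simulating cohort `%s` (seed %d)", tr$name, cfg$base_seed))
        generate_cohort(cfg, treatment = tr$name)
      }))
    } else {
      list_rbind(map(manifest$cohort_manifests, read_cohort))
    }
  })

  # stage 2: per-minute features
  note(sprintf("extracting features from %d recordings", nrow(cohorts)))
  features <- run_stage("features", sprintf("%d recordings", nrow(cohorts)),
    collect(epg_features(cohorts, bands = manifest$bands,
                         seg_seconds = manifest$seg_seconds)))

  # stage 3: TDAF
  tdaf <- run_stage("tdaf", "feature table", collect(tdaf_aggregate(features)))

  # stage 4: phase comparison (needs both phases)
  comparisons <- NULL
  if (all(c("before", "after") %in% unique(features$phase))) {
    comparisons <- run_stage("compare_phases", "TDAF table",
                             collect(compare_phases(tdaf)))
  } else {
    note("single phase present; skipping phase comparison")
  }

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    tdaf = file.path(out_dir, "tdaf.csv"),
    comparisons = file.path(out_dir, "phase_comparisons.csv"),
    log = file.path(out_dir, "run_log.json")
  )
  readr::write_csv(features, paths$features, progress = FALSE)
  readr::write_csv(tidy(tdaf), paths$tdaf, progress = FALSE)
  if (!is.null(comparisons)) {
    readr::write_csv(tidy(comparisons), paths$comparisons, progress = FALSE)
  }

  seeds <- NULL
  if (manifest$mode == "simulate") {
    gen <- manifest$generator
    seeds <- map(seq_along(manifest$treatments), function(i) {
      list(treatment = manifest$treatments[[i]]$name,
           base_seed = gen$base_seed + 299993L * (i - 1L))
    })
  }
  log <- list(
    package = "electrome",
    version = as.character(utils::packageVersion("electrome")),
    mode = manifest$mode,
    parameters = list(
      seg_seconds = manifest$seg_seconds,
      welch = list(window_seconds = 4, overlap_fraction = 0.5, taper = "hann",
                   detrend = "constant per segment",
                   scaling = "one-sided density, uV^2/Hz"),
      band_integration = "composite Simpson, trapezoid first interval when the in-band point count is even; trapezoid fallback below 3 points",
      quartile_convention = "linear interpolation between order statistics (stats::quantile type 7)",
      onset_rule = sprintf(
        "first after-phase minute whose median exceeds the before-phase pooled q3 (median of per-minute q3) for >= %d consecutive minutes",
        if (!is.null(comparisons)) attr(comparisons, "onset_min_run") else 5L),
      bands = as.data.frame(manifest$bands),
      base_seed = manifest$base_seed,
      cohort_seeds = seeds
    ),
    warnings = as.list(unique(log_warnings))
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  if (manifest$make_figures) {
    fig_dir <- file.path(out_dir, "figures")
    if (!dir.exists(fig_dir)) dir.create(fig_dir)
    for (feat in unique(tdaf$feature)) {
      p <- autoplot(tdaf, features = feat)
      fname <- file.path(fig_dir, paste0(gsub("[^a-z0-9]+", "_", feat), ".png"))
      ggplot2::ggsave(fname, p, width = 8, height = 4.5, dpi = 120)
      paths$figures <- c(paths$figures, fname)
    }
  }

  note(sprintf("wrote tables to %s", out_dir))
  invisible(structure(
    list(features = features, tdaf = tdaf, comparisons = comparisons,
         log = log, paths = paths),
    class = "epg_run"
  ))
}

#' @export
print.epg_run <- function(x, ...) {
  cat(sprintf("<epg_run> %d feature rows, %d TDAF rows, %s\n",
              nrow(x$features), nrow(x$tdaf),
              if (is.null(x$comparisons)) "no phase comparison" else
                sprintf("%d phase comparisons", nrow(x$comparisons))))
  invisible(x)
}
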