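# End-to-end orchestration: ingest -> link -> deduplicate -> adolescent
# filter -> frequency tables -> drill-down -> designated-control scans.

#' Pipeline run configuration
#'
#' Exactly one of `quarters` and `synthetic` must be supplied. `quarters` is
#' a list of entries `list(label = "2017q3", paths = c(DEMO = ..., ...))`;
#' `synthetic` a [synthetic_config()] (its seed is overridden by `seed` when
#' given).
#'
#' @param quarters list of quarter path entries, or `NULL`.
#' @param synthetic a `synthetic_config`, or `NULL`.
#' @param age_min,age_max adolescent window in years, `[age_min, age_max)`.
#' @param control_pt designated control preferred term (default
#'   `"Diarrhoea"`, the most reported PT in the target cohort).
#' @param case_pts case preferred terms to scan (defaults: Hyperglycaemia,
#'   Pneumothorax, Completed suicide, Drug interaction). Must not contain
#'   `control_pt`.
#' @param top_n_tables rows per frequency table (default 15).
#' @param top_n_scan number of most-reported drugs entering each scan
#'   (default 20).
#' @param roles drug-role exposure policy, `"all"` or `"suspect"`.
#' @param synonym_map optional drug synonym map.
#' @param out_dir output directory for tables and manifests.
#' @param seed integer seed used for any randomness (synthetic generation).
#' @return a validated `run_config`.
#' @export
run_config <- function(quarters = NULL, synthetic = NULL,
                       age_min = 12, age_max = 18,
                       control_pt = "Diarrhoea",
                       case_pts = c("Hyperglycaemia", "Pneumothorax",
                                    "Completed suicide", "Drug interaction"),
                       top_n_tables = 15, top_n_scan = 20,
                       roles = c("all", "suspect"),
                       synonym_map = NULL,
                       out_dir = "faersignal_out", seed = 1L) {
  roles <- match.arg(roles)
  if (is.null(quarters) == is.null(synthetic)) {
    stop_cfg("run_config: supply exactly one of quarters/synthetic")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop_cfg("run_config: synthetic must be a synthetic_config")
  }
  if (top_n_tables < 1 || top_n_scan < 1) stop_cfg("top_n values must be >= 1")
  if (age_min >= age_max) stop_cfg("age_min must be below age_max")
  ctrl <- squash_upper(control_pt)
  cases <- squash_upper(case_pts)
  if (ctrl %in% cases) {
    stop_cfg("control PT '", control_pt, "' must not appear among case PTs")
  }
  structure(
    list(quarters = quarters, synthetic = synthetic,
         age_min = age_min, age_max = age_max,
         control_pt = ctrl, case_pts = cases,
         top_n_tables = as.integer(top_n_tables),
         top_n_scan = as.integer(top_n_scan),
         roles = roles, synonym_map = synonym_map,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML or JSON
#'
#' File keys mirror the arguments of [run_config()]; a `synthetic` block is
#' passed to [synthetic_config()] (catalog blocks given as column lists are
#' coerced to data frames), and `quarters` entries carry a `label` plus one
#' path per table kind.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_cfg("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (!is.null(raw$synthetic)) {
    sc <- raw$synthetic
    for (fld in c("drug_catalog", "event_catalog", "signal_matrix")) {
      if (!is.null(sc[[fld]])) {
        sc[[fld]] <- as.data.frame(lapply(sc[[fld]], unlist),
                                   stringsAsFactors = FALSE)
      }
    }
    raw$synthetic <- do.call(synthetic_config, sc)
  }
  if (!is.null(raw$quarters)) {
    raw$quarters <- lapply(raw$quarters, function(entry) {
      label <- entry$label %||% stop_cfg("quarter entry lacks a label")
      paths <- unlist(entry[setdiff(names(entry), "label")])
      names(paths) <- toupper(names(paths))
      list(label = label, paths = paths)
    })
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_cfg("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

write_table_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — ingestion (or synthetic generation),
#' linkage, deduplication, adolescent filtering, the three frequency tables,
#' a drill-down of the most-reported drug, and one designated-control scan
#' per case PT over the most-reported drugs — writing each product under
#' `config$out_dir` and returning a manifest. Deterministic for fixed inputs
#' and seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines (default `FALSE`).
#' @return the manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(...) if (!quiet) message("[faersignal] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage_counts <- list()

  # -- ingest ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- config$seed
    gen_dir <- file.path(config$out_dir, "synthetic_quarter")
    gen <- generate(sc, gen_dir)
    quarters <- list(list(label = sc$quarter_label, paths = gen$paths))
    outputs["truth_table"] <- gen$truth_path
    log_line("generated synthetic quarter ", sc$quarter_label,
             " (n_cases=", sc$n_cases, ")")
  } else {
    quarters <- config$quarters
  }
  raws <- lapply(quarters, function(entry) {
    q <- read_quarter(entry$paths, entry$label)
    log_line("read quarter ", entry$label, ": ",
             q$parse_report$DEMO$n_rows, " DEMO rows")
    q
  })
  stage_counts$ingested_demo_rows <-
    sum(vapply(raws, function(q) q$parse_report$DEMO$n_rows, numeric(1)))

  # -- link + dedup ---------------------------------------------------------
  linked <- link_tables(raws, synonym_map = config$synonym_map)
  lr <- linked$link_report
  if (sum(unlist(lr$orphans)) > 0 || lr$excluded_no_drug + lr$excluded_no_reaction > 0) {
    log_line("WARN linkage: ", sum(unlist(lr$orphans)), " orphan child rows; ",
             lr$excluded_no_drug + lr$excluded_no_reaction, " cases excluded")
  }
  stage_counts$linked_cases <- nrow(linked$demo)
  deduped <- deduplicate(linked)
  stage_counts$deduplicated_cases <- nrow(deduped$demo)
  log_line("linked ", stage_counts$linked_cases, " cases; ",
           stage_counts$deduplicated_cases, " after deduplication")

  pr_path <- file.path(config$out_dir, "parse_report.json")
  parse_rep <- list(
    quarters = lapply(raws, function(q) list(quarter = q$quarter,
                                             tables = q$parse_report)),
    linkage = linked$link_report
  )
  writeLines(jsonlite::toJSON(parse_rep, auto_unbox = TRUE, pretty = TRUE), pr_path)
  outputs["parse_report"] <- pr_path

  # -- cohort ---------------------------------------------------------------
  cohort <- filter_adolescent(deduped, config$age_min, config$age_max)
  stage_counts$cohort_cases <- cohort$n_cases
  log_line("adolescent cohort [", config$age_min, ",", config$age_max, "): ",
           cohort$n_cases, " cases")
  outputs["cohort_summary"] <- file.path(config$out_dir, "cohort_summary.json")
  cohort_summary_json(cohort, outputs["cohort_summary"])

  # -- frequency tables -----------------------------------------------------
  freqs <- list()
  for (dim in c("drug", "reaction", "indication")) {
    freqs[[dim]] <- frequency_table(cohort, dim, top_n = config$top_n_tables)
    outputs[paste0("freq_", dim)] <-
      write_table_csv(freqs[[dim]], file.path(config$out_dir,
                                              paste0("freq_", dim, ".csv")))
  }
  log_line("frequency tables written (top ", config$top_n_tables, ")")

  # -- drill-down of the most reported drug ---------------------------------
  if (nrow(freqs$drug)) {
    top_drug <- freqs$drug$item[1]
    dd <- drug_drilldown(cohort, top_drug, top_n = 10, roles = config$roles)
    safe <- gsub("[^A-Za-z0-9]+", "_", tolower(top_drug))
    outputs["drilldown_reactions"] <-
      write_table_csv(dd$reactions,
                      file.path(config$out_dir, paste0("drilldown_", safe, "_reactions.csv")))
    outputs["drilldown_indications"] <-
      write_table_csv(dd$indications,
                      file.path(config$out_dir, paste0("drilldown_", safe, "_indications.csv")))
    log_line("drill-down for ", top_drug, " (", dd$n_cases, " cases)")
  }

  # -- scans ----------------------------------------------------------------
  scan_drug_list <- frequency_table(cohort, "drug", top_n = config$top_n_scan)$item
  scans <- character(0)
  for (pt in config$case_pts) {
    res <- scan_drugs(cohort, pt, config$control_pt, scan_drug_list,
                      roles = config$roles)
    safe <- gsub("[^A-Za-z0-9]+", "_", tolower(pt))
    path <- write_table_csv(res, file.path(config$out_dir,
                                           paste0("scan_", safe, ".csv")))
    outputs[paste0("scan_", safe)] <- path
    scans <- c(scans, path)
    log_line("scan ", pt, " vs ", config$control_pt, ": ",
             nrow(res), " drugs, ", sum(res$significant), " significant")
  }

  # -- manifest -------------------------------------------------------------
  cfg_for_hash <- config
  cfg_for_hash$synonym_map <- NULL
  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config_hash = fnv1a32(as.character(
      jsonlite::toJSON(cfg_for_hash[setdiff(names(cfg_for_hash), "synthetic")],
                       auto_unbox = TRUE, force = TRUE))),
    stage_counts = stage_counts,
    n_frequency_tables = 3L,
    n_scans = length(scans),
    outputs = as.list(outputs)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path)
  log_line("manifest written: ", manifest_path)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `simulate` (synthetic quarter only),
#' `scan` (one disproportionality scan), `freq` (one frequency table). All
#' take `--config <yaml|json>`; `run`/`simulate` accept `--out` and
#' `--seed` overrides, `scan` takes `--case-pt` (and optional
#' `--control-pt`), `freq` takes `--dimension`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return integer exit code: 0 ok, 1 configuration error, 2 stage failure.
#' @export
faersignal_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: faersignal <run|simulate|scan|freq> --config FILE",
        "[--out DIR] [--seed N] [--case-pt PT] [--control-pt PT]",
        "[--dimension drug|reaction|indication]\n")
  }
  if (!length(args)) { usage(); return(1L) }
  cmd <- args[[1]]
  opts <- parse_cli_opts(args[-1])
  code <- tryCatch({
    cfg <- load_run_config(opts$config %||% stop_cfg("--config is required"))
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    switch(cmd,
      run = { run_pipeline(cfg); 0L },
      simulate = {
        if (is.null(cfg$synthetic)) stop_cfg("simulate requires a synthetic block")
        sc <- cfg$synthetic; sc$seed <- cfg$seed
        generate(sc, cfg$out_dir)
        0L
      },
      scan = {
        case_pt <- opts[["case-pt"]] %||% stop_cfg("scan requires --case-pt")
        cohort <- pipeline_cohort(cfg)
        drugs <- frequency_table(cohort, "drug", top_n = cfg$top_n_scan)$item
        res <- scan_drugs(cohort, case_pt, opts[["control-pt"]] %||% cfg$control_pt,
                          drugs, roles = cfg$roles)
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_table_csv(res, file.path(cfg$out_dir, "scan.csv"))
        0L
      },
      freq = {
        dim <- opts$dimension %||% "drug"
        cohort <- pipeline_cohort(cfg)
        tab <- frequency_table(cohort, dim, top_n = cfg$top_n_tables)
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_table_csv(tab, file.path(cfg$out_dir, paste0("freq_", dim, ".csv")))
        0L
      },
      { usage(); 1L }
    )
  },
  faersignal_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 1L
  },
  error = function(e) {
    message("stage failure: ", conditionMessage(e)); 2L
  })
  code
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--") || i == length(args)) {
      stop_cfg("malformed CLI arguments near '", key, "'")
    }
    opts[[substring(key, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

# ingest + dedup + filter for the one-shot CLI subcommands
pipeline_cohort <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sc <- cfg$synthetic
    sc$seed <- cfg$seed
    gen <- generate(sc, file.path(cfg$out_dir, "synthetic_quarter"))
    quarters <- list(list(label = sc$quarter_label, paths = gen$paths))
  } else {
    quarters <- cfg$quarters
  }
  raws <- lapply(quarters, function(e) read_quarter(e$paths, e$label))
  deduped <- deduplicate(link_tables(raws, synonym_map = cfg$synonym_map))
  filter_adolescent(deduped, cfg$age_min, cfg$age_max)
}
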