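# FAERS quarterly ASCII ingestion: "$"-delimited tables, first line a header,
# no quoting. Both the post-2014 FAERS and the legacy LAERS column spellings
# are accepted through .faers_aliases.

.faers_kinds <- c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")

# legacy / variant header spellings mapped onto the modern names
.faers_aliases <- c(
  isr       = "primaryid",
  "case"    = "caseid",
  gndr_cod  = "sex",
  outc_code = "outc_cod",
  drug_rec_act = "drug_rec_act"
)

.faers_required <- list(
  DEMO = c("primaryid", "caseid", "caseversion", "fda_dt", "age", "age_cod", "sex"),
  DRUG = c("primaryid", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  RPSR = c("primaryid", "rpsr_cod"),
  THER = c("primaryid"),
  INDI = c("primaryid", "indi_pt")
)

.role_codes <- c(
  PS = "primary_suspect", SS = "secondary_suspect",
  C  = "concomitant",     I  = "interacting"
)

#' Read one FAERS quarter from ASCII tables
#'
#' Parses the seven dollar-delimited quarterly tables (DEMO, DRUG, REAC, OUTC,
#' RPSR, THER, INDI). The first line of each file is the header; fields are
#' split on `$` with no quoting, values are whitespace-trimmed, and files are
#' decoded as Latin-1 (legacy quarters are not UTF-8 clean). Rows whose field
#' count disagrees with the header are dropped and counted in the parse
#' report rather than aborting the load.
#'
#' @param paths named character vector or list mapping table kind
#'   (`"DEMO"`, `"DRUG"`, ...) to a file path. All seven kinds are required.
#' @param quarter_label label such as `"2017q3"`, recorded for provenance.
#' @return A `faers_raw` object: list with `quarter`, `tables` (named list of
#'   character data frames) and `parse_report` (per-table line/row/drop
#'   counts).
#' @seealso [link_tables()], [write_quarter()], [parse_report_json()]
#' @export
read_quarter <- function(paths, quarter_label) {
  stopifnot(is_string(quarter_label))
  paths <- as.list(paths)
  missing_kinds <- setdiff(.faers_kinds, names(paths))
  if (length(missing_kinds)) {
    stop_cfg("read_quarter: no path given for table kind(s): ",
             paste(missing_kinds, collapse = ", "))
  }
  tables <- list()
  report <- list()
  for (kind in .faers_kinds) {
    path <- paths[[kind]]
    if (!file.exists(path)) {
      stop_cfg("read_quarter: file for table ", kind, " not found: ", path)
    }
    parsed <- read_dollar_table(path, kind)
    tables[[kind]] <- parsed$rows
    report[[kind]] <- parsed$report
  }
  structure(
    list(quarter = quarter_label, tables = tables, parse_report = report),
    class = "faers_raw"
  )
}

read_dollar_table <- function(path, kind) {
  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop_cfg("read_quarter: ", kind, " file is empty: ", path)
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  alias_hit <- header %in% names(.faers_aliases)
  header[alias_hit] <- unname(.faers_aliases[header[alias_hit]])
  req <- .faers_required[[kind]]
  missing_cols <- setdiff(req, header)
  if (length(missing_cols)) {
    stop_cfg("read_quarter: ", kind, " header does not match a known FAERS ",
             "dialect; missing column(s): ", paste(missing_cols, collapse = ", "),
             "; saw: ", paste(header, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    parts <- strsplit(body, "$", fixed = TRUE)
    # strsplit drops a trailing empty field; pad to header length
    lens <- lengths(parts)
    pad <- lens == length(header) - 1L & endsWith(body, "$")
    parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
    lens <- lengths(parts)
    ok <- lens == length(header)
    kept <- parts[ok]
    n_dropped <- sum(!ok)
    if (length(kept)) {
      mat <- matrix(trimws(unlist(kept, use.names = FALSE)),
                    ncol = length(header), byrow = TRUE)
      rows <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(rows) <- header
    } else {
      rows <- empty_table(header)
    }
  } else {
    rows <- empty_table(header)
    n_dropped <- 0L
  }
  list(rows = rows,
       report = list(n_data_lines = length(body),
                     n_rows = nrow(rows),
                     n_dropped = n_dropped))
}

empty_table <- function(header) {
  rows <- as.data.frame(setNames(rep(list(character(0)), length(header)), header),
                        stringsAsFactors = FALSE)
  rows
}

#' Write a quarter back to FAERS-dialect files
#'
#' Inverse of [read_quarter()]: emits each table as a dollar-delimited file
#' with a header line. Used by the synthetic generator and for round-trip
#' testing.
#'
#' @param q a `faers_raw` object.
#' @param dir output directory (created if needed).
#' @param suffix filename suffix, default the quarter label.
#' @return named character vector of written paths, invisibly.
#' @export
write_quarter <- function(q, dir, suffix = q$quarter) {
  stopifnot(inherits(q, "faers_raw"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (kind in names(q$tables)) {
    tab <- q$tables[[kind]]
    path <- file.path(dir, paste0(kind, toupper(suffix), ".txt"))
    lines <- c(paste(names(tab), collapse = "$"),
               if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "$")))
    writeLines(lines, path, useBytes = TRUE)
    paths[kind] <- path
  }
  invisible(paths)
}

#' Normalize a verbatim drug name
#'
#' Upper-cases, trims, and collapses internal whitespace runs; then applies an
#' optional synonym map (exact match on the normalized form). No salt
#' stripping is performed by default: distinct verbatim products such as a
#' base compound and its fumarate salt stay distinct, which matters because
#' they can carry very different signals.
#'
#' @param verbatim character vector of verbatim drug names.
#' @param synonym_map optional named character vector mapping normalized names
#'   to replacement names.
#' @return character vector of normalized names; entries empty after trimming
#'   come back as `NA` with a warning (callers drop them).
#' @export
normalize_drug_name <- function(verbatim, synonym_map = NULL) {
  out <- squash_upper(verbatim)
  empty <- !is.na(out) & !nzchar(out)
  if (any(empty)) {
    warning(sum(empty), " drug entr", if (sum(empty) == 1L) "y" else "ies",
            " empty after normalization; dropped", call. = FALSE)
    out[empty] <- NA_character_
  }
  if (!is.null(synonym_map) && length(synonym_map)) {
    names(synonym_map) <- squash_upper(names(synonym_map))
    hit <- !is.na(out) & out %in% names(synonym_map)
    out[hit] <- unname(synonym_map[out[hit]])
  }
  out
}

#' Link quarterly tables into case reports
#'
#' Joins the child tables (DRUG, REAC, INDI, OUTC, RPSR) onto DEMO rows by
#' exact `primaryid` match. Child rows with no DEMO parent are counted as
#' orphans and excluded. Cases with zero drugs or zero reactions after
#' linking are excluded (they cannot contribute to any downstream statistic)
#' and counted. Drug names are normalized via [normalize_drug_name()] and
#' duplicate (name, role) pairs within a case are collapsed.
#'
#' @param q a `faers_raw` object, or a list of them (quarters are pooled).
#' @param synonym_map optional drug synonym map, see [normalize_drug_name()].
#' @return A `faers_cases` object: list of linked data frames (`demo`,
#'   `drugs`, `reactions`, `indications`, `outcomes`, `sources`) plus a
#'   `link_report` with orphan and exclusion counts.
#' @export
link_tables <- function(q, synonym_map = NULL) {
  if (inherits(q, "faers_raw")) q <- list(q)
  stopifnot(all(vapply(q, inherits, logical(1), "faers_raw")))

  demo <- do.call(rbind, lapply(q, function(x) {
    d <- x$tables$DEMO
    d$quarter <- rep_len(x$quarter, nrow(d))
    d[c("primaryid", "caseid", "caseversion", "fda_dt", "age", "age_cod",
        "sex", "quarter")]
  }))
  pool <- function(kind, cols) {
    do.call(rbind, lapply(q, function(x) {
      tab <- x$tables[[kind]]
      keep <- intersect(cols, names(tab))
      out <- tab[keep]
      for (miss in setdiff(cols, keep)) out[[miss]] <- rep(NA_character_, nrow(tab))
      out[cols]
    }))
  }
  drug <- pool("DRUG", c("primaryid", "role_cod", "drugname"))
  reac <- pool("REAC", c("primaryid", "pt"))
  indi <- pool("INDI", c("primaryid", "indi_pt"))
  outc <- pool("OUTC", c("primaryid", "outc_cod"))
  rpsr <- pool("RPSR", c("primaryid", "rpsr_cod"))

  demo$caseversion <- suppressWarnings(as.integer(demo$caseversion))
  demo$caseversion[is.na(demo$caseversion)] <- 1L
  demo$fda_dt <- as.Date(demo$fda_dt, format = "%Y%m%d")
  demo$sex <- decode_sex(demo$sex)
  demo$age_years <- normalize_age(demo$age, demo$age_cod)

  known <- demo$primaryid
  orphan <- function(tab) sum(!(tab$primaryid %in% known))
  orphans <- c(DRUG = orphan(drug), REAC = orphan(reac), INDI = orphan(indi),
               OUTC = orphan(outc), RPSR = orphan(rpsr))

  drug <- drug[drug$primaryid %in% known, , drop = FALSE]
  reac <- reac[reac$primaryid %in% known, , drop = FALSE]
  indi <- indi[indi$primaryid %in% known, , drop = FALSE]
  outc <- outc[outc$primaryid %in% known, , drop = FALSE]
  rpsr <- rpsr[rpsr$primaryid %in% known, , drop = FALSE]

  drug$verbatim_name <- drug$drugname
  drug$normalized_name <- suppressWarnings(normalize_drug_name(drug$drugname, synonym_map))
  n_empty_names <- sum(is.na(drug$normalized_name))
  drug <- drug[!is.na(drug$normalized_name), , drop = FALSE]
  role_raw <- toupper(trimws(drug$role_cod))
  drug$role <- unname(.role_codes[role_raw])
  drug$role[is.na(drug$role)] <- "concomitant"
  drug <- drug[!duplicated(drug[c("primaryid", "normalized_name", "role")]),
               c("primaryid", "verbatim_name", "normalized_name", "role")]

  reac$pt <- squash_upper(reac$pt)
  reac <- reac[nzchar(reac$pt), c("primaryid", "pt")]
  reac <- reac[!duplicated(reac), , drop = FALSE]
  indi$pt <- squash_upper(indi$indi_pt)
  indi <- indi[nzchar(indi$pt), c("primaryid", "pt")]
  indi <- indi[!duplicated(indi), , drop = FALSE]

  has_drug <- demo$primaryid %in% drug$primaryid
  has_reac <- demo$primaryid %in% reac$primaryid
  n_no_drug <- sum(!has_drug)
  n_no_reac <- sum(has_drug & !has_reac)
  demo <- demo[has_drug & has_reac, , drop = FALSE]

  keep_children <- function(tab) tab[tab$primaryid %in% demo$primaryid, , drop = FALSE]
  res <- structure(
    list(
      demo = demo,
      drugs = keep_children(drug),
      reactions = keep_children(reac),
      indications = keep_children(indi),
      outcomes = keep_children(outc[c("primaryid", "outc_cod")]),
      sources = keep_children(rpsr[c("primaryid", "rpsr_cod")]),
      link_report = list(
        orphans = as.list(orphans),
        excluded_no_drug = n_no_drug,
        excluded_no_reaction = n_no_reac,
        dropped_empty_drug_names = n_empty_names
      )
    ),
    class = "faers_cases"
  )
  res
}

decode_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("undefined", length(x))
  out[x == "M"] <- "male"
  out[x == "F"] <- "female"
  out
}

#' Deduplicate case reports by case version
#'
#' FAERS cases (`caseid`) accumulate versions across quarters; one report per
#' case must be retained. Keeps the row with the highest `caseversion`; ties
#' broken by latest receipt date (`fda_dt`), then highest `primaryid`
#' (lexicographic). Output is sorted by `caseid`, so the result is
#' deterministic and the operation idempotent.
#'
#' @param cases a `faers_cases` object.
#' @return a `faers_cases` object with one report per `caseid`; child tables
#'   are restricted to the retained `primaryid`s.
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  if (!nrow(demo)) return(cases)
  date_key <- as.integer(demo$fda_dt)
  date_key[is.na(date_key)] <- -.Machine$integer.max
  ord <- order(demo$caseid,
               -demo$caseversion,
               -date_key,
               # lexicographic descending primaryid
               -xtfrm(demo$primaryid))
  demo <- demo[ord, , drop = FALSE]
  demo <- demo[!duplicated(demo$caseid), , drop = FALSE]
  demo <- demo[order(demo$caseid), , drop = FALSE]
  rownames(demo) <- NULL
  out <- cases
  out$demo <- demo
  for (tab in c("drugs", "reactions", "indications", "outcomes", "sources")) {
    out[[tab]] <- out[[tab]][out[[tab]]$primaryid %in% demo$primaryid, , drop = FALSE]
  }
  out$link_report$deduplicated <- nrow(cases$demo) - nrow(demo)
  out
}

#' Parse report as JSON
#'
#' Serializes the per-table parse counts of a `faers_raw` (and optionally the
#' linkage report of a `faers_cases`) to a JSON string or file.
#'
#' @param q a `faers_raw` object.
#' @param cases optional `faers_cases` whose link report is appended.
#' @param path optional output path; when given, JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
parse_report_json <- function(q, cases = NULL, path = NULL) {
  stopifnot(inherits(q, "faers_raw"))
  rep <- list(quarter = q$quarter, tables = q$parse_report)
  if (!is.null(cases)) rep$linkage <- cases$link_report
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("FAERS quarter", x$quarter, "\n")
  for (kind in names(x$tables)) {
    cat(sprintf("  %s: %d rows (%d dropped)\n", kind,
                x$parse_report[[kind]]$n_rows, x$parse_report[[kind]]$n_dropped))
  }
  invisible(x)
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("Linked FAERS cases:", nrow(x$demo), "reports,",
      length(unique(x$demo$caseid)), "unique caseids\n")
  cat("  drug rows:", nrow(x$drugs), " reaction rows:", nrow(x$reactions), "\n")
  invisible(x)
}
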