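# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from checked-in data files.

# Write dollar-delimited table files from character vectors of lines.
# `tables` maps kind -> c(header, row, row, ...). Any kind not given gets a
# header-only file so read_quarter's all-seven contract is satisfied.
write_fixture_quarter <- function(tables, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixq")
    dir.create(dir)
  }
  defaults <- list(
    DEMO = "primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
    DRUG = "primaryid$caseid$drug_seq$role_cod$drugname",
    REAC = "primaryid$caseid$pt",
    OUTC = "primaryid$caseid$outc_cod",
    RPSR = "primaryid$caseid$rpsr_cod",
    THER = "primaryid$caseid$dsg_drug_seq$start_dt$end_dt",
    INDI = "primaryid$caseid$indi_drug_seq$indi_pt"
  )
  paths <- character(0)
  for (kind in names(defaults)) {
    lines <- tables[[kind]] %||% defaults[[kind]]
    path <- file.path(dir, paste0(kind, "TEST.txt"))
    writeLines(lines, path)
    paths[kind] <- path
  }
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a

demo_row <- function(primaryid, caseid, caseversion = 1, fda_dt = "20170801",
                     age = "15", age_cod = "YR", sex = "M") {
  paste(primaryid, caseid, caseversion, fda_dt, age, age_cod, sex, sep = "$")
}
drug_row <- function(primaryid, drugname, role = "PS", seq = 1, caseid = primaryid) {
  paste(primaryid, caseid, seq, role, drugname, sep = "$")
}
reac_row <- function(primaryid, pt, caseid = primaryid) {
  paste(primaryid, caseid, pt, sep = "$")
}

# Build a faers_cohort directly from per-case specs:
#   list(drugs = c("A"), reactions = c("X"), sex = "male", age = 15)
mk_cohort <- function(specs) {
  n <- length(specs)
  pid <- sprintf("%d1", 100 + seq_len(n))
  demo <- data.frame(
    primaryid = pid, caseid = as.character(100 + seq_len(n)),
    caseversion = 1L, fda_dt = as.Date("2017-08-01"),
    age = vapply(specs, function(s) as.character(s$age %||% 15), character(1)),
    age_cod = "YR",
    sex = vapply(specs, function(s) s$sex %||% "male", character(1)),
    quarter = "testq",
    age_years = vapply(specs, function(s) as.numeric(s$age %||% 15), numeric(1)),
    stringsAsFactors = FALSE
  )
  expand <- function(field, col) {
    items <- lapply(specs, function(s) unique(toupper(s[[field]] %||% character(0))))
    data.frame(primaryid = rep(pid, lengths(items)),
               item = unlist(items), stringsAsFactors = FALSE) |>
      stats::setNames(c("primaryid", col))
  }
  drugs <- expand("drugs", "normalized_name")
  drugs$verbatim_name <- drugs$normalized_name
  drugs$role <- "primary_suspect"
  cases <- structure(
    list(demo = demo,
         drugs = drugs[c("primaryid", "verbatim_name", "normalized_name", "role")],
         reactions = expand("reactions", "pt"),
         indications = expand("indications", "pt"),
         outcomes = data.frame(primaryid = character(0), outc_cod = character(0)),
         sources = data.frame(primaryid = character(0), rpsr_cod = character(0)),
         link_report = list(orphans = list(), excluded_no_drug = 0L,
                            excluded_no_reaction = 0L)),
    class = "faers_cases"
  )
  structure(list(cases = cases,
                 filters = list(age_min_years = 0, age_max_years_exclusive = 130,
                                missing_age = "excluded", quarters = "testq"),
                 n_cases = n),
            class = "faers_cohort")
}

# the recovery world used by the simulation-based acceptance criteria:
# ten drugs at 15% prevalence, a case/control event pair with drug-free
# control, one injected signal
recovery_config <- function(n_cases = 4700, seed = 1, log_or = log(8)) {
  drugs <- sprintf("DRUG%02d", 1:10)
  synthetic_config(
    n_cases = n_cases, seed = seed,
    drug_catalog = data.frame(name = drugs, prevalence = rep(0.15, 10),
                              stringsAsFactors = FALSE),
    event_catalog = data.frame(pt = c("EVENT CASE", "EVENT CONTROL"),
                               baseline = c(0.25, 0.30),
                               stringsAsFactors = FALSE),
    signal_matrix = if (log_or != 0) {
      data.frame(drug = "DRUG01", pt = "EVENT CASE", log_or = log_or,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(drug = character(0), pt = character(0), log_or = numeric(0))
    },
    duplicate_rate = 0, both_event_rate = 0
  )
}

# 2x2 cells for one drug from the generator's indicator matrices, under the
# designated-control XOR design; independent of build_contingency
cells_from_matrices <- function(X, Y, drug, case_pt, ctrl_pt) {
  case_only <- Y[, case_pt] & !Y[, ctrl_pt]
  ctrl_only <- Y[, ctrl_pt] & !Y[, case_pt]
  x <- X[, drug]
  contingency_table(a = sum(x & case_only), b = sum(x & ctrl_only),
                    c = sum(!x & case_only), d = sum(!x & ctrl_only),
                    drug = drug, case_event = case_pt, control_event = ctrl_pt)
}
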