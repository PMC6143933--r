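# Synthetic FAERS quarter generator.
#
# The stated world: a spontaneous-report cohort shaped like the adolescent
# FAERS extract — sex split roughly even with a few percent undefined, ages
# recorded in mixed units straddling the 12-18 window, a drug catalog headed
# by risperidone at ~11% of reports, event baselines matching the printed
# reaction frequencies (diarrhoea 4.6%, hyperglycaemia 4.4%, ...), 10%
# duplicate case versions. Event assignment is per-case Bernoulli under a
# logistic model: logit P(event) = logit(baseline) + sum of log-OR terms of
# the case's exposures, independently across events given exposures.

.filler_event <- "DRUG INEFFECTIVE"

.default_background_drugs <- c(
  "MULTIVITAMINS", "ACETAMINOPHEN", "AMOXICILLIN", "ALBUTEROL",
  "CETIRIZINE", "OMEPRAZOLE", "MELATONIN", "FERROUS SULFATE",
  "CHOLECALCIFEROL", "LORATADINE", "AZITHROMYCIN", "SERTRALINE"
)

.default_indications <- c(
  "PROPHYLAXIS", "ACUTE LYMPHOCYTIC LEUKAEMIA",
  "PRODUCT USED FOR UNKNOWN INDICATION", "BIPOLAR DISORDER",
  "ATTENTION DEFICIT/HYPERACTIVITY DISORDER", "DEPRESSION",
  "SCHIZOPHRENIA", "PAIN", "NAUSEA", "EPILEPSY"
)

#' Configuration for the synthetic FAERS generator
#'
#' Defaults emulate the adolescent FAERS extract the package targets: sex
#' probabilities (0.478, 0.492, 0.030), drug catalog headed by risperidone
#' at 10.6% marginal prevalence, event baselines at the printed reaction
#' frequencies, a 10% duplicate-version rate, and ages sampled in mixed
#' units (years, months, days, weeks, decades, plus 3% missing) straddling
#' the 12-18 boundary.
#'
#' @param n_cases number of unique cases (before duplicate versions).
#' @param seed integer seed; generation is fully reproducible from it.
#' @param age_mixture list of components `list(code=, min=, max=, weight=)`;
#'   `code = NA` means missing age. Values are uniform on [min, max] in the
#'   unit's own scale.
#' @param sex_probs probabilities for (male, female, undefined); must sum
#'   to 1.
#' @param drug_catalog data frame with columns `name`, `prevalence`
#'   (independent Bernoulli marginals).
#' @param event_catalog data frame with columns `pt`, `baseline`
#'   (probability for an unexposed case).
#' @param signal_matrix data frame with columns `drug`, `pt`, `log_or`;
#'   sparse injected associations. Every entry must reference catalog rows.
#' @param background_drugs character vector of drug names with no injected
#'   signal; a case that draws no catalog drug receives one of these
#'   uniformly at random (FAERS cases always list at least one drug), so
#'   catalog marginal prevalences stay exactly Bernoulli. Must be disjoint
#'   from the catalog.
#' @param duplicate_rate probability a case gets a second case version.
#' @param both_event_rate probability a case is forced to mention both of
#'   the first two catalog events (exercises both-event exclusion).
#' @param quarter_label label such as `"2017q3"`; also sets receipt dates.
#' @return a validated `synthetic_config`.
#' @export
synthetic_config <- function(
    n_cases = 5000,
    seed = 20170930,
    age_mixture = list(
      list(code = "YR",  min = 6,    max = 20,   weight = 0.78),
      list(code = "MON", min = 72,   max = 240,  weight = 0.08),
      list(code = "DY",  min = 2200, max = 7300, weight = 0.04),
      list(code = "WK",  min = 310,  max = 1040, weight = 0.02),
      list(code = "DEC", min = 0.6,  max = 2.0,  weight = 0.05),
      list(code = NA,    min = 0,    max = 0,    weight = 0.03)
    ),
    sex_probs = c(male = 0.478, female = 0.492, undefined = 0.030),
    drug_catalog = data.frame(
      name = c("RISPERIDONE", "PREDNISOLONE SODIUM SUCCINATE", "INFLIXIMAB",
               "METHOTREXATE", "IBUPROFEN", "OLANZAPINE", "QUETIAPINE FUMARATE",
               "LORAZEPAM", "VALPROIC ACID", "DIAZEPAM",
               "ONDANSETRON HYDROCHLORIDE"),
      prevalence = c(0.106, 0.038, 0.034, 0.070, 0.050, 0.030, 0.030,
                     0.025, 0.020, 0.015, 0.012),
      stringsAsFactors = FALSE
    ),
    event_catalog = data.frame(
      pt = c("DIARRHOEA", "HYPERGLYCAEMIA", "GYNAECOMASTIA", "VOMITING",
             "DRUG INTERACTION", "COMPLETED SUICIDE", "PNEUMOTHORAX"),
      baseline = c(0.046, 0.030, 0.012, 0.030, 0.020, 0.005, 0.004),
      stringsAsFactors = FALSE
    ),
    signal_matrix = data.frame(
      drug = c("RISPERIDONE", "RISPERIDONE", "ONDANSETRON HYDROCHLORIDE",
               "IBUPROFEN", "VALPROIC ACID"),
      pt = c("HYPERGLYCAEMIA", "GYNAECOMASTIA", "PNEUMOTHORAX",
             "COMPLETED SUICIDE", "DRUG INTERACTION"),
      log_or = log(c(8, 6, 7, 12, 10)),
      stringsAsFactors = FALSE
    ),
    background_drugs = .default_background_drugs,
    duplicate_rate = 0.10,
    both_event_rate = 0.01,
    quarter_label = "2017q3") {

  if (!is.numeric(n_cases) || n_cases < 1) stop_cfg("n_cases must be >= 1")
  n_cases <- as.integer(n_cases)
  seed <- as.integer(seed)
  w <- vapply(age_mixture, function(m) m$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop_cfg("age_mixture weights must be nonnegative and sum to 1")
  }
  if (length(sex_probs) != 3 || any(sex_probs < 0) || abs(sum(sex_probs) - 1) > 1e-8) {
    stop_cfg("sex_probs must be a 3-simplex (male, female, undefined)")
  }
  drug_catalog$name <- squash_upper(drug_catalog$name)
  event_catalog$pt <- squash_upper(event_catalog$pt)
  if (any(drug_catalog$prevalence < 0) || any(drug_catalog$prevalence > 1) ||
      any(event_catalog$baseline < 0) || any(event_catalog$baseline > 1)) {
    stop_cfg("prevalences and baselines must lie in [0, 1]")
  }
  if (anyDuplicated(drug_catalog$name) || anyDuplicated(event_catalog$pt)) {
    stop_cfg("catalog names must be unique")
  }
  background_drugs <- squash_upper(background_drugs)
  if (!length(background_drugs) || anyDuplicated(background_drugs)) {
    stop_cfg("background_drugs must be a non-empty set of distinct names")
  }
  if (any(drug_catalog$name %in% background_drugs)) {
    stop_cfg("background drug names are reserved and may not appear in the ",
             "drug catalog: ",
             paste(intersect(drug_catalog$name, background_drugs), collapse = ", "))
  }
  if (.filler_event %in% event_catalog$pt) {
    stop_cfg("'", .filler_event, "' is the reserved filler reaction and may ",
             "not appear in the event catalog")
  }
  if (nrow(signal_matrix)) {
    signal_matrix$drug <- squash_upper(signal_matrix$drug)
    signal_matrix$pt <- squash_upper(signal_matrix$pt)
    bad <- !(signal_matrix$drug %in% drug_catalog$name) |
           !(signal_matrix$pt %in% event_catalog$pt)
    if (any(bad)) {
      stop_cfg("signal_matrix references unknown catalog entries: ",
               paste(unique(paste(signal_matrix$drug[bad],
                                  signal_matrix$pt[bad], sep = "/")),
                     collapse = ", "))
    }
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) stop_cfg("duplicate_rate must be in [0, 1)")
  if (both_event_rate < 0 || both_event_rate >= 1) stop_cfg("both_event_rate must be in [0, 1)")
  if (!grepl("^[0-9]{4}q[1-4]$", quarter_label)) {
    stop_cfg("quarter_label must look like '2017q3'")
  }
  structure(
    list(n_cases = n_cases, seed = seed, age_mixture = age_mixture,
         sex_probs = sex_probs, drug_catalog = drug_catalog,
         event_catalog = event_catalog, signal_matrix = signal_matrix,
         background_drugs = background_drugs,
         duplicate_rate = duplicate_rate, both_event_rate = both_event_rate,
         quarter_label = quarter_label),
    class = "synthetic_config"
  )
}

#' True injected log odds ratios
#'
#' One row per (catalog drug, catalog event) pair with the injected log-OR
#' (zero for pairs absent from the signal matrix). This is the same table
#' [simulate_cases()] uses to build its logistic sampling model, so recovery
#' tests compare against exactly what was generated.
#'
#' @param config a `synthetic_config`.
#' @return data frame with columns `drug`, `pt`, `log_or`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- expand.grid(drug = config$drug_catalog$name,
                      pt = config$event_catalog$pt,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$log_or <- 0
  sm <- config$signal_matrix
  if (nrow(sm)) {
    key <- paste(grid$drug, grid$pt, sep = "\r")
    hit <- match(paste(sm$drug, sm$pt, sep = "\r"), key)
    grid$log_or[hit] <- sm$log_or
  }
  grid[order(grid$drug, grid$pt), , drop = FALSE]
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a cohort of spontaneous reports in memory
#'
#' Draws demographics, exposures and events under the configured logistic
#' model and returns both the FAERS-layout tables and the underlying
#' exposure/event indicator matrices (handy for fast simulation studies
#' that bypass file I/O). Cases that draw no catalog drug receive the
#' reserved filler drug, and cases with no catalog event the reserved
#' filler reaction, so every case has non-empty lists while catalog
#' marginals stay exactly Bernoulli.
#'
#' @param config a `synthetic_config`.
#' @param tables build the seven FAERS tables (default `TRUE`); set `FALSE`
#'   in simulation studies that only need the indicator matrices, which is
#'   roughly an order of magnitude faster.
#' @return list with `tables` (named list of the seven FAERS character data
#'   frames, duplicates included; `NULL` when `tables = FALSE`),
#'   `exposures` and `events` (logical matrices over unique cases, columns
#'   named by catalog entries), `caseid`, and `truth` (see [truth_table()]).
#' @export
simulate_cases <- function(config, tables = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_cases
    caseid <- 10000000L + seq_len(n)
    pid1 <- sprintf("%.0f", as.numeric(caseid) * 10 + 1)

    # ages in mixed units
    w <- vapply(config$age_mixture, function(m) m$weight, numeric(1))
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    age <- character(n); age_cod <- character(n)
    for (k in seq_along(config$age_mixture)) {
      m <- config$age_mixture[[k]]
      idx <- which(comp == k)
      if (!length(idx)) next
      if (is.na(m$code)) {
        age[idx] <- ""; age_cod[idx] <- ""
      } else {
        v <- stats::runif(length(idx), m$min, m$max)
        age[idx] <- if (m$code == "DEC") sprintf("%.1f", v) else
          sprintf("%d", as.integer(round(v)))
        age_cod[idx] <- m$code
      }
    }

    sex <- sample(c("M", "F", ""), n, replace = TRUE, prob = config$sex_probs)

    # exposures: independent Bernoulli per catalog drug
    dn <- config$drug_catalog$name
    X <- matrix(stats::runif(n * length(dn)), n) <
         matrix(config$drug_catalog$prevalence, n, length(dn), byrow = TRUE)
    colnames(X) <- dn

    # events under the logistic model, using the shared truth table
    truth <- truth_table(config)
    en <- config$event_catalog$pt
    B <- matrix(0, length(dn), length(en), dimnames = list(dn, en))
    B[cbind(match(truth$drug, dn), match(truth$pt, en))] <- truth$log_or
    eta <- matrix(stats::qlogis(config$event_catalog$baseline),
                  n, length(en), byrow = TRUE) + (X + 0) %*% B
    Y <- matrix(stats::runif(n * length(en)), n) < stats::plogis(eta)
    colnames(Y) <- en
    if (length(en) >= 2 && config$both_event_rate > 0) {
      force_both <- stats::runif(n) < config$both_event_rate
      Y[force_both, 1:2] <- TRUE
    }

    if (!tables) {
      return(list(tables = NULL, exposures = X, events = Y, caseid = caseid,
                  truth = truth))
    }

    # receipt dates inside the quarter
    yr <- as.integer(substr(config$quarter_label, 1, 4))
    qn <- as.integer(substr(config$quarter_label, 6, 6))
    q_start <- as.Date(sprintf("%d-%02d-01", yr, (qn - 1) * 3 + 1))
    fda_dt <- format(q_start + sample.int(80, n, replace = TRUE) - 1L, "%Y%m%d")

    demo <- data.frame(
      primaryid = pid1, caseid = as.character(caseid), caseversion = "1",
      fda_dt = fda_dt, age = age, age_cod = age_cod,
      sex = sex, wt = "", wt_cod = "", occp_cod = "CN",
      reporter_country = "US", stringsAsFactors = FALSE
    )

    # long-format (case, item) pairs from an indicator matrix, with filler
    # items for cases whose row is all-FALSE; rows sorted by case then column
    melt_indicators <- function(M, items, filler_pool) {
      hit <- which(M, arr.ind = TRUE)
      ci <- hit[, 1]; item <- items[hit[, 2]]
      zero <- which(rowSums(M) == 0)
      fillers <- if (length(zero)) sample(filler_pool, length(zero), replace = TRUE)
                 else character(0)
      ci <- c(ci, zero); item <- c(item, fillers)
      ord <- order(ci, seq_along(ci))
      list(case = ci[ord], item = item[ord])
    }

    ex <- melt_indicators(X, dn, config$background_drugs)
    n_per <- tabulate(ex$case, n)
    drug_seq <- sequence(n_per[n_per > 0])
    drug1 <- data.frame(
      primaryid = pid1[ex$case], caseid = as.character(caseid[ex$case]),
      drug_seq = as.character(drug_seq),
      role_cod = ifelse(drug_seq == 1L, "PS",
                        sample(c("SS", "C", "I"), length(ex$case), replace = TRUE)),
      drugname = ex$item, stringsAsFactors = FALSE
    )

    ev <- melt_indicators(Y, en, .filler_event)
    reac1 <- data.frame(
      primaryid = pid1[ev$case], caseid = as.character(caseid[ev$case]),
      pt = ev$item, stringsAsFactors = FALSE
    )

    has_indi <- stats::runif(nrow(drug1)) < 0.7
    indi1 <- data.frame(
      primaryid = drug1$primaryid[has_indi], caseid = drug1$caseid[has_indi],
      indi_drug_seq = drug1$drug_seq[has_indi],
      indi_pt = sample(.default_indications, sum(has_indi), replace = TRUE),
      stringsAsFactors = FALSE
    )

    has_outc <- stats::runif(n) < 0.5
    outc1 <- data.frame(
      primaryid = pid1[has_outc], caseid = as.character(caseid[has_outc]),
      outc_cod = sample(c("HO", "OT", "LT", "DE", "DS"), sum(has_outc),
                        replace = TRUE, prob = c(0.45, 0.35, 0.08, 0.05, 0.07)),
      stringsAsFactors = FALSE
    )

    has_rpsr <- stats::runif(n) < 0.3
    rpsr1 <- data.frame(
      primaryid = pid1[has_rpsr], caseid = as.character(caseid[has_rpsr]),
      rpsr_cod = sample(c("FGN", "SDY", "HP", "CSM", "OTH"), sum(has_rpsr),
                        replace = TRUE),
      stringsAsFactors = FALSE
    )

    has_ther <- stats::runif(n) < 0.5
    ther1 <- data.frame(
      primaryid = pid1[has_ther], caseid = as.character(caseid[has_ther]),
      dsg_drug_seq = "1", start_dt = fda_dt[has_ther], end_dt = "",
      stringsAsFactors = FALSE
    )

    # duplicate case versions: identical content, caseversion 2, later receipt
    dup <- stats::runif(n) < config$duplicate_rate
    dup_case <- as.character(caseid[dup])
    pid2_of <- function(cid) sprintf("%.0f", as.numeric(cid) * 10 + 2)
    bump <- function(tab, pid_col = "primaryid") {
      sel <- tab[tab$caseid %in% dup_case, , drop = FALSE]
      if (!nrow(sel)) return(sel)
      sel[[pid_col]] <- pid2_of(sel$caseid)
      sel
    }
    demo2 <- bump(demo)
    if (nrow(demo2)) {
      demo2$caseversion <- "2"
      demo2$fda_dt <- format(as.Date(demo2$fda_dt, "%Y%m%d") + 7L, "%Y%m%d")
    }

    tables <- list(
      DEMO = rbind(demo, demo2),
      DRUG = rbind(drug1, bump(drug1)),
      REAC = rbind(reac1, bump(reac1)),
      OUTC = rbind(outc1, bump(outc1)),
      RPSR = rbind(rpsr1, bump(rpsr1)),
      THER = rbind(ther1, bump(ther1)),
      INDI = rbind(indi1, bump(indi1))
    )
    tables <- lapply(tables, function(tab) { rownames(tab) <- NULL; tab })
    list(tables = tables, exposures = X, events = Y, caseid = caseid,
         truth = truth)
  })
}

#' Generate synthetic FAERS quarter files on disk
#'
#' Runs [simulate_cases()] and writes the seven dollar-delimited tables into
#' `dir` (filenames `DEMO2017Q3.txt` etc.), plus the truth table as CSV.
#' Byte-identical output for a fixed config.
#'
#' @param config a `synthetic_config`.
#' @param dir output directory.
#' @return list with `paths` (named vector of table files), `truth_path`,
#'   `truth`, and `quarter_label`, invisibly.
#' @export
generate <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  sim <- simulate_cases(config)
  q <- structure(list(quarter = config$quarter_label, tables = sim$tables,
                      parse_report = NULL),
                 class = "faers_raw")
  paths <- write_quarter(q, dir, suffix = config$quarter_label)
  truth_path <- file.path(dir, paste0("truth_", config$quarter_label, ".csv"))
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(list(paths = paths, truth_path = truth_path, truth = sim$truth,
                 quarter_label = config$quarter_label))
}
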