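test_that("read_quarter parses dollar-delimited tables", {
  paths <- write_fixture_quarter(list(
    DEMO = c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
             demo_row("1011", "101"), demo_row("1021", "102", sex = "F")),
    DRUG = c("primaryid$caseid$drug_seq$role_cod$drugname",
             drug_row("1011", "RISPERIDONE 2 MG", role = "PS"))
  ))
  q <- read_quarter(paths, "2017q3")
  expect_s3_class(q, "faers_raw")
  expect_equal(nrow(q$tables$DEMO), 2)
  # embedded spaces preserved verbatim
  expect_equal(q$tables$DRUG$drugname, "RISPERIDONE 2 MG")
  # header-only REAC: empty table, no error
  expect_equal(nrow(q$tables$REAC), 0)
  expect_equal(q$parse_report$REAC$n_dropped, 0)
})

test_that("read_quarter drops malformed rows with a count and flags bad headers", {
  paths <- write_fixture_quarter(list(
    DEMO = c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
             demo_row("1011", "101"),
             "too$few$fields",
             demo_row("1021", "102"))
  ))
  q <- read_quarter(paths, "2017q3")
  expect_equal(nrow(q$tables$DEMO), 2)
  expect_equal(q$parse_report$DEMO$n_dropped, 1)
  expect_equal(q$parse_report$DEMO$n_data_lines, 3)

  # legacy gndr_cod spelling is aliased onto sex
  paths2 <- write_fixture_quarter(list(
    DEMO = c("primaryid$caseid$caseversion$fda_dt$age$age_cod$gndr_cod",
             demo_row("1011", "101"))
  ))
  expect_equal(read_quarter(paths2, "x")$tables$DEMO$sex, "M")

  # unknown dialect -> error listing the missing columns
  paths3 <- write_fixture_quarter(list(DEMO = c("foo$bar", "1$2")))
  expect_error(read_quarter(paths3, "x"), "missing column")

  paths4 <- write_fixture_quarter(list())
  paths4["DEMO"] <- "/nonexistent"
  expect_error(read_quarter(paths4, "x"), "DEMO")
})

test_that("write_quarter/read_quarter round-trips synthetic rows exactly", {
  cfg <- synthetic_config(n_cases = 60, seed = 11)
  dir <- tempfile(); gen <- generate(cfg, dir)
  q1 <- read_quarter(gen$paths, cfg$quarter_label)
  dir2 <- tempfile()
  paths2 <- write_quarter(q1, dir2, suffix = "RT")
  q2 <- read_quarter(paths2, cfg$quarter_label)
  expect_identical(q1$tables, q2$tables)
  for (k in names(q1$parse_report)) {
    expect_equal(q1$parse_report[[k]]$n_dropped, 0)
  }
})

test_that("normalize_drug_name trims, squashes and maps synonyms", {
  expect_equal(normalize_drug_name("  risperidone "), "RISPERIDONE")
  # salt forms stay distinct without an explicit synonym map
  expect_equal(normalize_drug_name("QUETIAPINE FUMARATE"), "QUETIAPINE FUMARATE")
  expect_equal(
    normalize_drug_name("Ondansetron  HCl",
                        c("ONDANSETRON HCL" = "ONDANSETRON HYDROCHLORIDE")),
    "ONDANSETRON HYDROCHLORIDE")
  expect_warning(res <- normalize_drug_name(c("A", "   ")), "dropped")
  expect_identical(res, c("A", NA_character_))
})

test_that("link_tables attaches children by primaryid and excludes orphans", {
  paths <- write_fixture_quarter(list(
    DEMO = c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
             demo_row("1011", "101"), demo_row("1021", "102")),
    DRUG = c("primaryid$caseid$drug_seq$role_cod$drugname",
             drug_row("1011", "A"), drug_row("1011", "B", role = "SS", seq = 2),
             drug_row("1011", "C", role = "C", seq = 3),
             drug_row("1021", "D"),
             drug_row("9999", "ORPHAN")),
    REAC = c("primaryid$caseid$pt",
             reac_row("1011", "Nausea"), reac_row("1011", "Rash"))
  ))
  cases <- link_tables(read_quarter(paths, "t"))
  # case 1011: 3 drugs, 2 reactions; case 1021 has no reactions -> excluded
  expect_equal(nrow(cases$demo), 1)
  expect_equal(sum(cases$drugs$primaryid == "1011"), 3)
  expect_equal(sort(cases$reactions$pt), c("NAUSEA", "RASH"))
  expect_equal(cases$link_report$orphans$DRUG, 1)
  expect_equal(cases$link_report$excluded_no_reaction, 1)
  # conservation: every DRUG row is attached, orphaned, or dropped with an
  # excluded case (1021's single drug row)
  attached <- nrow(cases$drugs)
  orphaned <- cases$link_report$orphans$DRUG
  excluded_case_rows <- 1
  expect_equal(attached + orphaned + excluded_case_rows, 5)
})

test_that("deduplicate keeps the highest caseversion with stated tie-breaks", {
  paths <- write_fixture_quarter(list(
    DEMO = c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
             demo_row("1011", "101", 1), demo_row("1012", "101", 2),
             # caseid 102: version tie, later fda_dt wins
             demo_row("1021", "102", 1, fda_dt = "20170101"),
             demo_row("1022", "102", 1, fda_dt = "20170601"),
             # caseid 103: full tie, higher primaryid wins
             demo_row("1031", "103", 1), demo_row("1039", "103", 1)),
    DRUG = c("primaryid$caseid$drug_seq$role_cod$drugname",
             drug_row("1011", "A"), drug_row("1012", "A"), drug_row("1021", "A"),
             drug_row("1022", "A"), drug_row("1031", "A"), drug_row("1039", "A")),
    REAC = c("primaryid$caseid$pt",
             reac_row("1011", "X"), reac_row("1012", "X"), reac_row("1021", "X"),
             reac_row("1022", "X"), reac_row("1031", "X"), reac_row("1039", "X"))
  ))
  linked <- link_tables(read_quarter(paths, "t"))
  dd <- deduplicate(linked)
  expect_equal(dd$demo$primaryid, c("1012", "1022", "1039"))
  # caseid set preserved, count never increases
  expect_setequal(dd$demo$caseid, unique(linked$demo$caseid))
  expect_lte(nrow(dd$demo), nrow(linked$demo))
  # idempotence
  expect_identical(deduplicate(dd)$demo, dd$demo)
})

test_that("deduplicate retains all distinct caseids", {
  cfg <- synthetic_config(n_cases = 50, seed = 3, duplicate_rate = 0)
  gen <- generate(cfg, tempfile())
  linked <- link_tables(read_quarter(gen$paths, cfg$quarter_label))
  expect_equal(nrow(deduplicate(linked)$demo), 50)
})

test_that("parse_report_json serializes counts", {
  cfg <- synthetic_config(n_cases = 20, seed = 5)
  gen <- generate(cfg, tempfile())
  q <- read_quarter(gen$paths, cfg$quarter_label)
  js <- jsonlite::fromJSON(parse_report_json(q, link_tables(q)))
  expect_equal(js$quarter, "2017q3")
  expect_true(all(c("DEMO", "REAC") %in% names(js$tables)))
  expect_named(js$linkage$orphans, ignore.order = TRUE,
               expected = c("DRUG", "REAC", "INDI", "OUTC", "RPSR"))
})
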