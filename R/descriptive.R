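# Frequency tables and per-drug drill-downs.
#
# Two denominator conventions coexist on purpose. Cohort-level tables divide
# by the number of cases in the cohort (case-count semantics: a case counts
# once per distinct item). Drill-downs divide by the total number of distinct
# (case, item) mentions in the sub-cohort, so percentages over all items sum
# to 100. Published FAERS frequency tables mix both conventions, so each
# output is labelled with the convention used.

dimension_table <- function(cohort, dimension = c("drug", "reaction", "indication")) {
  dimension <- match.arg(dimension)
  cases <- cohort$cases
  switch(dimension,
    drug = data.frame(primaryid = cases$drugs$primaryid,
                      item = cases$drugs$normalized_name,
                      stringsAsFactors = FALSE),
    reaction = data.frame(primaryid = cases$reactions$primaryid,
                          item = cases$reactions$pt, stringsAsFactors = FALSE),
    indication = data.frame(primaryid = cases$indications$primaryid,
                            item = cases$indications$pt, stringsAsFactors = FALSE)
  )
}

freq_from_mentions <- function(mentions, demo, denominator, top_n, convention) {
  # collapse within-case duplicates: a case contributes once per distinct item
  mentions <- mentions[!duplicated(mentions[c("primaryid", "item")]), , drop = FALSE]
  if (!nrow(mentions)) {
    out <- data.frame(item = character(0), count = integer(0),
                      n_male = integer(0), n_female = integer(0),
                      n_undefined = integer(0), pct = numeric(0))
    attr(out, "denominator") <- denominator
    attr(out, "convention") <- convention
    class(out) <- c("freq_table", class(out))
    return(out)
  }
  sex <- demo$sex[match(mentions$primaryid, demo$primaryid)]
  sex[!(sex %in% c("male", "female"))] <- "undefined"
  agg <- table(factor(mentions$item), factor(sex, levels = c("male", "female", "undefined")))
  count <- rowSums(agg)
  out <- data.frame(item = rownames(agg),
                    count = as.integer(count),
                    n_male = as.integer(agg[, "male"]),
                    n_female = as.integer(agg[, "female"]),
                    n_undefined = as.integer(agg[, "undefined"]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$item), , drop = FALSE]
  out$pct <- round_half_up(100 * out$count / denominator, 2)
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  attr(out, "denominator") <- denominator
  attr(out, "convention") <- convention
  class(out) <- c("freq_table", class(out))
  out
}

#' Frequency table for drugs, reactions, or indications
#'
#' Counts, per distinct item, the number of cohort cases mentioning it
#' (within-case duplicate mentions collapse to one), with a sex breakdown per
#' item. Rows sort by count descending, ties broken alphabetically, and the
#' table is truncated to `top_n`. Percentages use the cohort case count as
#' denominator and are rounded half-up to 2 decimals.
#'
#' @param cohort a `faers_cohort`.
#' @param dimension one of `"drug"`, `"reaction"`, `"indication"`.
#' @param top_n number of rows to keep (default 15).
#' @return a `freq_table` data frame with columns `item`, `count`, `n_male`,
#'   `n_female`, `n_undefined`, `pct`, carrying `denominator` and
#'   `convention` attributes.
#' @export
frequency_table <- function(cohort, dimension = c("drug", "reaction", "indication"),
                            top_n = 15) {
  stopifnot(inherits(cohort, "faers_cohort"), top_n >= 1)
  mentions <- dimension_table(cohort, dimension)
  freq_from_mentions(mentions, cohort$cases$demo,
                     denominator = max(cohort$n_cases, 1L),
                     top_n = top_n, convention = "cohort_cases")
}

#' Reaction and indication profile of one drug
#'
#' Restricts the cohort to cases listing the drug (any role by default) and
#' tabulates their reactions and indications. Unlike [frequency_table()],
#' the denominator is the total number of distinct (case, item) mentions in
#' the sub-cohort for that dimension, so the untruncated percentages sum
#' to 100.
#'
#' @param cohort a `faers_cohort`.
#' @param drug normalized drug name (see [normalize_drug_name()]).
#' @param top_n rows to keep in each table (default 10).
#' @param roles `"all"` (default) or `"suspect"` to require PS/SS roles.
#' @return list with `reactions` and `indications` `freq_table`s and
#'   `n_cases`, the sub-cohort size.
#' @export
drug_drilldown <- function(cohort, drug, top_n = 10, roles = c("all", "suspect")) {
  stopifnot(inherits(cohort, "faers_cohort"), is_string(drug), top_n >= 1)
  roles <- match.arg(roles)
  ids <- exposed_ids(cohort, drug, roles)
  sub <- cohort
  sub$cases$demo <- cohort$cases$demo[cohort$cases$demo$primaryid %in% ids, , drop = FALSE]
  sub$n_cases <- nrow(sub$cases$demo)
  one <- function(dimension) {
    mentions <- dimension_table(sub, dimension)
    mentions <- mentions[mentions$primaryid %in% ids, , drop = FALSE]
    mentions <- mentions[!duplicated(mentions[c("primaryid", "item")]), , drop = FALSE]
    freq_from_mentions(mentions, sub$cases$demo,
                       denominator = max(nrow(mentions), 1L),
                       top_n = top_n, convention = "dimension_mentions")
  }
  list(reactions = one("reaction"), indications = one("indication"),
       n_cases = sub$n_cases)
}

# primaryids of cohort cases exposed to `drug` under the role policy
exposed_ids <- function(cohort, drug, roles = c("all", "suspect")) {
  roles <- match.arg(roles)
  drugs <- cohort$cases$drugs
  hit <- drugs$normalized_name == squash_upper(drug)
  if (roles == "suspect") {
    hit <- hit & drugs$role %in% c("primary_suspect", "secondary_suspect")
  }
  unique(drugs$primaryid[hit])
}

#' Read a drug-gene annotation table
#'
#' Loads a user-supplied tab-separated table with columns `drug`, `gene`,
#' `score` (a nonnegative relevance score, e.g. exported from a gene-drug
#' knowledge base). Validates uniqueness of (drug, gene) pairs.
#'
#' @param path TSV path with a header line.
#' @return data frame with columns `drug`, `gene`, `score`.
#' @export
read_gene_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "gene", "score")
  if (!all(need %in% names(tab))) {
    stop_cfg("gene annotation table must have columns drug, gene, score; saw: ",
             paste(names(tab), collapse = ", "))
  }
  tab <- tab[need]
  tab$drug <- squash_upper(tab$drug)
  tab$score <- as.numeric(tab$score)
  if (any(!is.finite(tab$score) | tab$score < 0)) {
    stop_cfg("gene annotation scores must be finite and nonnegative")
  }
  if (anyDuplicated(tab[c("drug", "gene")])) {
    stop_cfg("duplicate (drug, gene) pairs in annotation table")
  }
  tab
}

#' Top genes annotated to a drug
#'
#' Ranks the genes annotated to a drug by relevance score, descending, ties
#' broken by gene symbol ascending, and returns the top `k`.
#'
#' @param drug drug name (normalized internally).
#' @param annotations data frame as returned by [read_gene_annotations()].
#' @param k number of genes (default 10); if larger than the table, the full
#'   sorted table is returned.
#' @return data frame with columns `gene`, `score`, at most `k` rows (empty
#'   when the drug is absent).
#' @export
rank_genes <- function(drug, annotations, k = 10) {
  stopifnot(is_string(drug), k >= 1)
  sub <- annotations[annotations$drug == squash_upper(drug), , drop = FALSE]
  sub <- sub[order(-sub$score, sub$gene), c("gene", "score"), drop = FALSE]
  sub <- utils::head(sub, k)
  rownames(sub) <- NULL
  sub
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Frequency table (%s denominator = %d)\n",
              attr(x, "convention"), attr(x, "denominator")))
  print.data.frame(x, ...)
  invisible(x)
}
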