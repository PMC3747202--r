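# Population-based exclusion: classify individuals by tag-SNP genotypes into
# risk-allele carrier classes, then drop candidates that are common among
# negative-class individuals.

POP_CLASSES <- c("RISK_POS", "CONFOUNDER_POS", "NEGATIVE")

#' Validate a tag-SNP genotype-to-class rule table
#'
#' The rule table maps the joint diploid genotypes at two tag SNPs (dosages
#' of the tagging allele, 0/1/2 each) to a carrier class: `RISK_POS`
#' (predicted risk-allele carrier), `CONFOUNDER_POS` (carrier of the
#' inconclusive confounding allele, removed from comparisons) or `NEGATIVE`.
#' The mapping must be total: all nine joint genotypes, each exactly once.
#'
#' @param rules Tibble with columns `g_tag1`, `g_tag2`, `class`.
#' @return The validated tibble (invisibly usable downstream).
#' @export
validate_tag_rules <- function(rules) {
  rules <- as_tibble(rules)
  if (!all(c("g_tag1", "g_tag2", "class") %in% names(rules))) {
    abort("rule table needs columns g_tag1, g_tag2, class.")
  }
  full <- tidyr::expand_grid(g_tag1 = 0:2, g_tag2 = 0:2)
  got <- distinct(rules, .data$g_tag1, .data$g_tag2)
  if (nrow(rules) != 9 || nrow(dplyr::inner_join(full, got,
      by = c("g_tag1", "g_tag2"))) != 9) {
    abort("rule table must map all 9 joint tag genotypes exactly once.")
  }
  if (!all(rules$class %in% POP_CLASSES)) {
    abort(sprintf("rule classes must be one of: %s",
      paste(POP_CLASSES, collapse = ", ")))
  }
  rules
}

#' Classify population individuals from tag-SNP genotypes
#'
#' Deterministic lookup of each individual's joint tag genotype in the rule
#' table. Individuals with a missing tag genotype are classed `UNKNOWN` and
#' take no part in carrier counting; `CONFOUNDER_POS` individuals are
#' likewise excluded downstream.
#'
#' @param tag_genotypes Tibble with columns `individual`, `g_tag1`,
#'   `g_tag2` (dosages 0/1/2 or `NA`).
#' @param rules Rule table, see [validate_tag_rules()].
#' @return Tibble `individual`, `class`.
#' @export
classify_individuals <- function(tag_genotypes, rules) {
  rules <- validate_tag_rules(rules)
  tg <- as_tibble(tag_genotypes)
  out <- left_join(tg, rules, by = c("g_tag1", "g_tag2"))
  out$class[is.na(out$g_tag1) | is.na(out$g_tag2)] <- "UNKNOWN"
  select(out, "individual", "class")
}

#' Exclude candidates common among negative-class individuals
#'
#' For each candidate variant, counts the `NEGATIVE`-class individuals
#' carrying it (dosage >= 1; or carrier chromosomes, i.e. the dosage sum,
#' with `count_chromosomes = TRUE`) and drops the candidate when the count
#' strictly exceeds `max_negative_carriers`. Candidates absent from the
#' population panel's site list cannot fail an unobservable filter and are
#' kept with `negative_carriers = NA`.
#'
#' @param candidates Candidate tibble with `pos`, `ref`, `alt`.
#' @param pop_genotypes Wide genotype tibble for the population panel: one
#'   row per site with `pos`, `ref`, `alt` and one dosage column per
#'   individual.
#' @param classes Tibble `individual`, `class` from
#'   [classify_individuals()] (or generator truth).
#' @param max_negative_carriers Drop when the carrier count is strictly
#'   greater than this (default 10).
#' @param count_chromosomes Count carrier chromosomes instead of carrier
#'   individuals.
#' @return `candidates` annotated with `negative_carriers` and `kept`; the
#'   final candidate set is `dplyr::filter(out, kept)`.
#' @export
carrier_exclusion <- function(candidates, pop_genotypes, classes,
                              max_negative_carriers = 10,
                              count_chromosomes = FALSE) {
  candidates <- as_tibble(candidates)
  pop <- as_tibble(pop_genotypes)
  neg_ids <- classes$individual[classes$class == "NEGATIVE"]
  neg_ids <- intersect(neg_ids, names(pop))
  counts <- rep(NA_integer_, nrow(candidates))
  if (length(neg_ids) > 0 && nrow(pop) > 0) {
    key_pop <- paste(pop$pos, pop$ref, pop$alt)
    key_cand <- paste(candidates$pos, candidates$ref, candidates$alt)
    idx <- match(key_cand, key_pop)
    dos <- as.matrix(pop[neg_ids])
    for (i in which(!is.na(idx))) {
      d <- dos[idx[i], ]
      counts[i] <- if (count_chromosomes) {
        sum(d, na.rm = TRUE)
      } else {
        sum(d >= 1, na.rm = TRUE)
      }
    }
  }
  mutate(candidates,
    negative_carriers = counts,
    kept = is.na(counts) | counts <= max_negative_carriers
  )
}
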