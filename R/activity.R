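## Active/inactive classification of TEs from protein-domain hits, and the
## bootstrap comparing active vs inactive singleton counts within genomes.

#' Pfam domains marking potentially active TEs
#'
#' The six transposition-associated domains used for the activity call:
#' the three DDE transposase families, retrotransposon gag, the integrase
#' core domain and the retroviral aspartyl protease. A TE with at least one
#' hit to any of these is called potentially active; with none, inactive.
#'
#' @return named character vector of Pfam accessions.
#' @export
activePfamDomains <- function() {
  c(DDE_1 = "PF03184", DDE_2 = "PF02914", DDE_3 = "PF13358",
    gag = "PF03732", integrase = "PF00665", protease = "PF00077")
}

#' Classify TEs as potentially active or inactive
#'
#' A record is active iff it has at least one domain hit to the whitelist
#' (default [activePfamDomains()]). Ids without any hit — including ids
#' supplied via `ids` that never appear in `domainHits` — are inactive.
#'
#' @param domainHits domain hit table (see [readDomainTable()]); the
#'   `copy_id` column may hold copy ids or family/consensus ids depending
#'   on what was searched.
#' @param ids optional character vector of ids that must appear in the
#'   output even without hits.
#' @param targets whitelist of Pfam accessions.
#' @return data.frame with columns `id`, `active`, `matched_domains`
#'   (`;`-separated accessions, empty string when inactive).
#' @export
classifyActivity <- function(domainHits, ids = NULL,
                             targets = activePfamDomains()) {
  checkColumns(domainHits, c("copy_id", "pfam_accession"), "domain hits")
  all_ids <- unique(c(domainHits$copy_id, ids))
  hitMatch <- domainHits[domainHits$pfam_accession %in% targets, ,
                         drop = FALSE]
  matched <- lapply(split(hitMatch$pfam_accession, hitMatch$copy_id),
                    function(x) sort(unique(x)))
  out <- data.frame(
    id = all_ids,
    active = all_ids %in% names(matched),
    matched_domains = vapply(all_ids, function(i)
      paste(matched[[i]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split per-genome singleton counts by activity
#'
#' Singleton families (TE nodes of degree 1 in the content network) are
#' split into potentially active and inactive using family-level activity
#' calls, yielding per-genome counts of each; the DNMT (or PIWI) group
#' comparison is then run separately on the two splits. Families with no
#' activity call are counted as inactive (no domain found).
#'
#' @param net a [ContentNetwork-class].
#' @param activityCalls output of [classifyActivity()] keyed by family id.
#' @param annotations species annotation table.
#' @param grouping `"has_dnmt"` (default) or `"has_piwi"`.
#' @return list with `perGenome` (data.frame: `genome_id`,
#'   `active_singletons`, `inactive_singletons`, `n_singletons`, annotation
#'   columns) and `tests` (list of [TestResult-class] for the active and
#'   inactive splits).
#' @export
singletonsByActivity <- function(net, activityCalls, annotations,
                                 grouping = "has_dnmt") {
  g <- asIgraph(net)
  validateAnnotations(annotations)
  activeIds <- activityCalls$id[activityCalls$active]
  deg <- igraph::degree(g)
  genomes <- genomeNodeIds(net)
  rows <- lapply(genomes, function(v) {
    nb <- igraph::neighbors(g, v)
    sing <- nb$name[deg[nb$name] == 1]
    data.frame(genome_id = v,
               active_singletons = sum(sing %in% activeIds),
               inactive_singletons = sum(!sing %in% activeIds),
               n_singletons = length(sing), stringsAsFactors = FALSE)
  })
  perGenome <- do.call(rbind, rows)
  idx <- match(perGenome$genome_id, annotations$genome_id)
  perGenome <- cbind(perGenome,
                     annotations[idx, setdiff(names(annotations),
                                              "genome_id"), drop = FALSE])
  rownames(perGenome) <- NULL
  tests <- list(
    active = groupComparison(perGenome, grouping, "active_singletons")$test,
    inactive = groupComparison(perGenome, grouping,
                               "inactive_singletons")$test)
  list(perGenome = perGenome, tests = tests)
}

#' Bootstrap of active vs inactive singleton counts
#'
#' Repeatedly samples `sampleSize` genomes from a group (30 genomes, 1,000
#' repetitions by default) and, within each resample, tests active against
#' inactive singleton counts with a Wilcoxon test — paired (signed-rank) by
#' default, since both counts come from the same genome; set
#' `paired = FALSE` for the rank-sum variant. Sampling is without
#' replacement when the group is large enough, otherwise with replacement
#' (with a warning).
#'
#' @param perGenome data.frame with `genome_id`, `active_singletons`,
#'   `inactive_singletons` (as from [singletonsByActivity()]).
#' @param genomes character vector naming the group to resample from
#'   (default: all rows).
#' @param sampleSize genomes per resample (default 30).
#' @param reps number of resamples (default 1000).
#' @param seed RNG seed.
#' @param paired use the signed-rank test on within-genome differences?
#' @return list with `pValues` (numeric vector of length `reps`) and
#'   `summary` (quantiles of the p-value distribution).
#' @export
bootstrapSingletons <- function(perGenome, genomes = NULL, sampleSize = 30,
                                reps = 1000, seed = 0, paired = TRUE) {
  if (sampleSize < 2) stop("sampleSize must be at least 2")
  checkColumns(perGenome, c("genome_id", "active_singletons",
                            "inactive_singletons"), "per-genome counts")
  if (is.null(genomes)) genomes <- perGenome$genome_id
  pool <- perGenome[perGenome$genome_id %in% genomes, , drop = FALSE]
  if (!nrow(pool)) stop("no genomes to resample from")
  replace <- nrow(pool) < sampleSize
  if (replace)
    warning("group has ", nrow(pool), " < ", sampleSize,
            " genomes; sampling with replacement")
  pv <- withSeed(seed, vapply(seq_len(reps), function(r) {
    i <- sample(nrow(pool), sampleSize, replace = replace)
    a <- pool$active_singletons[i]
    b <- pool$inactive_singletons[i]
    res <- if (paired) {
      d <- a - b
      if (all(d == 0)) return(1)
      suppressWarnings(suppressMessages(wilcoxonSignedRank(d)))
    } else wilcoxonRankSum(a, b)
    pValue(res)
  }, numeric(1)))
  list(pValues = pv,
       summary = stats::quantile(pv, c(0.025, 0.25, 0.5, 0.75, 0.975)))
}
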