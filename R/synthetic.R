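## Synthetic TE landscape and alignment-hit generators. These emulate the
## statistical structure of a multi-genome TE survey — clade-shared and
## species-private families, silencing-regime effects on family richness
## and copy number, orthogroup counts decaying with phylogenetic distance,
## planted convergent-similarity segments and planted horizontal transfer —
## so every pipeline stage can be validated against known ground truth.
## Similarity is modelled at the hit level; no nucleotide sequences are
## simulated.

#' Configuration for the synthetic TE landscape
#'
#' Defaults describe a survey of 40 species in 4 clades where half the
#' species carry the piRNA pathway and half carry DNA methylation
#' (independently assigned). piRNA+ species draw twice as many shared
#' families, each with half the copies, so total TE content is matched in
#' expectation between regimes and any degree/weighted-degree dissociation
#' is the planted signal rather than a content confound. DNMT+ species
#' additionally accumulate extra inactive species-private (singleton)
#' families. Orthogroup counts start at `orthoMax` within a clade and decay
#' exponentially with the between-clade tree distance, so that the default
#' genome-genome threshold of 4,500 retains only within-clade pairs.
#'
#' @param nSpecies number of species (default 40).
#' @param nClades number of clades, species split evenly (default 4).
#' @param piwiFraction,dnmtFraction fraction of species carrying each
#'   silencing pathway (default 0.5 each, assigned independently).
#' @param famMeanNoPiwi mean number of clade-shared families per piRNA-
#'   species (default 8).
#' @param famRatioPiwi multiplier on family richness for piRNA+ species
#'   (default 2).
#' @param copyMeanNoPiwi mean copies per family for piRNA- species
#'   (default 6).
#' @param copyRatioPiwi multiplier on copies/family for piRNA+ species
#'   (default 0.5).
#' @param privateMean mean number of species-private (singleton) families
#'   per species (default 2).
#' @param inactiveSingletonMeanDnmt mean number of extra inactive singleton
#'   families in DNMT+ species (default 3).
#' @param lengthMeanlog,lengthSdlog log-normal copy length parameters
#'   (default meanlog log(800), sdlog 0.45; lengths floored at 50 bp).
#' @param orthoMax expected shared-orthogroup count for a within-clade pair
#'   (default 9000).
#' @param orthoDecay exponential decay rate per unit of between-clade tree
#'   distance (default 0.8).
#' @param orthoNoiseSd gaussian noise on orthogroup counts (default 150).
#' @param nSuperfamilies number of superfamily labels (default 6).
#' @param dominantSuperfamily label of the superfamily drawn with extra
#'   weight, producing the node-count imbalance seen for dominant
#'   superfamilies in real surveys (default `"Gypsy"`).
#' @param dominantWeight sampling weight multiplier for the dominant
#'   superfamily (default 4).
#' @param regimeByClade assign the silencing regimes to whole clades
#'   instead of independent species (default `FALSE`)? Clade-uniform
#'   regimes model lineages such as flies, where every sampled species
#'   shares the same silencing machinery, and are the relevant setting for
#'   group-level comparisons after phylogenetic collapsing.
#' @param seed RNG seed; mandatory.
#' @return a [LandscapeConfig-class].
#' @export
landscapeConfig <- function(nSpecies = 40, nClades = 4,
                            piwiFraction = 0.5, dnmtFraction = 0.5,
                            famMeanNoPiwi = 8, famRatioPiwi = 2,
                            copyMeanNoPiwi = 6, copyRatioPiwi = 0.5,
                            privateMean = 2, inactiveSingletonMeanDnmt = 3,
                            lengthMeanlog = log(800), lengthSdlog = 0.45,
                            orthoMax = 9000, orthoDecay = 0.8,
                            orthoNoiseSd = 150, nSuperfamilies = 6,
                            dominantSuperfamily = "Gypsy",
                            dominantWeight = 4, regimeByClade = FALSE,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  new("LandscapeConfig", nSpecies = as.integer(nSpecies),
      nClades = as.integer(nClades), piwiFraction = piwiFraction,
      dnmtFraction = dnmtFraction, famMeanNoPiwi = famMeanNoPiwi,
      famRatioPiwi = famRatioPiwi, copyMeanNoPiwi = copyMeanNoPiwi,
      copyRatioPiwi = copyRatioPiwi, privateMean = privateMean,
      inactiveSingletonMeanDnmt = inactiveSingletonMeanDnmt,
      lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
      orthoMax = orthoMax, orthoDecay = orthoDecay,
      orthoNoiseSd = orthoNoiseSd,
      nSuperfamilies = as.integer(nSuperfamilies),
      dominantSuperfamily = dominantSuperfamily,
      dominantWeight = dominantWeight, regimeByClade = regimeByClade,
      seed = as.integer(seed))
}

#' Simulate a multi-genome TE landscape
#'
#' Pure function of the configuration (including its seed): the same
#' config yields byte-identical output. See [landscapeConfig()] for the
#' generative model.
#'
#' @param cfg a [LandscapeConfig-class].
#' @return list with `copies` (TE copy table), `annotations` (species
#'   table), `orthoTable` ([OrthoTable-class]) and `truth`, a list of
#'   planted ground truth: `familyActivity` (family, active, singleton),
#'   `cladeOf` (named vector), regime assignments.
#' @export
simulateLandscape <- function(cfg) {
  stopifnot(is(cfg, "LandscapeConfig"))
  withSeed(cfg@seed, {
    n <- cfg@nSpecies
    species <- sprintf("sp%03d", seq_len(n))
    clades <- paste0("clade", LETTERS[seq_len(cfg@nClades)])
    cladeOf <- setNames(clades[((seq_len(n) - 1) %% cfg@nClades) + 1],
                        species)
    if (cfg@regimeByClade) {
      pw <- setNames(rep(FALSE, cfg@nClades), clades)
      pw[sample(cfg@nClades, round(cfg@piwiFraction * cfg@nClades))] <- TRUE
      dn <- setNames(rep(FALSE, cfg@nClades), clades)
      dn[sample(cfg@nClades, round(cfg@dnmtFraction * cfg@nClades))] <- TRUE
      hasPiwi <- setNames(unname(pw[cladeOf]), species)
      hasDnmt <- setNames(unname(dn[cladeOf]), species)
    } else {
      hasPiwi <- setNames(rep(FALSE, n), species)
      hasPiwi[sample(n, round(cfg@piwiFraction * n))] <- TRUE
      hasDnmt <- setNames(rep(FALSE, n), species)
      hasDnmt[sample(n, round(cfg@dnmtFraction * n))] <- TRUE
    }

    supers <- c(cfg@dominantSuperfamily,
                paste0("SF", seq_len(max(0, cfg@nSuperfamilies - 1))))
    superProb <- c(cfg@dominantWeight, rep(1, length(supers) - 1))

    ## clade-shared family pools, sized so the richest regime rarely
    ## exhausts them
    poolSize <- ceiling(3 * cfg@famMeanNoPiwi * max(1, cfg@famRatioPiwi))
    pools <- lapply(clades, function(cl)
      sprintf("%s.fam%03d", cl, seq_len(poolSize)))
    names(pools) <- clades
    famSuper <- list()
    for (cl in clades)
      famSuper[[cl]] <- setNames(
        sample(supers, poolSize, replace = TRUE, prob = superProb),
        pools[[cl]])

    copyRows <- list()
    famActive <- list()
    for (s in species) {
      cl <- cladeOf[s]
      famLambda <- cfg@famMeanNoPiwi *
        if (hasPiwi[s]) cfg@famRatioPiwi else 1
      copyLambda <- cfg@copyMeanNoPiwi *
        if (hasPiwi[s]) cfg@copyRatioPiwi else 1
      nShared <- min(rpoisPos(1, famLambda), poolSize)
      shared <- sample(pools[[cl]], nShared)
      nPriv <- stats::rpois(1, cfg@privateMean)
      priv <- if (nPriv) sprintf("%s.priv%02d", s, seq_len(nPriv))
              else character()
      privActive <- if (nPriv) stats::runif(nPriv) < 0.5 else logical()
      nInact <- if (hasDnmt[s])
        stats::rpois(1, cfg@inactiveSingletonMeanDnmt) else 0L
      inact <- if (nInact) sprintf("%s.old%02d", s, seq_len(nInact))
               else character()
      fams <- c(shared, priv, inact)
      famsSuper <- c(famSuper[[cl]][shared],
                     setNames(sample(supers, nPriv + nInact, replace = TRUE,
                                     prob = superProb), c(priv, inact)))
      famActive[[s]] <- data.frame(
        family = c(priv, inact), active = c(privActive, rep(FALSE, nInact)),
        singleton = rep(TRUE, nPriv + nInact), stringsAsFactors = FALSE)
      if (!length(fams)) next
      nCopies <- rpoisPos(length(fams), copyLambda)
      fam <- rep(fams, nCopies)
      lens <- pmax(50L, as.integer(round(stats::rlnorm(
        length(fam), cfg@lengthMeanlog, cfg@lengthSdlog))))
      starts <- cumsum(c(0L, utils::head(lens, -1) + 500L))
      copyRows[[s]] <- data.frame(
        genome_id = s, seq_id = "scaffold_1",
        start = starts, end = starts + lens,
        strand = sample(c("+", "-"), length(fam), replace = TRUE),
        family = fam, superfamily = unname(famsSuper[fam]),
        length_bp = lens, stringsAsFactors = FALSE)
    }
    copies <- do.call(rbind, copyRows)
    copies$copy_id <- sprintf("%s:%s:%d-%d:%s:%s#%d",
                              copies$genome_id, copies$seq_id, copies$start,
                              copies$end, copies$strand, copies$family,
                              seq_len(nrow(copies)))
    copies$provenance <- "native"
    copies <- copies[, c("copy_id", "genome_id", "seq_id", "start", "end",
                         "strand", "family", "superfamily", "length_bp",
                         "provenance")]
    rownames(copies) <- NULL

    annotations <- data.frame(
      genome_id = species, clade_label = unname(cladeOf),
      has_dnmt = unname(hasDnmt), has_piwi = unname(hasPiwi),
      genome_size_bp = as.integer(round(stats::rlnorm(
        n, log(1e8), 0.3))), stringsAsFactors = FALSE)

    ## orthogroup counts: clades arranged on a balanced topology; distance
    ## 1 within a clade, 2 between sister clades, 3 otherwise
    cladeIdx <- setNames(seq_along(clades), clades)
    m <- matrix(NA_real_, n, n, dimnames = list(species, species))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ci <- cladeIdx[cladeOf[species[i]]]
      cj <- cladeIdx[cladeOf[species[j]]]
      d <- if (ci == cj) 1
           else if ((ci - 1) %/% 2 == (cj - 1) %/% 2) 2 else 3
      v <- cfg@orthoMax * exp(-cfg@orthoDecay * (d - 1)) +
        stats::rnorm(1, 0, cfg@orthoNoiseSd)
      m[i, j] <- m[j, i] <- max(0, round(v))
    }

    sharedTruth <- do.call(rbind, lapply(clades, function(cl)
      data.frame(family = pools[[cl]],
                 active = TRUE, singleton = FALSE,
                 stringsAsFactors = FALSE)))
    truthActivity <- rbind(sharedTruth, do.call(rbind, famActive))
    truthActivity <- truthActivity[
      truthActivity$family %in% copies$family, , drop = FALSE]
    rownames(truthActivity) <- NULL

    list(copies = copies, annotations = annotations,
         orthoTable = new("OrthoTable", counts = m),
         truth = list(familyActivity = truthActivity,
                      cladeOf = cladeOf, hasPiwi = hasPiwi,
                      hasDnmt = hasDnmt))
  })
}

#' Configuration for the synthetic alignment-hit generator
#'
#' Within-family copy pairs receive hits with probability `withinDensity`
#' and bitscores around `withinMean`; between-family pairs receive hits at
#' `betweenDensity`/`betweenMean` (no between-family hits by default). An
#' optional convergent segment shared by two designated families
#' (the analogue of two subfamilies independently co-opting the same host
#' gene sequence) adds moderate-bitscore cross-family hits so the pair
#' merges into one mixed cluster; the planted ordering
#' within > convergent > between is enforced. Families listed in
#' `dde3Families` model recently active transposase-bearing elements:
#' their copies are fully connected within the family and receive DDE3
#' (PF13358) domain hits.
#'
#' @param withinMean,withinSd within-family bitscore mean/sd (default
#'   300/25 bits).
#' @param withinDensity probability of a within-family edge (default 0.7).
#' @param betweenMean,betweenDensity background cross-family hits (default
#'   0/0: none).
#' @param convergentPair character(2) of family names sharing the
#'   convergent segment, or character(0) for none.
#' @param convergentMean,convergentDensity bitscore mean and pair density
#'   of the convergent-segment hits (default 150 bits, 0.5).
#' @param dde3Families families flagged as DDE3-positive.
#' @param seed RNG seed; mandatory.
#' @return a [HitModelConfig-class].
#' @export
hitModelConfig <- function(withinMean = 300, withinSd = 25,
                           withinDensity = 0.7, betweenMean = 0,
                           betweenDensity = 0,
                           convergentPair = character(),
                           convergentMean = 150, convergentDensity = 0.5,
                           dde3Families = character(), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  new("HitModelConfig", withinMean = withinMean, withinSd = withinSd,
      withinDensity = withinDensity, betweenMean = betweenMean,
      betweenDensity = betweenDensity,
      convergentPair = as.character(convergentPair),
      convergentMean = convergentMean,
      convergentDensity = convergentDensity,
      dde3Families = as.character(dde3Families), seed = as.integer(seed))
}

hitRow <- function(qid, sid, score, qlen, slen) {
  alen <- as.integer(pmax(50, round(pmin(qlen, slen) * 0.8)))
  data.frame(query_id = qid, subject_id = sid,
             pct_identity = round(stats::runif(length(qid), 80, 99), 1),
             aln_length = alen, mismatches = as.integer(round(alen * 0.05)),
             gap_opens = 1L, qstart = 1L, qend = alen,
             sstart = 1L, send = alen,
             evalue = 10^(-pmax(1, score / 8)),
             bitscore = score, stringsAsFactors = FALSE)
}

samplePairs <- function(ids1, ids2 = NULL, density) {
  if (is.null(ids2)) {
    if (length(ids1) < 2) return(NULL)
    pr <- t(utils::combn(ids1, 2))
  } else {
    if (!length(ids1) || !length(ids2)) return(NULL)
    pr <- as.matrix(expand.grid(ids1, ids2, stringsAsFactors = FALSE))
  }
  keep <- stats::runif(nrow(pr)) < density
  if (!any(keep)) return(NULL)
  pr[keep, , drop = FALSE]
}

#' Simulate alignment and domain hits over a TE copy table
#'
#' Pure function of `(copies, cfg)`; see [hitModelConfig()] for the model.
#' Copies planted by [plantHorizontalTransfer()] carry their donor family
#' name, so within-family hits automatically tie them to the donor copies.
#'
#' @param copies TE copy table.
#' @param cfg a [HitModelConfig-class].
#' @return list with `hits` (12-column alignment hit table) and `domains`
#'   (domain hit table with PF13358 rows for DDE3-flagged copies).
#' @export
simulateHits <- function(copies, cfg) {
  stopifnot(is(cfg, "HitModelConfig"))
  validateCopies(copies)
  withSeed(cfg@seed, {
    lens <- setNames(copies$length_bp, copies$copy_id)
    byFam <- split(copies$copy_id, copies$family)
    out <- list()
    for (f in names(byFam)) {
      dens <- if (f %in% cfg@dde3Families) 1 else cfg@withinDensity
      pr <- samplePairs(byFam[[f]], density = dens)
      if (is.null(pr)) next
      sc <- pmax(30, stats::rnorm(nrow(pr), cfg@withinMean, cfg@withinSd))
      out[[length(out) + 1]] <- hitRow(pr[, 1], pr[, 2], round(sc, 1),
                                       lens[pr[, 1]], lens[pr[, 2]])
    }
    if (cfg@betweenDensity > 0 && length(byFam) > 1) {
      fams <- names(byFam)
      for (i in seq_len(length(fams) - 1)) for (j in seq(i + 1, length(fams))) {
        pr <- samplePairs(byFam[[fams[i]]], byFam[[fams[j]]],
                          cfg@betweenDensity)
        if (is.null(pr)) next
        sc <- pmax(25, stats::rnorm(nrow(pr), cfg@betweenMean,
                                    cfg@withinSd))
        out[[length(out) + 1]] <- hitRow(pr[, 1], pr[, 2], round(sc, 1),
                                         lens[pr[, 1]], lens[pr[, 2]])
      }
    }
    if (length(cfg@convergentPair) == 2) {
      fa <- cfg@convergentPair[1]; fb <- cfg@convergentPair[2]
      miss <- setdiff(c(fa, fb), names(byFam))
      if (length(miss))
        stop("convergent family not in copies: ", paste(miss, collapse = ", "))
      pr <- samplePairs(byFam[[fa]], byFam[[fb]], cfg@convergentDensity)
      if (!is.null(pr)) {
        sc <- pmax(25, stats::rnorm(nrow(pr), cfg@convergentMean,
                                    cfg@withinSd))
        out[[length(out) + 1]] <- hitRow(pr[, 1], pr[, 2], round(sc, 1),
                                         lens[pr[, 1]], lens[pr[, 2]])
      }
    }
    hits <- if (length(out)) do.call(rbind, out) else
      hitRow(character(), character(), numeric(), integer(), integer())
    rownames(hits) <- NULL

    dde3Copies <- copies$copy_id[copies$family %in% cfg@dde3Families]
    domains <- data.frame(
      copy_id = dde3Copies,
      pfam_accession = rep("PF13358", length(dde3Copies)),
      domain_name = rep("DDE_3", length(dde3Copies)),
      evalue = rep(1e-20, length(dde3Copies)),
      env_start = rep(10L, length(dde3Copies)),
      env_end = rep(120L, length(dde3Copies)),
      stringsAsFactors = FALSE)
    list(hits = hits, domains = domains)
  })
}

#' Plant a horizontal transfer event
#'
#' Adds `nCopies` new copies of a donor family to a recipient genome,
#' labelled with the donor family name and marked `provenance = "hgt"`, so
#' a subsequent [simulateHits()] ties them to the donor copies and the
#' rebuilt similarity network should place them in the donor family's
#' cluster — the simulated five-copy cross-species transfer scenario.
#'
#' @param copies TE copy table.
#' @param donorFamily family to transfer (must be present in
#'   `donorGenome`).
#' @param donorGenome,recipientGenome genome ids.
#' @param nCopies number of transferred copies (default 5); 0 returns the
#'   input unchanged.
#' @param seed RNG seed for the copied lengths.
#' @return the augmented copy table, with a `provenance` column
#'   (`"native"`/`"hgt"`).
#' @export
plantHorizontalTransfer <- function(copies, donorFamily, donorGenome,
                                    recipientGenome, nCopies = 5, seed = 0) {
  validateCopies(copies)
  donors <- copies[copies$family == donorFamily &
                   copies$genome_id == donorGenome, , drop = FALSE]
  if (!nrow(donors))
    stop("family '", donorFamily, "' not present in donor genome '",
         donorGenome, "'")
  if (!recipientGenome %in% copies$genome_id)
    stop("unknown recipient genome '", recipientGenome, "'")
  if (!"provenance" %in% names(copies)) copies$provenance <- "native"
  if (nCopies == 0) return(copies)
  withSeed(seed, {
    lens <- sample(donors$length_bp, nCopies, replace = TRUE)
    starts <- cumsum(c(0L, utils::head(lens, -1) + 500L))
    newRows <- data.frame(
      copy_id = sprintf("%s:hgt_scaffold:%d-%d:+:%s#hgt%d",
                        recipientGenome, starts, starts + lens,
                        donorFamily, seq_len(nCopies)),
      genome_id = recipientGenome, seq_id = "hgt_scaffold",
      start = starts, end = starts + lens, strand = "+",
      family = donorFamily,
      superfamily = donors$superfamily[1], length_bp = lens,
      provenance = "hgt", stringsAsFactors = FALSE)
    out <- rbind(copies, newRows)
    rownames(out) <- NULL
    out
  })
}
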