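# In-code fixtures and independent brute-force oracles used across the suite.

# Minimal copy table: one row per (genome, family) copy, deterministic ids.
makeCopies <- function(spec) {
  # spec: data.frame(genome_id, family, n, len) -> expanded copy table
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    len <- rep(spec$len[i], length.out = n)
    starts <- cumsum(c(0L, head(len, -1) + 100L))
    data.frame(genome_id = spec$genome_id[i], seq_id = "chr1",
               start = starts, end = starts + len, strand = "+",
               family = spec$family[i],
               superfamily = if ("superfamily" %in% names(spec))
                 spec$superfamily[i] else "DNA/Generic",
               length_bp = len, stringsAsFactors = FALSE)
  })
  copies <- do.call(rbind, rows)
  copies$copy_id <- sprintf("%s:%s#%d", copies$genome_id, copies$family,
                            ave(seq_len(nrow(copies)),
                                paste(copies$genome_id, copies$family),
                                FUN = seq_along))
  copies[, c("copy_id", "genome_id", "seq_id", "start", "end", "strand",
             "family", "superfamily", "length_bp")]
}

makeAnnotations <- function(genomes, hasDnmt = NULL, hasPiwi = NULL,
                            sizes = NULL) {
  n <- length(genomes)
  data.frame(genome_id = genomes,
             clade_label = rep(c("cladeA", "cladeB"), length.out = n),
             has_dnmt = if (is.null(hasDnmt)) rep(TRUE, n) else hasDnmt,
             has_piwi = if (is.null(hasPiwi)) rep(TRUE, n) else hasPiwi,
             genome_size_bp = if (is.null(sizes)) rep(1e6L, n) else sizes,
             stringsAsFactors = FALSE)
}

# A hit row with only the fields the builders care about populated.
makeHits <- function(q, s, bitscore, evalue = 1e-50) {
  n <- length(q)
  if (n == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(query_id = q, subject_id = s,
             pct_identity = 95, aln_length = 100L, mismatches = 5L,
             gap_opens = 1L, qstart = 1L, qend = 100L, sstart = 1L,
             send = 100L, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

writeRepeatMaskerFixture <- function(path, rows) {
  # rows: data.frame(seq, begin, end, strand, family, class)
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  body <- sprintf(
    "  %d  %.1f  %.1f  %.1f  %s  %d  %d  (%d)  %s  %s  %s  %d  (%d)  %d",
    1000 + seq_len(nrow(rows)), 10.0, 1.0, 1.0, rows$seq, rows$begin,
    rows$end, 0L, rows$strand, rows$family, rows$class,
    rows$end - rows$begin + 1L, 0L, seq_len(nrow(rows)))
  writeLines(c(header, body), path)
  path
}

# ---- independent oracles ----

randIndexBrute <- function(m1, m2) {
  m2 <- m2[names(m1)]
  ids <- names(m1)
  n <- length(ids)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    total <- total + 1L
    same1 <- m1[ids[i]] == m1[ids[j]]
    same2 <- m2[ids[i]] == m2[ids[j]]
    if (same1 == same2) agree <- agree + 1L
  }
  agree / total
}

# Exact two-sided rank-sum p by enumerating all rank assignments (no ties).
rankSumBrute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all <- combn(nx + ny, nx)
  ws <- colSums(matrix(seq_len(nx + ny)[all], nrow = nx)) -
    nx * (nx + 1) / 2
  pl <- mean(ws <= wObs); pg <- mean(ws >= wObs)
  min(1, 2 * min(pl, pg))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
signedRankBrute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  pl <- mean(vs <= vObs); pg <- mean(vs >= vObs)
  min(1, 2 * min(pl, pg))
}

# Two-sided Fisher p as the hypergeometric sum of tables with fixed margins
# whose probability does not exceed the observed one.
fisherBrute <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Connected components by boolean transitive closure.
componentsBrute <- function(edges, nodes) {
  reach <- diag(length(nodes)) > 0
  dimnames(reach) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    reach[edges$from[i], edges$to[i]] <- TRUE
    reach[edges$to[i], edges$from[i]] <- TRUE
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  memb <- integer(length(nodes)); names(memb) <- nodes
  cid <- 0L
  for (v in nodes) {
    if (memb[v] == 0L) {
      cid <- cid + 1L
      memb[reach[v, ]] <- cid
    }
  }
  memb
}

# Small planted-cluster hit simulator used by several suites: k families of
# size m, fully parameterised through hitModelConfig.
plantedSSN <- function(k = 8, m = 8, seed = 1, ...) {
  spec <- data.frame(genome_id = "sp1",
                     family = sprintf("fam%02d", seq_len(k)),
                     n = m, len = 500L)
  copies <- makeCopies(spec)
  sim <- simulateHits(copies, hitModelConfig(seed = seed, ...))
  list(copies = copies, hits = sim$hits, domains = sim$domains)
}
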