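## Parsers for the annotation and alignment formats the pipeline consumes.
## All genomic coordinates are stored 0-based half-open internally; the
## RepeatMasker dialect (1-based inclusive) is converted at the boundary.

#' Read a RepeatMasker annotation table
#'
#' Parses the whitespace-delimited `.out` dialect (three header lines, then
#' one row per annotated repeat). Each row becomes one TE copy record with
#' coordinates converted from 1-based inclusive to 0-based half-open, strand
#' `"C"` mapped to `"-"`, and a synthesised unique `copy_id` of the form
#' `genome:seq:start-end:strand:family#n`.
#'
#' Repeats whose class/family is `Unknown` or `Unclassified` are excluded by
#' default, mirroring the global exclusion of unclassified repeats applied
#' throughout the analyses; set `includeUnclassified = TRUE` to keep them.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @param genomeId species/assembly identifier attached to every copy (the
#'   file itself does not name the genome).
#' @param includeUnclassified keep rows classified Unknown/Unclassified?
#' @return data.frame with columns `copy_id`, `genome_id`, `seq_id`,
#'   `start`, `end`, `strand`, `family`, `superfamily`, `length_bp`.
#' @export
readRepeatMasker <- function(path, genomeId, includeUnclassified = FALSE) {
  lines <- readLines(path)
  body <- if (length(lines) > 3) lines[-(1:3)] else character()
  keep <- nzchar(trimws(body))
  lineNo <- which(keep) + 3L
  body <- body[keep]
  if (!length(body)) {
    warning("no annotation rows in ", path)
    return(emptyCopies())
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 11)
      stop("malformed RepeatMasker row at line ", lineNo[i], ": expected >= 11 fields, got ",
           length(f))
    begin <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end) || end < begin)
      stop("malformed coordinates at line ", lineNo[i])
    strand <- f[9]
    if (!strand %in% c("+", "C", "-"))
      stop("malformed strand '", strand, "' at line ", lineNo[i])
    out[[i]] <- data.frame(
      genome_id = genomeId, seq_id = f[5],
      start = begin - 1L, end = end,
      strand = if (strand == "C") "-" else strand,
      family = f[10], superfamily = f[11],
      stringsAsFactors = FALSE)
  }
  copies <- do.call(rbind, out)
  if (!includeUnclassified) {
    drop <- grepl("^(Unknown|Unclassified)", copies$superfamily,
                  ignore.case = TRUE)
    copies <- copies[!drop, , drop = FALSE]
  }
  if (!nrow(copies)) {
    warning("all annotation rows in ", path, " were filtered out")
    return(emptyCopies())
  }
  copies$length_bp <- copies$end - copies$start
  copies$copy_id <- sprintf("%s:%s:%d-%d:%s:%s#%d",
                            copies$genome_id, copies$seq_id, copies$start,
                            copies$end, copies$strand, copies$family,
                            seq_len(nrow(copies)))
  rownames(copies) <- NULL
  copies[, c("copy_id", "genome_id", "seq_id", "start", "end", "strand",
             "family", "superfamily", "length_bp")]
}

emptyCopies <- function() {
  data.frame(copy_id = character(), genome_id = character(),
             seq_id = character(), start = integer(), end = integer(),
             strand = character(), family = character(),
             superfamily = character(), length_bp = integer(),
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular alignment hit table
#'
#' The standard tabular local-alignment format: query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bitscore. Self-hits (query == subject) are
#' dropped and their count reported with a message.
#'
#' @param path path to the tab-separated hit table (no header).
#' @return data.frame of hits with named columns; zero rows for an empty file.
#' @export
readAlignmentHits <- function(path, dropSelfHits = TRUE) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    hits <- as.data.frame(setNames(rep(list(character()), 12), cols))
    hits[3:12] <- lapply(hits[3:12], as.numeric)
    return(hits)
  }
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12)
    stop("expected 12 tab-separated columns, found ", ncol(hits))
  names(hits) <- cols
  bs <- suppressWarnings(as.numeric(hits$bitscore))
  if (anyNA(bs))
    stop("non-numeric bitscore at line ", which(is.na(bs))[1])
  hits$bitscore <- bs
  for (col in c("pct_identity", "evalue"))
    hits[[col]] <- as.numeric(hits[[col]])
  for (col in c("aln_length", "mismatches", "gap_opens", "qstart", "qend",
                "sstart", "send"))
    hits[[col]] <- as.integer(hits[[col]])
  if (dropSelfHits) {
    self <- hits$query_id == hits$subject_id
    if (any(self))
      message("dropped ", sum(self), " self-hit(s)")
    hits <- hits[!self, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Read a HMMER per-domain hit table
#'
#' Parses the `domtblout` dialect written by `hmmsearch --domtblout`
#' (`#`-prefixed comment lines, whitespace-delimited columns). One record is
#' produced per domain row whose independent e-value passes `maxEvalue`.
#' Profile accession versions (e.g. `PF13358.12`) are stripped to the bare
#' Pfam accession.
#'
#' @param path path to a domtblout file.
#' @param maxEvalue per-domain (independent) e-value ceiling; default `1e-5`.
#' @return data.frame with columns `copy_id`, `pfam_accession`,
#'   `domain_name`, `evalue`, `env_start`, `env_end`.
#' @export
readDomainTable <- function(path, maxEvalue = 1e-5) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(copy_id = character(), pfam_accession = character(),
                      domain_name = character(), evalue = numeric(),
                      env_start = integer(), env_end = integer(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  fields <- strsplit(trimws(body), "[[:space:]]+")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 22)
      stop("malformed domain table row ", i, ": expected >= 22 fields")
    acc <- sub("\\..*$", "", f[5])
    if (acc == "-" || !grepl("^PF[0-9]{5}$", acc))
      stop("missing or malformed profile accession '", f[5], "' in row ", i)
    data.frame(copy_id = f[1], pfam_accession = acc, domain_name = f[4],
               evalue = as.numeric(f[13]),
               env_start = as.integer(f[20]), env_end = as.integer(f[21]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= maxEvalue, , drop = FALSE]
  rownames(hits) <- NULL
  if (!nrow(hits)) empty else hits
}

#' Read a shared-orthogroup count table
#'
#' Accepts either a long format with three columns (`genome_a`, `genome_b`,
#' `shared_orthogroups`; header optional) or a labelled square matrix with
#' genome ids as the first row and first column. Symmetry is enforced: if a
#' pair is reported in both orientations with different counts, an error is
#' raised.
#'
#' @param path path to the TSV table.
#' @return an [OrthoTable-class] object.
#' @export
readOrthoTable <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (length(first) == 3) {
    hasHeader <- is.na(suppressWarnings(as.numeric(first[3])))
    long <- utils::read.delim(path, header = hasHeader,
                              stringsAsFactors = FALSE)
    names(long) <- c("genome_a", "genome_b", "shared_orthogroups")
    return(orthoTableFromPairs(long))
  }
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m)))
    stop("orthogroup matrix must be square with matching genome labels")
  m <- m[rownames(m), rownames(m)]
  if (any(m[row(m) != col(m)] < 0, na.rm = TRUE))
    stop("negative orthogroup counts")
  if (!isTRUE(all.equal(m, t(m))))
    stop("orthogroup matrix is not symmetric")
  diag(m) <- NA_real_
  new("OrthoTable", counts = m)
}

#' Build an OrthoTable from long-format pair counts
#'
#' @param pairs data.frame with columns `genome_a`, `genome_b`,
#'   `shared_orthogroups`.
#' @return an [OrthoTable-class] object.
#' @export
orthoTableFromPairs <- function(pairs) {
  checkColumns(pairs, c("genome_a", "genome_b", "shared_orthogroups"),
               "orthogroup pair table")
  if (any(pairs$shared_orthogroups < 0))
    stop("negative orthogroup counts")
  ids <- sort(unique(c(pairs$genome_a, pairs$genome_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$genome_a[i]; b <- pairs$genome_b[i]
    v <- pairs$shared_orthogroups[i]
    if (a == b) next
    prev <- m[a, b]
    if (!is.na(prev) && prev != v)
      stop("inconsistent counts for pair (", a, ", ", b, "): ",
           prev, " vs ", v)
    m[a, b] <- v
    m[b, a] <- v
  }
  new("OrthoTable", counts = m)
}

#' Validate a TE copy table
#'
#' Checks the internal copy-table contract: required columns present,
#' `end > start`, `length_bp == end - start`, strand in `{+,-}` and unique
#' `copy_id`s. Called by the network builders; exported because synthetic or
#' externally assembled tables should be checked at the boundary too.
#'
#' @param copies data.frame of TE copies.
#' @return the validated table, invisibly.
#' @export
validateCopies <- function(copies) {
  checkColumns(copies, c("copy_id", "genome_id", "seq_id", "start", "end",
                         "strand", "family", "superfamily", "length_bp"),
               "copy table")
  if (nrow(copies)) {
    if (any(copies$end <= copies$start))
      stop("copy intervals must satisfy end > start")
    if (any(copies$length_bp != copies$end - copies$start))
      stop("length_bp must equal end - start")
    if (!all(copies$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (anyDuplicated(copies$copy_id))
      stop("duplicate copy_id(s): ",
           paste(unique(copies$copy_id[duplicated(copies$copy_id)])[1:3],
                 collapse = ", "))
  }
  invisible(copies)
}

#' Validate a species annotation table
#'
#' @param annotations data.frame with `genome_id`, `clade_label`,
#'   `has_dnmt`, `has_piwi` and (optionally) `genome_size_bp`.
#' @param requireSize require positive genome sizes (needed by the
#'   percent-of-genome abundance metric)?
#' @return the validated table, invisibly.
#' @export
validateAnnotations <- function(annotations, requireSize = FALSE) {
  checkColumns(annotations, c("genome_id", "clade_label", "has_dnmt",
                              "has_piwi"), "annotation table")
  if (anyDuplicated(annotations$genome_id))
    stop("duplicate genome_id in annotations")
  if (requireSize) {
    checkColumns(annotations, "genome_size_bp", "annotation table")
    if (any(is.na(annotations$genome_size_bp)) ||
        any(annotations$genome_size_bp <= 0))
      stop("genome_size_bp must be > 0 for percentage metrics")
  }
  invisible(annotations)
}
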