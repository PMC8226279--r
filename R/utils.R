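## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a record table to the canonical tab-separated form
#'
#' Plain TSV with a header row, no quoting, no row names; `NA` written as
#' the literal string `NA`. [readTsv()] restores column types by standard
#' type conversion, so a write/read round trip reproduces the table exactly
#' for the integer/double/logical/character columns used throughout.
#'
#' @param x data.frame.
#' @param path output file.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeTsv
#' @return for `readTsv`, a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Require that a data.frame carries a set of columns.
checkColumns <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(x)
}

## >=1 truncated Poisson draw.
rpoisPos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) {
    i <- x == 0
    x[i] <- stats::rpois(sum(i), lambda)
  }
  x
}

## Majority value of a vector plus the fraction of entries agreeing with it.
majorityVote <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  list(value = names(tab)[1], agreement = as.numeric(tab[1]) / length(x))
}
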