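# Small internal helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a fixed seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so seeded generators never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an explicit integer `seed` is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, staying well inside
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}

#' Write a data frame as TSV with a reproducible numeric format
#'
#' Doubles are written with 12 significant digits so identical inputs give
#' byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  df2 <- df
  num <- vapply(df2, is.double, TRUE)
  df2[num] <- lapply(df2[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by this package
#'
#' Columns are converted to numeric or logical only when every entry parses
#' as such; bare `"F"`/`"T"` stay character (they are sex codes, not
#' logicals, in this package's tables — base `read.table` would silently
#' turn a single `"F"` into `FALSE`).
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("expected file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  raw[] <- lapply(raw, function(x) {
    num <- suppressWarnings(as.numeric(x))
    if (all(is.na(num) == (x == "NA"))) return(num)
    if (all(x %in% c("TRUE", "FALSE"))) return(as.logical(x))
    x
  })
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
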