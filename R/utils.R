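## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

## Row-wise softmax on a logit matrix; numerically stable.
softmax_rows <- function(z) {
  z <- as.matrix(z)
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## One-hot encode an integer vector (1-based) into n classes.
one_hot <- function(idx, n) {
  out <- matrix(0, length(idx), n)
  ok <- !is.na(idx)
  out[cbind(which(ok), idx[ok])] <- 1
  out
}

## Clamp probabilities away from 0/1 before taking logs.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

## Guess the field delimiter of a delimited text file from its first line.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

## Read a small delimited file into a character matrix, keeping track of the
## original line number of every row (for error messages).  Blank lines and
## lines starting with '#' are skipped.
read_delim_rows <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    return(list(rows = matrix(character(), 0L, n_fields), lines = integer()))
  delim <- sniff_delim(path)
  parts <- strsplit(lines[keep], delim, fixed = TRUE)
  lens <- lengths(parts)
  bad <- lens != n_fields
  if (any(bad)) {
    stop(sprintf("malformed %s row at line %d of '%s': expected %d fields, found %d",
                 what, keep[which(bad)[1L]], path, n_fields, lens[which(bad)[1L]]),
         call. = FALSE)
  }
  rows <- matrix(trimws(unlist(parts)), ncol = n_fields, byrow = TRUE)
  ## optional header: first row whose leading field is clearly a column label
  if (nrow(rows) > 0L &&
      grepl("^(species|sample|#|id$)", tolower(rows[1L, 1L]))) {
    rows <- rows[-1L, , drop = FALSE]
    keep <- keep[-1L]
  }
  list(rows = rows, lines = keep)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
}
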