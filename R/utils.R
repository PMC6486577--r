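#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the strict A/C/G/T alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

## uppercase + alphabet check for sequence inputs
clean_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (length(x) != 1L || is.na(x) || !is.character(x))
    stop(sprintf("%s must be a single DNA string", what), call. = FALSE)
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L)
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(sprintf("%s contains characters outside A/C/G/T: %s", what, x),
         call. = FALSE)
  x
}

## split equal-length strings into a character matrix (n x width);
## avoids per-string strsplit on large vectors
seq_matrix <- function(x, width = NULL) {
  if (is.null(width)) width <- nchar(x[1L])
  stopifnot(all(nchar(x) == width))
  m <- matrix("", nrow = length(x), ncol = width)
  for (j in seq_len(width)) m[, j] <- substr(x, j, j)
  m
}

## run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## derive a child seed from a base seed, staying below 2^31
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}
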