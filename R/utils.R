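#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rexp rgamma rgeom rnorm rpois runif
#'   optim nls coef pchisq predict setNames quantile
#' @importFrom utils read.delim write.table head
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stopf("'%s' must be positive", name)
  invisible(x)
}

#' Derive a named substream seed from a top-level seed
#'
#' All generators in the package draw their randomness from one top-level
#' seed through named substreams, so each simulation stage can be
#' regenerated independently of the order in which stages run.
#'
#' @param seed Integer top-level seed.
#' @param name Character substream name.
#' @return An integer seed in `[0, 2^31 - 1)`, a deterministic function of
#'   `(seed, name)`.
#' @examples
#' substream_seed(1, "junctions") != substream_seed(1, "endseq")
#' @export
substream_seed <- function(seed, name) {
  seed <- check_count(seed, "seed")
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 2147483647
  as.integer((seed * 7919 + h) %% 2147483647)
}

# Run code under a substream seed without disturbing the caller's RNG state.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

valid_dna <- function(x, name = "sequence", allow_empty = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single character string", name)
  if (!allow_empty && nchar(x) == 0L) stopf("'%s' must be non-empty", name)
  if (grepl("[^ACGTN]", x)) stopf("'%s' must be uppercase ACGTN", name)
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random ACGT string(s); vectorised over n.
random_dna <- function(len, n = 1L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Write and read whitespace-delimited tables with headers
#'
#' Thin wrappers fixing the dialect used throughout the package: TSV, header
#' row, no quoting, no row names. Ground-truth tables round-trip through
#' these unchanged.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write/read a single-channel image as a plain-text matrix
#'
#' The image external interface of this package is a numeric matrix stored
#' as TSV (rows = image rows). Binary image formats are deliberately not
#' used so that fixtures stay text.
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @return `read_image_tsv()` returns a numeric matrix.
#' @export
write_image_tsv <- function(img, path) {
  stopifnot(is.matrix(img))
  write.table(img, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  as.matrix(read.delim(path, header = FALSE, sep = "\t"))
}
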