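#' @importFrom stats median quantile rbinom rnorm rpois runif var prcomp
#'   pnorm p.adjust kmeans setNames dist
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Hamming distance between equal-length strings
#'
#' Vectorised over `b`: counts mismatching positions of each element of `b`
#' against the single string `a`.
#'
#' @param a single string.
#' @param b character vector of strings of the same nchar as `a`.
#' @return integer vector of mismatch counts.
#' @keywords internal
hamming_dist <- function(a, b) {
  am <- strsplit(a, "", fixed = TRUE)[[1]]
  vapply(strsplit(b, "", fixed = TRUE),
         function(x) sum(x != am), integer(1))
}

## all strings at Hamming distance exactly 1 from x (DNA alphabet)
hamming1_neighbors <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    for (b in DNA_BASES[DNA_BASES != chars[i]]) {
      k <- k + 1L
      y <- chars
      y[i] <- b
      out[k] <- paste(y, collapse = "")
    }
  }
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

## deterministic sub-seed so independent emissions don't share streams;
## kept below 2^31 - 1
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
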