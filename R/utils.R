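#' Derive a deterministic sub-seed for a named pipeline stage
#'
#' A single global seed fans out to per-stage seeds through a small string
#' hash, so that adding or reordering stages never changes the random stream
#' any other stage sees.
#'
#' @param seed Integer global seed.
#' @param name Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# uniformly random DNA strings
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  m <- matrix(bases[sample.int(4L, n * len, replace = TRUE)], nrow = n)
  do.call(paste0, split(m, col(m)))
}

# per-base substitution errors; each erroneous position becomes one of the
# three other bases uniformly
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# order timepoint labels like D0 < D2 < D14 by their numeric suffix,
# falling back to lexicographic order for labels without digits
order_timepoints <- function(tp) {
  u <- unique(as.character(tp))
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", u)))
  u[order(is.na(num), num, u)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ct <- function(...) stop(..., call. = FALSE)
warn_ct <- function(...) warning(..., call. = FALSE)
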