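#' @importFrom stats setNames lowess approx pnorm pt pf phyper rnbinom rnorm
#'   runif var median quantile optimize sd
#' @importFrom utils head read.delim write.table
NULL

# Reverse complement of a plain character vector of DNA strings (IUPAC
# aware; plain chartr/utf8 beats the S4 machinery for short queries).
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# GC content in percent; non-ACGT bases count toward length, not GC.
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  100 * gc / n
}

# Length of the longest run of a given base.
max_base_run <- function(x, base = "T") {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    runs <- r$lengths[r$values == base]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

has_base_run <- function(x, base = "T", min_run = 4L) {
  grepl(strrep(base, min_run), x, fixed = TRUE)
}

# Does `x` contain `site` on either strand?
contains_site_either_strand <- function(x, sites) {
  hit <- rep(FALSE, length(x))
  rc <- revcomp(x)
  for (s in sites) {
    hit <- hit | grepl(s, x, fixed = TRUE) | grepl(s, rc, fixed = TRUE)
  }
  hit
}

# Integer-encode DNA: A=0 C=1 G=2 T=3, anything else NA (never matches).
DNA_CODE <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 0L; v[utf8ToInt("a") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L; v[utf8ToInt("c") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L; v[utf8ToInt("g") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L; v[utf8ToInt("t") + 1L] <- 3L
  v
})

encode_dna <- function(x) DNA_CODE[utf8ToInt(x) + 1L]

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
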