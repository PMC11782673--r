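# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain character vectors, position-by-position scans.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           V = "B", B = "V", R = "Y", Y = "R")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "")[[1]])
    paste(map[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_iupac_match <- function(pattern_char, base_char) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               V = c("A", "C", "G"), B = c("C", "G", "T"),
               N = c("A", "C", "G", "T"))
  base_char %in% sets[[pattern_char]]
}

# every protospacer site over a raw sequence: PAM on the protospacer
# strand immediately 5' of a full-length spacer
oracle_scan <- function(seq, pam = "TTTV", sl = 23L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  pw <- nchar(pam)
  pam_ch <- strsplit(pam, "")[[1]]
  hits <- list()
  matches_at <- function(chars, p0) {
    all(vapply(seq_len(pw), function(k)
      oracle_iupac_match(pam_ch[k], chars[p0 + k - 1]), logical(1)))
  }
  for (p in seq_len(L)) {
    # plus strand: PAM at [p, p+pw-1], spacer right of it
    if (p + pw - 1 + sl <= L && matches_at(ch, p)) {
      hits[[length(hits) + 1]] <- data.frame(
        strand = "+", pam_start = p,
        spacer_start = p + pw, spacer_end = p + pw + sl - 1,
        spacer_seq = paste(ch[(p + pw):(p + pw + sl - 1)], collapse = ""))
    }
    # minus strand: genomic revcomp(PAM) at [p, p+pw-1], spacer left of it
    rc_pam <- strsplit(oracle_revcomp(pam), "")[[1]]
    if (p + pw - 1 <= L && p > sl &&
        all(vapply(seq_len(pw), function(k)
          oracle_iupac_match(rc_pam[k], ch[p + k - 1]), logical(1)))) {
      hits[[length(hits) + 1]] <- data.frame(
        strand = "-", pam_start = p,
        spacer_start = p - sl, spacer_end = p - 1,
        spacer_seq = oracle_revcomp(paste(ch[(p - sl):(p - 1)], collapse = "")))
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(0), pam_start = integer(0),
                      spacer_start = integer(0), spacer_end = integer(0),
                      spacer_seq = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$spacer_start, out$strand), , drop = FALSE]
}

# exhaustive sliding-window Hamming scan: all sites on either strand of a
# set of contig strings matching `spacer` with <= max_mm substitutions;
# optionally require an adjacent exact TTTV-style PAM
oracle_hamming_sites <- function(contigs, spacer, max_mm,
                                 require_pam = FALSE) {
  sl <- nchar(spacer)
  sp_f <- strsplit(spacer, "")[[1]]
  sp_r <- strsplit(oracle_revcomp(spacer), "")[[1]]
  out <- list()
  for (nm in names(contigs)) {
    ch <- strsplit(contigs[[nm]], "")[[1]]
    L <- length(ch)
    if (L < sl) next
    for (s in seq_len(L - sl + 1)) {
      win <- ch[s:(s + sl - 1)]
      for (ori in c("+", "-")) {
        pat <- if (ori == "+") sp_f else sp_r
        mm <- sum(win != pat | !win %in% c("A", "C", "G", "T"))
        if (mm > max_mm) next
        if (require_pam) {
          if (ori == "+") {
            if (s < 5) next
            pam <- ch[(s - 4):(s - 1)]
            if (!(all(pam[1:3] == "T") && pam[4] %in% c("A", "C", "G"))) next
          } else {
            if (s + sl + 3 > L) next
            pam <- ch[(s + sl):(s + sl + 3)]
            if (!(pam[1] %in% c("C", "G", "T") && all(pam[2:4] == "A"))) next
          }
        }
        out[[length(out) + 1]] <- data.frame(
          contig = nm, start = s, orientation = ori, mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      orientation = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
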