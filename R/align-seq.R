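# Global sequence alignment (Needleman-Wunsch) for putting two homologous
# chains in register, e.g. H3 vs the CENP-A variant whose loop 1 carries a
# 2-residue insertion.  Scores: match +2, mismatch -1, gap -2 (linear).

#' Globally align two sequences
#'
#' @param a,b character vectors (one symbol per residue) or single strings.
#' @param match,mismatch,gap alignment scores.
#' @return list with `pairs` (2-column matrix of aligned 1-based positions),
#'   `insertions_b` (positions of `b` aligned to gaps in `a`),
#'   `insertions_a` (positions of `a` aligned to gaps in `b`), and `score`.
#' @export
align_sequences <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback (prefer diagonal, then up (gap in b), then left (gap in a))
  i <- n; j <- m
  pa <- integer(0); pb <- integer(0)
  ins_b <- integer(0); ins_a <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      pa <- c(i, pa); pb <- c(j, pb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ins_a <- c(i, ins_a); i <- i - 1L
    } else {
      ins_b <- c(j, ins_b); j <- j - 1L
    }
  }
  list(pairs = cbind(a = pa, b = pb), insertions_a = ins_a,
       insertions_b = ins_b, score = S[n + 1L, m + 1L])
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", MSE = "M", PHE = "F",
             PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y",
             VAL = "V")

#' One-letter sequence of a chain
#' @param system a `MolecularSystem`.
#' @param chain chain identifier.
#' @return character vector, one letter per residue (X for non-standard).
#' @export
chain_sequence <- function(system, chain) {
  a <- system$atoms[system$atoms$chain_id == chain, ]
  res <- a$residue_name[!duplicated(a$residue_number)]
  out <- .AA3TO1[toupper(res)]
  out[is.na(out)] <- "X"
  unname(out)
}
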