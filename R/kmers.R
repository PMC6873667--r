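#' Canonical k-mer classes
#'
#' A canonical class pools a k-mer with its reverse complement, because
#' sequencing reads both strands; the class representative is the
#' lexicographically smaller of the two. For even k there are
#' `(4^k + 4^(k/2)) / 2` classes (136 for k = 4), of which `4^(k/2)` are
#' palindromic.
#'
#' @param k k-mer size; must be even and in `[2, 8]`.
#' @return A list with `classes` (sorted representatives), `kmers` (all
#'   `4^k` words), `rc` (their reverse complements) and `class_of` (the
#'   representative of each word).
#' @export
canonical_kmers <- function(k) {
  k <- as.integer(k)
  if (k %% 2L != 0L || k < 2L || k > 8L)
    pb_stop("pb_bad_k", "k must be even and in [2, 8], got %d", k)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  class_of <- ifelse(kmers <= rc, kmers, rc)
  list(classes = sort(unique(class_of)), kmers = kmers, rc = rc,
       class_of = class_of)
}

#' Reverse-complement a k-mer string
#'
#' @param w A DNA string over A/C/G/T.
#' @return Its reverse complement.
#' @export
revcomp <- function(w) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
}

#' Count canonical k-mers per contig
#'
#' For every contig and every canonical class \{w, rc(w)\} the count is the
#' number of occurrences of `w` plus the occurrences of `rc(w)` on the
#' forward sequence; palindromic words are counted once per occurrence.
#' Windows containing `N` are skipped. Contigs shorter than k yield an
#' all-zero row with a warning.
#'
#' @param contigs A named `DNAStringSet`.
#' @param k Even k-mer size in `[2, 8]` (default 4).
#' @return An integer matrix, contigs by canonical classes, with attribute
#'   `k`. Column names are the class representatives.
#' @export
count_canonical_kmers <- function(contigs, k = 4L) {
  ck <- canonical_kmers(k)
  if (any(Biostrings::width(contigs) < k))
    warning(sprintf("%d contig(s) shorter than k = %d: zero composition rows",
                    sum(Biostrings::width(contigs) < k), k))
  # per-word counts over ACGT windows only (N windows never match a word)
  W <- Biostrings::oligonucleotideFrequency(contigs, width = k)
  collapse <- matrix(0L, nrow = length(ck$kmers), ncol = length(ck$classes),
                     dimnames = list(ck$kmers, ck$classes))
  collapse[cbind(seq_along(ck$kmers), match(ck$class_of, ck$classes))] <- 1L
  Z <- W %*% collapse
  storage.mode(Z) <- "integer"
  rownames(Z) <- names(contigs)
  attr(Z, "k") <- as.integer(k)
  Z
}
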