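#' Position frequency matrices and information-content scoring
#'
#' A PFM here is a numeric matrix with one row per motif position and four
#' columns (A, C, G, U) of relative nucleotide frequencies; each row sums
#' to 1. The binding-site scanner weights each position by its information
#' content
#' \deqn{I_p = 2 - \left(-\sum_{n=1}^{4} f_n \log_2 f_n\right),}
#' i.e. 2 bits minus the Shannon entropy of the position's frequencies
#' (with the convention \eqn{0 \log_2 0 = 0}), so fully conserved positions
#' contribute up to 2 bits and uninformative positions contribute nothing.
#'
#' @name pfm
NULL

PFM_ALPHABET <- c("A", "C", "G", "U")

#' Construct a position frequency matrix
#'
#' @param freqs numeric matrix, positions x 4 nucleotides. Columns are
#'   taken in A, C, G, U order (T is accepted as an alias for U in column
#'   names).
#' @return an object of class `pfm`: the frequency matrix with an `ic`
#'   attribute holding per-position information content in bits.
#' @examples
#' m <- matrix(0.25, nrow = 7, ncol = 4)
#' p <- pfm(m)
#' attr(p, "ic")  # all zero: uniform positions carry no information
#' @export
pfm <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4L) stop("a PFM needs exactly 4 nucleotide columns")
  if (!is.null(colnames(freqs))) {
    cn <- chartr("T", "U", toupper(colnames(freqs)))
    if (!setequal(cn, PFM_ALPHABET)) {
      stop("PFM columns must be A, C, G, U (or T)")
    }
    colnames(freqs) <- cn
    freqs <- freqs[, PFM_ALPHABET, drop = FALSE]
  } else {
    colnames(freqs) <- PFM_ALPHABET
  }
  if (any(freqs < 0)) stop("PFM frequencies must be non-negative")
  rs <- rowSums(freqs)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("every PFM row must sum to 1 (got ", paste(signif(rs, 4), collapse = ", "), ")")
  }
  structure(freqs, ic = apply(freqs, 1L, position_information_content),
            class = c("pfm", "matrix"))
}

#' Per-position information content in bits
#'
#' @param freqs numeric vector of 4 relative frequencies summing to 1.
#' @return `2 - entropy(freqs)` in bits, in `[0, 2]`.
#' @examples
#' position_information_content(c(0.25, 0.25, 0.25, 0.25))  # 0
#' position_information_content(c(1, 0, 0, 0))              # 2
#' @export
position_information_content <- function(freqs) {
  if (length(freqs) != 4L) stop("expected 4 frequencies")
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  nz <- freqs > 0
  2 - (-sum(freqs[nz] * log2(freqs[nz])))
}

#' Read a PFM from a tab-separated file
#'
#' Expects a header line naming the four nucleotide columns (A, C, G, U)
#' and one row per motif position.
#'
#' @param path file path.
#' @return a [pfm] object.
#' @export
read_pfm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  pfm(as.matrix(tab))
}

#' Write a PFM to a tab-separated file
#' @param x a [pfm] object.
#' @param path destination path.
#' @export
write_pfm <- function(x, path) {
  utils::write.table(format(unclass(x), digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus sequence of a PFM
#'
#' The highest-frequency nucleotide at each position (ties broken in
#' A, C, G, U order), returned in the DNA alphabet for planting into and
#' matching against genomic sequence.
#'
#' @param x a [pfm] object.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @return a character scalar of length `nrow(x)`.
#' @export
pfm_consensus <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  cons <- paste(PFM_ALPHABET[apply(unclass(x), 1L, which.max)], collapse = "")
  if (alphabet == "DNA") chartr("U", "T", cons) else cons
}

# Precompute the (positions x 5) lookup of f_{p,n} * I_p; column 5 is the
# zero contribution assigned to ambiguous bases.
pfm_weights <- function(x) {
  ic <- attr(x, "ic")
  cbind(unclass(x) * ic, 0)
}

#' Score a single k-mer window against a PFM
#'
#' The window score is \eqn{\sum_p f_{p,n(p)} I_p} where `n(p)` is the
#' window's nucleotide at motif position `p`. Ambiguous bases (anything
#' outside A/C/G/T/U) contribute 0 at their position.
#'
#' @param window character scalar whose length equals `nrow(pfm)`.
#' @param pfm a [pfm] object.
#' @return numeric score in `[0, sum(attr(pfm, "ic"))]`.
#' @export
score_7mer <- function(window, pfm) {
  w <- nrow(pfm)
  window <- as_dna(window)
  if (nchar(window) != w) stop("window length must equal PFM width (", w, ")")
  idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  wt <- pfm_weights(pfm)
  sum(wt[cbind(seq_len(w), idx)])
}

#' Scan a PAS-flanking window with a PFM
#'
#' Scores every k-mer start position fully contained in the flank. The
#' flank is expected in transcript orientation (see [pas_flank]); position
#' labels are relative to the cleavage site, with `-upstream` the first
#' base of the flank and `0` the cleavage site itself.
#'
#' @param flank character scalar, the flanking sequence 5' to 3'.
#' @param pfm a [pfm] object.
#' @param upstream how many nucleotides of the flank lie 5' of the
#'   cleavage site (default 100, matching a -100..+100 scan window).
#' @return named numeric vector of scores, one per k-mer start position;
#'   empty when the flank is shorter than the PFM.
#' @export
scan_pas_region <- function(flank, pfm, upstream = 100L) {
  flank <- as_dna(flank)
  n <- nchar(flank)
  w <- nrow(pfm)
  if (n < w) return(stats::setNames(numeric(0), character(0)))
  chars <- strsplit(flank, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  wt <- pfm_weights(pfm)
  nwin <- n - w + 1L
  scores <- numeric(nwin)
  for (p in seq_len(w)) {
    scores <- scores + wt[p, idx[seq_len(nwin) + p - 1L]]
  }
  names(scores) <- seq_len(nwin) - upstream - 1L
  scores
}
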