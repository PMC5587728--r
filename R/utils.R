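# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement subseq
NULL

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize a nucleotide string to the DNA alphabet (U -> T), uppercase.
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Extract a genomic subsequence by 0-based half-open coordinates,
# clipped to contig bounds. `genome` is a named DNAStringSet.
genome_slice <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' not found in genome", call. = FALSE)
  }
  len <- length(genome[[contig]])
  s <- max(start0, 0L)
  e <- min(end0, len)
  if (s >= e) return("")
  as.character(Biostrings::subseq(genome[[contig]], s + 1L, e))
}

#' Extract a PAS-flanking sequence in transcript orientation
#'
#' Returns the sequence spanning `upstream` nucleotides 5' of the cleavage
#' site through `downstream` nucleotides 3' of it, read 5' to 3' along the
#' transcript. The cleavage position itself (the last transcribed
#' nucleotide) sits at index `upstream + 1` of the returned string. For
#' minus-strand sites the genomic window is reverse-complemented. Windows
#' truncated by contig edges return shorter strings.
#'
#' @param genome a named `DNAStringSet` (one entry per contig).
#' @param contig contig name.
#' @param position 0-based coordinate of the last transcribed nucleotide.
#' @param strand `"+"` or `"-"` (transcript strand).
#' @param upstream,downstream flank extents in nucleotides.
#' @return a character scalar.
#' @export
pas_flank <- function(genome, contig, position, strand,
                      upstream = 100L, downstream = 100L) {
  stopifnot(length(position) == 1L, strand %in% c("+", "-"))
  if (strand == "+") {
    genome_slice(genome, contig, position - upstream, position + downstream + 1L)
  } else {
    revcomp(genome_slice(genome, contig, position - downstream,
                         position + upstream + 1L))
  }
}

#' @describeIn pas_flank vectorized over a data.frame of sites with
#'   `contig`, `position` and `strand` columns.
#' @param sites data.frame of PAS sites.
#' @export
pas_flanks <- function(genome, sites, upstream = 100L, downstream = 100L) {
  vapply(seq_len(nrow(sites)), function(i) {
    pas_flank(genome, sites$contig[i], sites$position[i], sites$strand[i],
              upstream = upstream, downstream = downstream)
  }, character(1))
}

# Deterministic child seed derivation, kept below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}
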