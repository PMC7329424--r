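#' Canonical 2-bit encoding of k-mers
#'
#' Encodes each k-mer and its reverse complement in 2 bits per base
#' (A=0, C=1, G=2, T=3, first base in the highest bits) and returns the
#' smaller of the two codes, so a k-mer and its reverse complement encode
#' identically. K-mers containing any base outside `{A,C,G,T}` yield `NA`.
#'
#' @param kmers Character vector of k-mers, all of length `k`.
#' @param k Expected k-mer length (1--26 so codes are exact doubles).
#' @return Numeric vector of canonical codes (`NA` where invalid).
#' @examples
#' encode_canonical_kmer(strrep("A", 16)) # 0
#' @export
encode_canonical_kmer <- function(kmers, k = NULL) {
  if (length(kmers) == 0) return(numeric())
  if (is.null(k)) k <- nchar(kmers[[1]])
  if (any(nchar(kmers) != k))
    stop("all k-mers must have length ", k, call. = FALSE)
  cpp_encode_canonical(kmers)
}

#' Hash k-mers with the database hash function h1
#'
#' Applies the fixed 64-bit mixer (splitmix64 finalizer, truncated to 53
#' bits) to the canonical code of each k-mer. These are the feature values
#' stored in, and looked up against, the reference database.
#'
#' @param kmers Character vector of equal-length k-mers.
#' @return Numeric vector of feature values (`NA` for k-mers containing N).
#' @export
hash_kmers <- function(kmers) {
  if (length(kmers) == 0) return(numeric())
  k <- nchar(kmers[[1]])
  if (any(nchar(kmers) != k))
    stop("all k-mers must have the same length", call. = FALSE)
  cpp_hash_kmers(kmers)
}

#' Window spans of a sequence
#'
#' Distributes a sequence of length `L` into windows of size `w` placed
#' every `t` bases: if `L < k` a single (k-mer-free) span `[0, L)`;
#' otherwise `m = floor((L - k) / t) + 1` spans, span i = `[i*t,
#' min(i*t + w, L))`. The union of the spans covers `[0, L)` and every
#' k-mer start position falls inside at least one span. Positions are
#' 0-based, half-open.
#'
#' @param L Sequence length.
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `window`, `start`, `end`.
#' @examples
#' window_spans(98, sketch_params()) # [0,56), [41,97), [82,98)
#' @export
window_spans <- function(L, params) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  k <- params$k; w <- params$w; t <- params$t
  if (L < k) {
    return(tibble::tibble(window = 0L, start = 0L, end = L))
  }
  m <- (L - k) %/% t + 1L
  i <- seq_len(m) - 1L
  tibble::tibble(window = i, start = i * t, end = pmin(i * t + w, L))
}

#' Minhash sketch of one window
#'
#' Hashes every valid k-mer whose start lies in `[start, end - k]` with h1,
#' deduplicates the values and returns the `s` smallest in ascending order.
#' K-mers containing N contribute nothing.
#'
#' @param sequence Nucleotide string.
#' @param start,end 0-based half-open span within `sequence`.
#' @param params A [sketch_params()] object.
#' @return Ascending numeric vector of at most `s` distinct feature values.
#' @export
sketch_window <- function(sequence, start, end, params) {
  stopifnot(start >= 0, end <= nchar(sequence), start < end)
  sub <- substr(sequence, start + 1L, end)
  df <- cpp_sketch_windows(sub, params$k, params$s, end - start, end - start)
  df$feature
}

#' Windowed sketches of sequences
#'
#' Applies [window_spans()] and per-window minhash sketching to each input
#' sequence. The identical function serves the reference (database build)
#' and the read (mapping) side, which is what makes sketch lookup
#' meaningful. Sequences shorter than `k` yield no rows.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `seq` (1-based index into `seqs`), `window`
#'   (0-based), `feature`; features ascend within each window.
#' @export
sketch_seqs <- function(seqs, params) {
  df <- cpp_sketch_windows(seqs, params$k, params$s, params$w, params$t)
  tibble::as_tibble(df)
}

#' Sketch one read (mate 2)
#'
#' @param seq A single cDNA sequence.
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `window`, `feature` (empty if the read is
#'   shorter than `k`).
#' @export
sketch_read <- function(seq, params) {
  sketch_seqs(seq, params)[, c("window", "feature")]
}

#' Reverse complement of nucleotide strings
#'
#' @param seqs Character vector over `{A,C,G,T,N}`.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
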