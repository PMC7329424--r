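#' Pipeline tuning parameters
#'
#' Collects every tunable of the sketch-mapping pipeline in one object.
#' Derived defaults follow the read length `R`: the window size is
#' `w = floor((R + k - 1) / 2)` (56 for 98-base reads with `k = 16`), the
#' stride is `t = w - k + 1` so that every k-mer of a sequence is considered
#' exactly once, and the accumulation range is `floor((R - k - 1) / t) + 2`,
#' the largest number of reference stride bins the k-mers of one
#' contiguously aligned read can touch (3 under the defaults), so hits from
#' a single alignment are never split across ranges.
#'
#' @param read_length Expected cDNA (mate 2) read length `R` in bases.
#' @param k K-mer length (1--31; at most 26 if you need exact canonical codes
#'   at the R level).
#' @param s Sketch size: maximum number of features kept per window.
#' @param w Window size in bases; default derived from `read_length`.
#' @param t Window stride in bases; default `w - k + 1`.
#' @param r Accumulation range in windows; default derived (see above).
#' @param threshold Minimum accumulated hit score for a mapping candidate
#'   (inclusive: a score equal to the threshold qualifies).
#' @param max_locations Features stored at more than this many reference
#'   locations are dropped from the database.
#' @param whitelist_fraction Fraction of all reads covered by the barcode
#'   whitelist prefix-sum rule.
#' @param dedup_factor Occurrence factor of the directional UMI collapse:
#'   UMI A absorbs Hamming-1 neighbour B when
#'   `count(A) >= dedup_factor * count(B) - 1`.
#' @param cb_len,umi_len Cell-barcode and UMI lengths on mate 1
#'   (16 and 10 for Chromium v2).
#'
#' @return An object of class `sketch_params` (a validated named list).
#' @examples
#' p <- sketch_params()
#' p$w # 56
#' p$t # 41
#' @export
sketch_params <- function(read_length = 98L, k = 16L, s = 16L,
                          w = NULL, t = NULL, r = NULL,
                          threshold = 28L, max_locations = 1000L,
                          whitelist_fraction = 0.95, dedup_factor = 2,
                          cb_len = 16L, umi_len = 10L) {
  read_length <- as.integer(read_length)
  k <- as.integer(k)
  s <- as.integer(s)
  if (is.null(w)) w <- (read_length + k - 1L) %/% 2L
  w <- as.integer(w)
  if (is.null(t)) t <- w - k + 1L
  t <- as.integer(t)
  if (is.null(r)) r <- (read_length - k - 1L) %/% t + 2L
  r <- as.integer(r)
  threshold <- as.integer(threshold)
  max_locations <- as.integer(max_locations)

  stopifnot(
    "k must be in 1..31" = k >= 1L && k <= 31L,
    "s must be >= 1" = s >= 1L,
    "w must be >= k" = w >= k,
    "t must be in 1..(w - k + 1)" = t >= 1L && t <= w - k + 1L,
    "r must be >= 1" = r >= 1L,
    "threshold must be >= 1" = threshold >= 1L,
    "max_locations must be >= 1" = max_locations >= 1L,
    "whitelist_fraction must be in (0, 1]" =
      whitelist_fraction > 0 && whitelist_fraction <= 1,
    "dedup_factor must be >= 1" = dedup_factor >= 1,
    "cb_len must be >= 1" = cb_len >= 1L,
    "umi_len must be >= 1" = umi_len >= 1L
  )

  structure(
    list(
      read_length = read_length, k = k, s = s, w = w, t = t, r = r,
      threshold = threshold, max_locations = max_locations,
      whitelist_fraction = whitelist_fraction,
      dedup_factor = dedup_factor,
      cb_len = as.integer(cb_len), umi_len = as.integer(umi_len)
    ),
    class = "sketch_params"
  )
}

#' @export
print.sketch_params <- function(x, ...) {
  cat("<sketch_params>\n")
  cat(sprintf("  k = %d, s = %d, w = %d, t = %d, r = %d\n",
              x$k, x$s, x$w, x$t, x$r))
  cat(sprintf("  threshold = %d, max_locations = %d\n",
              x$threshold, x$max_locations))
  cat(sprintf("  whitelist_fraction = %g, dedup_factor = %g\n",
              x$whitelist_fraction, x$dedup_factor))
  cat(sprintf("  read_length = %d, cb_len = %d, umi_len = %d\n",
              x$read_length, x$cb_len, x$umi_len))
  invisible(x)
}

#' Maximum number of sketch features extractable from a read
#'
#' Sums the per-window sketch capacity `min(s, n_kmers)` over the windows of
#' a read of the given length: 33 for 98-base reads under the defaults
#' (two full windows of 16 features plus a final one-k-mer window).
#'
#' @param params A [sketch_params()] object.
#' @param read_length Read length; defaults to `params$read_length`.
#' @return Integer feature capacity.
#' @examples
#' max_read_features(sketch_params()) # 33
#' @export
max_read_features <- function(params, read_length = params$read_length) {
  spans <- window_spans(read_length, params)
  n_kmers <- pmax(spans$end - spans$start - params$k + 1L, 0L)
  sum(pmin(n_kmers, params$s))
}
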