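#' Split mate-1 sequences into cell barcode and UMI
#'
#' The first `cb_len` bases are the cell barcode and the following
#' `umi_len` bases the UMI; any trailing bases are ignored. Reads shorter
#' than `cb_len + umi_len` are flagged malformed (counted, not fatal).
#'
#' @param seqs Character vector of mate-1 sequences.
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `cb`, `umi`, `malformed`.
#' @export
split_read1 <- function(seqs, params) {
  need <- params$cb_len + params$umi_len
  malformed <- nchar(seqs) < need
  tibble::tibble(
    cb = ifelse(malformed, NA_character_, substr(seqs, 1L, params$cb_len)),
    umi = ifelse(malformed, NA_character_,
                 substr(seqs, params$cb_len + 1L, need)),
    malformed = malformed
  )
}

#' Count exact cell-barcode occurrences
#'
#' @param pairs Tibble of read pairs (see [read_fastq_pairs()]).
#' @param params A [sketch_params()] object.
#' @return Tibble with columns `cb`, `n` (one row per distinct barcode);
#'   malformed mate-1 reads are excluded.
#' @export
count_barcodes <- function(pairs, params) {
  bc <- split_read1(pairs$mate1_seq, params)
  bc |>
    dplyr::filter(!.data$malformed) |>
    dplyr::count(.data$cb, name = "n")
}

#' Merge per-batch barcode counts
#'
#' Associative, order-normalized merge: counting in batches then merging
#' equals single-pass counting for any batch split.
#'
#' @param counts_list List of tibbles as produced by [count_barcodes()].
#' @return A single merged count tibble.
#' @export
merge_barcode_counts <- function(counts_list) {
  dplyr::bind_rows(counts_list) |>
    dplyr::summarise(n = sum(.data$n), .by = "cb") |>
    dplyr::arrange(.data$cb)
}

#' Build the cell-barcode whitelist by the sorted prefix-sum rule
#'
#' Barcodes are sorted by count descending (ties broken lexicographically),
#' an inclusive prefix sum over the counts is computed in that order, and a
#' barcode is admitted iff its prefix sum is strictly below
#' `fraction * total`. Note that under this strict rule the last-sorted
#' barcode (inclusive prefix = total) is never admitted, whatever the
#' fraction.
#'
#' @param counts Tibble with columns `cb`, `n`.
#' @param fraction Proportion of all reads the whitelist may cover.
#' @return A `cb_whitelist`: tibble with columns `cb`, `n`, carrying
#'   attributes `fraction` and `total`.
#' @examples
#' counts <- tibble::tibble(cb = c("A", "B", "C", "D"), n = c(50, 30, 15, 5))
#' build_whitelist(counts, 0.9)$cb # "A" "B"
#' @export
build_whitelist <- function(counts, fraction = 0.95) {
  stopifnot(fraction > 0, fraction <= 1)
  total <- sum(counts$n)
  wl <- counts |>
    dplyr::arrange(dplyr::desc(.data$n), .data$cb) |>
    dplyr::mutate(.prefix = cumsum(.data$n)) |>
    dplyr::filter(.data$.prefix < fraction * total) |>
    dplyr::select("cb", "n")
  structure(wl, class = c("cb_whitelist", class(wl)),
            fraction = fraction, total = total)
}

#' Correct cell barcodes against a whitelist
#'
#' Exact whitelist members are returned unchanged. Otherwise the whitelist
#' members within edit distance one of the barcode are collected
#' (Levenshtein over the extracted fixed-length string by default, or
#' substitutions only with `method = "hamming"`); if exactly one candidate
#' exists, or one candidate has strictly the highest whitelist count, it is
#' returned, else the barcode is unmatched (`NA`) and the read will be
#' discarded.
#'
#' @param cbs Character vector of observed barcodes.
#' @param whitelist A [build_whitelist()] result (or tibble `cb`, `n`).
#' @param method `"levenshtein"` (default) or `"hamming"`.
#' @return Character vector of accepted barcodes, `NA` where unmatched.
#' @export
correct_barcode <- function(cbs, whitelist,
                            method = c("levenshtein", "hamming")) {
  method <- match.arg(method)
  wl_cb <- whitelist$cb
  wl_n <- whitelist$n
  out <- ifelse(cbs %in% wl_cb, cbs, NA_character_)
  todo <- unique(cbs[is.na(out) & !is.na(cbs)])
  if (length(todo) == 0 || length(wl_cb) == 0) return(out)
  d <- if (method == "hamming") {
    cpp_hamming_cross(todo, wl_cb)
  } else {
    adist(todo, wl_cb)
  }
  fixed <- vapply(seq_along(todo), function(i) {
    hits <- which(d[i, ] <= 1L)
    if (length(hits) == 0) return(NA_character_)
    if (length(hits) == 1) return(wl_cb[hits])
    top <- hits[wl_n[hits] == max(wl_n[hits])]
    if (length(top) == 1) wl_cb[top] else NA_character_
  }, character(1))
  idx <- match(cbs, todo)
  replace(out, !is.na(idx), fixed[idx[!is.na(idx)]])
}

#' Write or read a whitelist TSV (one barcode per line, optional count)
#'
#' @param whitelist A whitelist tibble.
#' @param path TSV path.
#' @return `write_whitelist()` returns `path` invisibly; `read_whitelist()`
#'   a tibble with columns `cb`, `n` (`n` is `NA` when absent in the file).
#' @export
write_whitelist <- function(whitelist, path) {
  readr::write_tsv(tibble::as_tibble(whitelist)[, c("cb", "n")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(tbl)[1] <- "cb"
  if (ncol(tbl) >= 2) names(tbl)[2] <- "n" else tbl$n <- NA_integer_
  tbl[, c("cb", "n")]
}

#' @exportS3Method generics::tidy
tidy.cb_whitelist <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cb", "n")])
}
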