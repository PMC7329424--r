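#' Look up read sketch features in the database
#'
#' Every feature occurrence across all read windows increments the hit
#' count of every stored (transcript, window) location of that feature by
#' one; features absent from the table (including capped-away ones)
#' contribute nothing. A feature value recurring in two read windows
#' therefore counts twice.
#'
#' @param db A `sketch_db`.
#' @param read_sketch Tibble with columns `window`, `feature`
#'   (from [sketch_read()]).
#' @return Tibble with columns `transcript`, `window` (reference window),
#'   `hits`.
#' @export
lookup_hits <- function(db, read_sketch) {
  dplyr::inner_join(read_sketch["feature"], db$table,
                    by = "feature", relationship = "many-to-many") |>
    dplyr::count(.data$transcript, .data$window, name = "hits")
}

#' Best accumulated score over any r consecutive windows
#'
#' The mapping score of a read against one transcript: the maximum over
#' start positions j of the summed hit counts in windows `j .. j+r-1`
#' (absent windows count 0). Hits spread farther apart than the range are
#' never aggregated.
#'
#' @param window_hits Tibble with columns `window`, `hits` for one
#'   transcript (or a named vector, names = window indices).
#' @param r Range size in windows.
#' @return Integer score (0 for an empty map).
#' @examples
#' best_range_score(tibble::tibble(window = c(0, 2, 3), hits = c(3, 5, 2)), 2)
#' @export
best_range_score <- function(window_hits, r) {
  stopifnot(r >= 1)
  if (!is.data.frame(window_hits)) {
    window_hits <- tibble::tibble(
      window = as.integer(names(window_hits)),
      hits = as.integer(window_hits)
    )
  }
  if (nrow(window_hits) == 0) return(0L)
  scores <- range_scores(
    dplyr::mutate(window_hits, transcript = 1L), r
  )
  as.integer(scores$score[1])
}

# Range-accumulated score per transcript, vectorized over a hit table with
# columns transcript, window, hits (and optionally read). A hit at window w
# contributes to ranges starting at j in {w-r+1, ..., w}; the score is the
# max over j of the per-range sums.
range_scores <- function(hit_tbl, r) {
  keys <- intersect(c("read", "transcript"), names(hit_tbl))
  tidyr::expand_grid(d = 0:(r - 1L), hit_tbl) |>
    dplyr::mutate(j = .data$window - .data$d) |>
    dplyr::filter(.data$j >= 0L) |>
    dplyr::summarise(range_sum = sum(.data$hits),
                     .by = dplyr::all_of(c(keys, "j"))) |>
    dplyr::summarise(score = max(.data$range_sum),
                     .by = dplyr::all_of(keys))
}

#' Threshold transcript scores into mapping candidates
#'
#' Inclusive rule: a transcript whose score equals the threshold is a
#' candidate (with the default maximum of 33 read features, the default
#' threshold 28 corresponds to ~85% of a perfect hit).
#'
#' @param scores Tibble with columns `transcript`, `score`.
#' @param threshold Minimum qualifying score.
#' @return The candidate subset of `scores`.
#' @export
select_candidates <- function(scores, threshold) {
  stopifnot(threshold >= 1)
  dplyr::filter(scores, .data$score >= threshold)
}

#' Resolve candidate transcripts to a single gene
#'
#' No candidates: the read is unmapped. All candidates in one gene: that
#' gene, with the maximum candidate score. Candidates in two or more genes:
#' the read is discarded as gene-ambiguous.
#'
#' @param candidates Tibble with columns `transcript` (index into the
#'   database transcript list), `score`.
#' @param db A `sketch_db`.
#' @return List with fields `status` (`"mapped"`, `"unmapped"` or
#'   `"ambiguous_gene"`), `gene`, `score`.
#' @export
resolve_gene <- function(candidates, db) {
  if (nrow(candidates) == 0)
    return(list(status = "unmapped", gene = NA_character_, score = NA_integer_))
  genes <- unname(db$taxonomy$tx2gene[db$transcript_ids[candidates$transcript]])
  if (dplyr::n_distinct(genes) > 1)
    return(list(status = "ambiguous_gene", gene = NA_character_,
                score = NA_integer_))
  list(status = "mapped", gene = genes[1],
       score = as.integer(max(candidates$score)))
}

MAP_STATUSES <- c("mapped", "malformed", "cb_unmatched", "unmapped",
                  "ambiguous_gene")

#' Map a batch of read pairs to genes
#'
#' Composes barcode extraction and correction, read sketching, feature
#' lookup, range accumulation, thresholding and gene resolution for every
#' read of a batch. All failures are typed discards, with precedence
#' malformed > cb_unmatched > unmapped > ambiguous_gene. Mate-2 reads
#' shorter than `k` are malformed (they carry no features).
#'
#' @param db A `sketch_db`.
#' @param pairs Tibble of read pairs (see [read_fastq_pairs()]).
#' @param whitelist A [build_whitelist()] result or whitelist tibble.
#' @param params A [sketch_params()]; defaults to the database's.
#' @param cb_method Barcode edit-distance model, see [correct_barcode()].
#' @return Tibble of mapping records: `read`, `cb_raw`, `cb`, `umi`,
#'   `gene`, `score`, `status`.
#' @export
map_reads <- function(db, pairs, whitelist, params = db$params,
                      cb_method = "levenshtein") {
  n <- nrow(pairs)
  bc <- split_read1(pairs$mate1_seq, params)
  malformed <- bc$malformed | nchar(pairs$mate2_seq) < params$k
  cb <- rep(NA_character_, n)
  ok <- !malformed
  cb[ok] <- correct_barcode(bc$cb[ok], whitelist, method = cb_method)

  records <- tibble::tibble(
    read = seq_len(n),
    cb_raw = bc$cb,
    cb = cb,
    umi = bc$umi,
    gene = NA_character_,
    score = NA_integer_,
    status = dplyr::case_when(
      malformed ~ "malformed",
      is.na(cb) ~ "cb_unmatched",
      .default = "unmapped"
    )
  )

  live <- which(records$status == "unmapped")
  if (length(live) > 0 && nrow(db$table) > 0) {
    feats <- sketch_seqs(pairs$mate2_seq[live], params)
    hits <- dplyr::inner_join(
      feats, db$table, by = "feature", relationship = "many-to-many",
      suffix = c("_read", "")
    ) |>
      dplyr::count(.data$seq, .data$transcript, .data$window, name = "hits") |>
      dplyr::rename(read = "seq")
    if (nrow(hits) > 0) {
      scored <- range_scores(hits, params$r) |>
        dplyr::filter(.data$score >= params$threshold) |>
        dplyr::mutate(
          gene = unname(db$taxonomy$tx2gene[db$transcript_ids[.data$transcript]])
        )
      resolved <- scored |>
        dplyr::summarise(
          n_genes = dplyr::n_distinct(.data$gene),
          gene = .data$gene[1],
          score = max(.data$score),
          .by = "read"
        )
      if (nrow(resolved) > 0) {
        idx <- live[resolved$read]
        amb <- resolved$n_genes > 1
        records$status[idx] <- ifelse(amb, "ambiguous_gene", "mapped")
        records$gene[idx] <- ifelse(amb, NA_character_, resolved$gene)
        records$score[idx] <- ifelse(amb, NA_integer_,
                                     as.integer(resolved$score))
      }
    }
  }
  records$status <- factor(records$status, levels = MAP_STATUSES)
  records
}

#' Map a single read pair
#'
#' Convenience wrapper over [map_reads()] for one read.
#'
#' @param db A `sketch_db`.
#' @param pair One-row tibble with `mate1_seq`, `mate2_seq`.
#' @param whitelist Whitelist tibble.
#' @param params A [sketch_params()].
#' @return One-row mapping record tibble.
#' @export
map_read <- function(db, pair, whitelist, params = db$params) {
  map_reads(db, pair, whitelist, params)
}
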