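#' Directional adjacency between UMIs of one (cell, gene) group
#'
#' An edge A -> B exists iff the UMIs differ at exactly one position
#' (Hamming distance 1; UMIs are fixed length, so substitution-only edit
#' distance applies) and `count(A) >= factor * count(B) - 1`. A faulty UMI
#' produced by a sequencing error is expected to occur much less often than
#' the true UMI it derives from, which is what the occurrence factor
#' encodes.
#'
#' @param counts Tibble with columns `umi`, `n` (counts >= 1).
#' @param factor Occurrence factor (default 2).
#' @return Tibble with columns `from`, `to` (UMI strings).
#' @examples
#' directional_edges(tibble::tibble(umi = c("AAAA", "AAAT"), n = c(10, 4)), 2)
#' @export
directional_edges <- function(counts, factor = 2) {
  stopifnot(factor >= 1)
  u <- counts$umi
  n <- counts$n
  if (dplyr::n_distinct(nchar(u)) > 1)
    stop("UMIs of unequal length in one group", call. = FALSE)
  if (length(u) < 2)
    return(tibble::tibble(from = character(), to = character()))
  d <- cpp_hamming_cross(u, u)
  idx <- which(d == 1L, arr.ind = TRUE)
  keep <- n[idx[, 1]] >= factor * n[idx[, 2]] - 1
  tibble::tibble(from = u[idx[keep, 1]], to = u[idx[keep, 2]])
}

#' Collapse the UMIs of one (cell, gene) group into molecules
#'
#' UMIs are visited in descending count order (ties lexicographic); each
#' unvisited UMI seeds a breadth-first expansion along the directional
#' edges, marking every reached UMI visited. The number of expansions
#' started is the molecule count; the seeds are the representative UMIs.
#'
#' @param counts Tibble with columns `umi`, `n`.
#' @param factor Occurrence factor, see [directional_edges()].
#' @return List with fields `molecules` (integer) and `representatives`
#'   (character vector of seed UMIs).
#' @examples
#' count_molecules(tibble::tibble(umi = c("AAAA", "AAAT", "TAAT"),
#'                                n = c(10, 4, 2)))$molecules # 1
#' @export
count_molecules <- function(counts, factor = 2) {
  stopifnot(nrow(counts) > 0)
  ord <- order(-counts$n, counts$umi)
  u <- counts$umi[ord]
  edges <- directional_edges(counts, factor)
  adj <- split(edges$to, base::factor(edges$from, levels = u))
  visited <- setNames(rep(FALSE, length(u)), u)
  reps <- character()
  for (seed in u) {
    if (visited[[seed]]) next
    reps <- c(reps, seed)
    queue <- seed
    visited[[seed]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nxt <- adj[[cur]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) > 0) {
        visited[nxt] <- TRUE
        queue <- c(queue, nxt)
      }
    }
  }
  list(molecules = length(reps), representatives = reps)
}

#' Deduplicate the mapped records of one cell
#'
#' Records are grouped by gene; within each group the UMI counts are
#' collapsed with [count_molecules()]. A UMI string recurring under two
#' genes of the same cell is two molecules (grouping is per (cell, gene)).
#'
#' @param records Mapping-record tibble of a single cell (all rows share
#'   one corrected `cb`), only `status == "mapped"` rows are used.
#' @param factor Occurrence factor.
#' @return Tibble with columns `cb`, `gene`, `molecules`.
#' @export
dedup_cell <- function(records, factor = 2) {
  dedup_records(records, factor)
}

#' Deduplicate mapped records into per-(cell, gene) molecule counts
#'
#' @param records Mapping-record tibble (any number of cells).
#' @param factor Occurrence factor.
#' @return Tibble with columns `cb`, `gene`, `molecules`, one row per
#'   (cell, gene) with at least one mapped read.
#' @export
dedup_records <- function(records, factor = 2) {
  mapped <- dplyr::filter(records, .data$status == "mapped")
  if (nrow(mapped) == 0)
    return(tibble::tibble(cb = character(), gene = character(),
                          molecules = integer()))
  mapped |>
    dplyr::count(.data$cb, .data$gene, .data$umi, name = "n") |>
    dplyr::reframe(
      molecules = count_molecules(dplyr::pick("umi", "n"), factor)$molecules,
      .by = c("cb", "gene")
    ) |>
    dplyr::mutate(molecules = as.integer(.data$molecules))
}
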