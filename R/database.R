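#' Build the minhash feature database over a transcriptome
#'
#' For each transcript, in input order, every window is sketched and each
#' sketch feature is appended to a multi-value feature table together with
#' its (transcript, window) location. Features occurring at more than
#' `params$max_locations` locations are then removed entirely with
#' [cap_features()].
#'
#' @param transcripts Tibble with columns `id`, `sequence`
#'   (as from [read_fasta()]).
#' @param tax A `tx_taxonomy`; every transcript id must be present.
#' @param params A [sketch_params()] object.
#' @return A `sketch_db` object: fields `params`, `table` (tibble
#'   `feature`, `transcript`, `window` in insertion order), `taxonomy`,
#'   `transcript_ids`, `window_counts`.
#' @export
build_database <- function(transcripts, tax, params = sketch_params()) {
  stopifnot(inherits(tax, "tx_taxonomy"), inherits(params, "sketch_params"))
  missing <- setdiff(transcripts$id, names(tax$tx2gene))
  if (length(missing) > 0)
    stop("transcript(s) missing from taxonomy: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript id in reference", call. = FALSE)

  feats <- sketch_seqs(transcripts$sequence, params)
  table <- tibble::tibble(
    feature = feats$feature,
    transcript = feats$seq,
    window = feats$window
  )
  table <- cap_features(table, params$max_locations)

  structure(
    list(
      params = params,
      table = table,
      taxonomy = tax,
      transcript_ids = transcripts$id,
      window_counts = cpp_window_counts(nchar(transcripts$sequence),
                                        params$k, params$t)
    ),
    class = "sketch_db"
  )
}

#' Drop over-represented features from a feature table
#'
#' Features whose location list is longer than `max_locations` are removed
#' entirely (not truncated), avoiding both hash-table overflow and
#' location-order bias; all other entries pass through unchanged.
#'
#' @param table Tibble with columns `feature`, `transcript`, `window`.
#' @param max_locations Cap on locations per feature (inclusive: a feature
#'   with exactly `max_locations` locations is kept).
#' @return The filtered table, original row order preserved.
#' @export
cap_features <- function(table, max_locations) {
  stopifnot(max_locations >= 1)
  table |>
    dplyr::add_count(.data$feature, name = ".n_loc") |>
    dplyr::filter(.data$.n_loc <= max_locations) |>
    dplyr::select(-".n_loc")
}

#' @export
print.sketch_db <- function(x, ...) {
  cat(sprintf(
    "<sketch_db> %d transcripts, %d genes, %d distinct features, %d locations\n",
    length(x$transcript_ids), length(x$taxonomy$gene_order),
    dplyr::n_distinct(x$table$feature), nrow(x$table)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sketch_db <- function(x, ...) {
  tibble::tibble(
    feature = x$table$feature,
    transcript = x$transcript_ids[x$table$transcript],
    window = x$table$window
  )
}

#' @exportS3Method generics::glance
glance.sketch_db <- function(x, ...) {
  tibble::tibble(
    n_transcripts = length(x$transcript_ids),
    n_genes = length(x$taxonomy$gene_order),
    n_features = dplyr::n_distinct(x$table$feature),
    n_locations = nrow(x$table),
    k = x$params$k, s = x$params$s, w = x$params$w, t = x$params$t
  )
}

DB_MAGIC <- "dropsketch-db"
DB_VERSION <- 1L

#' Save or load a sketch database
#'
#' The on-disk file is a versioned container; `load_database(save_database(db))`
#' reproduces the database exactly, including feature-table row order.
#' Files with a wrong magic tag or version, or truncated files, raise a
#' load error.
#'
#' @param db A `sketch_db` object.
#' @param path Database file path.
#' @return `save_database()` returns `path` invisibly; `load_database()`
#'   returns the `sketch_db`.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "sketch_db"))
  saveRDS(list(magic = DB_MAGIC, version = DB_VERSION, db = db), path)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable dropsketch database (truncated or foreign file): ",
         path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$magic, DB_MAGIC))
    stop("not a dropsketch database file: ", path, call. = FALSE)
  if (!identical(obj$version, DB_VERSION))
    stop("unsupported database version ", obj$version, " in ", path,
         call. = FALSE)
  obj$db
}
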