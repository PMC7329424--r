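#' Run the full count-matrix pipeline
#'
#' Executes the three stages in order with stage barriers: (1) barcode
#' counting and whitelist construction (skipped when a whitelist is
#' supplied), (2) sketch-based read mapping with barcode correction, (3)
#' directional UMI deduplication, followed by matrix assembly and,
#' optionally, output. Reads are processed in `batches` independent
#' batches whose merge is associative and order-normalized, so the result
#' is identical for any batch count.
#'
#' @param db A `sketch_db` (or a path readable by [load_database()]).
#' @param r1,r2 Paths to the mate-1/mate-2 FASTQ files (optionally
#'   gzipped). Alternatively supply `pairs` directly.
#' @param pairs Optional in-memory read-pair tibble (overrides `r1`/`r2`).
#' @param params A [sketch_params()]; defaults to the database's.
#' @param whitelist Optional externally supplied whitelist (tibble with a
#'   `cb` column, a character vector of barcodes, or a TSV path); skips
#'   stage 1.
#' @param whitelist_fraction Fraction for [build_whitelist()] when the
#'   whitelist is inferred.
#' @param batches Number of processing batches (determinism contract: any
#'   value yields identical output).
#' @param out_dir Optional output directory: writes the matrix files, a
#'   `run_summary.json`, and `whitelist.tsv`.
#' @param dialect Matrix output dialect, see [write_matrix()].
#' @param keep_records Keep the per-read mapping records in the result.
#' @param cb_method Barcode edit-distance model, see [correct_barcode()].
#' @return A `pipeline_run`: fields `matrix` (a `gene_cell_matrix`),
#'   `molecule_counts`, `whitelist`, `stats` (named list of stage counts),
#'   `params`, and `records` (if kept).
#' @export
run_pipeline <- function(db, r1 = NULL, r2 = NULL, pairs = NULL,
                         params = NULL, whitelist = NULL,
                         whitelist_fraction = NULL, batches = 1L,
                         out_dir = NULL, dialect = "native",
                         keep_records = TRUE, cb_method = "levenshtein") {
  if (is.character(db)) db <- load_database(db)
  stopifnot(inherits(db, "sketch_db"))
  if (is.null(params)) params <- db$params
  if (is.null(whitelist_fraction))
    whitelist_fraction <- params$whitelist_fraction
  if (is.null(pairs)) {
    if (is.null(r1) || is.null(r2))
      stop("supply either `pairs` or both `r1` and `r2`", call. = FALSE)
    pairs <- read_fastq_pairs(r1, r2)
  }
  n <- nrow(pairs)
  batches <- max(1L, min(as.integer(batches), max(n, 1L)))
  batch_of <- if (n > 0) sort(rep_len(seq_len(batches), n)) else integer()

  # stage 1: whitelist (barrier: complete before any mapping)
  if (is.null(whitelist)) {
    counts <- merge_barcode_counts(lapply(
      split(seq_len(n), batch_of),
      function(idx) count_barcodes(pairs[idx, ], params)
    ))
    wl <- build_whitelist(counts, whitelist_fraction)
  } else {
    wl <- normalize_whitelist(whitelist)
  }

  # stage 2: mapping (barrier: all batches mapped before deduplication)
  records <- if (n == 0) {
    map_reads(db, pairs, wl, params, cb_method = cb_method)
  } else {
    dplyr::bind_rows(lapply(
      split(seq_len(n), batch_of),
      function(idx) {
        r <- map_reads(db, pairs[idx, ], wl, params, cb_method = cb_method)
        r$read <- idx[r$read]
        r
      }
    )) |> dplyr::arrange(.data$read)
  }

  # stage 3: directional deduplication, cells partitioned across batches
  mapped_cbs <- sort(unique(records$cb[records$status == "mapped"]))
  molecule_counts <- if (length(mapped_cbs) == 0) {
    dedup_records(records[0, ], params$dedup_factor)
  } else {
    cell_batch <- rep_len(seq_len(batches), length(mapped_cbs))
    dplyr::bind_rows(lapply(
      split(mapped_cbs, cell_batch),
      function(cbs) dedup_records(
        dplyr::filter(records, .data$cb %in% cbs), params$dedup_factor
      )
    )) |> dplyr::arrange(.data$cb, .data$gene)
  }

  mat <- assemble_matrix(molecule_counts, db$taxonomy)
  stats <- c(
    list(n_reads = n,
         n_whitelisted_cbs = nrow(wl),
         n_cells = length(mat$cell_ids),
         n_molecules = sum(mat$triplets$count),
         nnz = nrow(mat$triplets)),
    as.list(table(records$status))
  )

  run <- structure(
    list(matrix = mat, molecule_counts = molecule_counts, whitelist = wl,
         stats = stats, params = params,
         records = if (keep_records) records else NULL),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(mat, out_dir, dialect)
    write_whitelist(wl, file.path(out_dir, "whitelist.tsv"))
    jsonlite::write_json(stats, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run
}

normalize_whitelist <- function(whitelist) {
  if (is.character(whitelist) && length(whitelist) == 1 &&
      file.exists(whitelist)) {
    whitelist <- read_whitelist(whitelist)
  }
  if (is.character(whitelist)) {
    whitelist <- tibble::tibble(cb = whitelist, n = NA_integer_)
  }
  stopifnot(is.data.frame(whitelist), "cb" %in% names(whitelist))
  if (!"n" %in% names(whitelist)) whitelist$n <- NA_integer_
  whitelist$n[is.na(whitelist$n)] <- 1L
  whitelist
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$stats
  cat("<pipeline_run>\n")
  cat(sprintf("  reads: %d  whitelisted CBs: %d\n",
              s$n_reads, s$n_whitelisted_cbs))
  cat(sprintf("  mapped: %s  malformed: %s  cb_unmatched: %s  unmapped: %s  ambiguous_gene: %s\n",
              s$mapped, s$malformed, s$cb_unmatched, s$unmapped,
              s$ambiguous_gene))
  cat(sprintf("  cells: %d  molecules: %d  nonzero entries: %d\n",
              s$n_cells, s$n_molecules, s$nnz))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pipeline_run <- function(x, ...) {
  tibble::as_tibble(x$stats)
}

#' @exportS3Method generics::tidy
tidy.pipeline_run <- function(x, ...) {
  tidy(x$matrix)
}

#' Build a database from reference files
#'
#' Thin orchestration over [read_fasta()], [parse_gtf_tx2gene()],
#' [build_database()] and [save_database()]; the `build` CLI subcommand.
#'
#' @param fasta Reference transcriptome FASTA.
#' @param gtf Annotation GTF supplying the transcript-to-gene taxonomy.
#' @param out Optional database output path.
#' @param params A [sketch_params()].
#' @return The `sketch_db`, invisibly when `out` is given.
#' @export
build_database_files <- function(fasta, gtf, out = NULL,
                                 params = sketch_params()) {
  db <- build_database(read_fasta(fasta), parse_gtf_tx2gene(gtf), params)
  if (!is.null(out)) {
    save_database(db, out)
    return(invisible(db))
  }
  db
}
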