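#' Read a FASTA reference into a tibble
#'
#' Record ids are truncated at the first whitespace of the header and
#' sequences are uppercased, so `">a desc\nacgt"` yields id `"a"` and
#' sequence `"ACGT"`. Multi-line sequences are concatenated.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (length(set) > 0 && any(!nzchar(ids)))
    stop("malformed FASTA in ", path, ": empty record id", call. = FALSE)
  tibble::tibble(id = ids, sequence = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read paired FASTQ files into a tibble of read pairs
#'
#' Mates are paired positionally: record n of the first file pairs with
#' record n of the second (the 10x layout); read names are not parsed.
#' Gzipped input is handled transparently.
#'
#' @param path_r1 Mate-1 FASTQ (cell barcode + UMI).
#' @param path_r2 Mate-2 FASTQ (cDNA).
#' @return A tibble with columns `name`, `mate1_seq`, `mate2_seq`,
#'   `mate1_qual`, `mate2_qual`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    short <- if (nrow(r1) < nrow(r2)) path_r1 else path_r2
    stop(sprintf(
      "record count mismatch: %s has %d records, %s has %d (%s ended first)",
      path_r1, nrow(r1), path_r2, nrow(r2), short), call. = FALSE)
  }
  tibble::tibble(
    name = r1$name,
    mate1_seq = r1$seq, mate2_seq = r2$seq,
    mate1_qual = r1$qual, mate2_qual = r2$qual
  )
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  quals <- S4Vectors::mcols(set)$qualities
  tibble::tibble(
    name = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set))),
    qual = if (is.null(quals)) NA_character_ else unname(as.character(quals))
  )
}

#' Write paired reads to FASTQ
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()]; missing quality
#'   columns are filled with `"I"`.
#' @param path_r1,path_r2 Output paths; a `.gz` suffix triggers compression.
#' @return Invisibly, `c(path_r1, path_r2)`.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_fastq_one(pairs$name, pairs$mate1_seq, pairs$mate1_qual, path_r1)
  write_fastq_one(pairs$name, pairs$mate2_seq, pairs$mate2_qual, path_r2)
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(names, seqs, quals, path) {
  if (is.null(quals) || all(is.na(quals)))
    quals <- strrep("I", nchar(seqs))
  set <- Biostrings::DNAStringSet(setNames(seqs, names))
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path)
  )
}

#' Extract the transcript-to-gene taxonomy from a GTF annotation
#'
#' Scans every feature row whose attribute column carries both a
#' `transcript_id` and a `gene_id` (both `key "value";` and `key value;`
#' attribute dialects are accepted). Gene order is the order of first
#' appearance in the file; duplicate (transcript, gene) assignments collapse
#' silently, but a transcript annotated to two different genes is an error.
#'
#' @param path Path to a GTF file (plain or gzipped; `#` comments ignored).
#' @return A `tx_taxonomy` object; see [taxonomy()].
#' @export
parse_gtf_tx2gene <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(taxonomy(character(), character()))
  fields <- stringr::str_split_fixed(lines, "\t", 9)
  bad <- which(!nzchar(fields[, 9]))
  if (length(bad) > 0)
    stop("malformed GTF line (fewer than 9 tab-separated fields): line ",
         bad[1], call. = FALSE)
  attrs <- fields[, 9]
  tx <- stringr::str_match(attrs, "transcript_id\\s+\"?([^\";]+)\"?")[, 2]
  gene <- stringr::str_match(attrs, "gene_id\\s+\"?([^\";]+)\"?")[, 2]
  missing_gene <- !is.na(tx) & is.na(gene)
  if (any(missing_gene))
    stop("GTF row with transcript_id but no gene_id: line ",
         which(missing_gene)[1], call. = FALSE)
  keep <- !is.na(tx) & !is.na(gene)
  taxonomy(tx[keep], gene[keep])
}

#' Build a two-level transcript-to-gene taxonomy
#'
#' @param transcripts Character vector of transcript ids (repeats allowed).
#' @param genes Matching character vector of gene ids.
#' @return A `tx_taxonomy` object with fields `tx2gene` (named character
#'   vector), `gene_order`, `transcript_order`.
#' @export
taxonomy <- function(transcripts, genes) {
  stopifnot(length(transcripts) == length(genes))
  pairs <- tibble::tibble(transcript = transcripts, gene = genes) |>
    dplyr::distinct(.data$transcript, .data$gene)
  dup <- pairs |> dplyr::count(.data$transcript) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("transcript mapped to multiple genes: ",
         paste(dup$transcript, collapse = ", "), call. = FALSE)
  structure(
    list(
      tx2gene = setNames(pairs$gene, pairs$transcript),
      gene_order = unique(pairs$gene),
      transcript_order = pairs$transcript
    ),
    class = "tx_taxonomy"
  )
}

#' @export
print.tx_taxonomy <- function(x, ...) {
  cat(sprintf("<tx_taxonomy> %d transcripts -> %d genes\n",
              length(x$tx2gene), length(x$gene_order)))
  invisible(x)
}

#' @rdname taxonomy
#' @param x A `tx_taxonomy` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tx_taxonomy <- function(x, ...) {
  tibble::tibble(transcript = names(x$tx2gene), gene = unname(x$tx2gene))
}

#' Write a minimal transcript-level GTF for a taxonomy
#'
#' Each transcript becomes one `transcript` feature row on its own
#' "contig" with `gene_id`/`transcript_id` attributes; lengths default to 1.
#'
#' @param tax A `tx_taxonomy` object.
#' @param path Output path.
#' @param lengths Optional named integer vector of transcript lengths.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tax, path, lengths = NULL) {
  tx <- names(tax$tx2gene)
  len <- if (is.null(lengths)) rep(1L, length(tx)) else unname(lengths[tx])
  lines <- sprintf(
    '%s\tdropsketch\ttranscript\t1\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
    tx, len, unname(tax$tx2gene), tx
  )
  writeLines(lines, path)
  invisible(path)
}
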