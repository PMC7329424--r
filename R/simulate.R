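#' Simulation configuration
#'
#' Describes a synthetic droplet scRNA-seq experiment: a multi-isoform
#' transcriptome (isoforms of one gene share at least half their sequence;
#' optional gene pairs share a verbatim read-length block, creating true
#' gene ambiguity), a known set of well-separated cell barcodes, and
#' per-molecule UMIs with PCR duplication and substitution errors.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (isoform 1 is the base).
#' @param shared_block_genes Number of gene *pairs* that share a verbatim
#'   block of `read_length + 10` bases (exercises gene-ambiguous reads).
#' @param transcript_length Length range `c(min, max)` of base isoforms.
#' @param n_cells Number of true cells (= size of the true barcode set).
#' @param cb_len,umi_len Barcode and UMI lengths.
#' @param min_cb_dist Minimum pairwise Hamming distance among true
#'   barcodes (rejection-sampled).
#' @param mean_molecules Poisson mean of molecules per (cell, gene).
#' @param pcr_rate Per-molecule duplication probability; reads per molecule
#'   are `1 + Binomial(pcr_max_dup, pcr_rate)`.
#' @param pcr_max_dup Maximum extra PCR copies per molecule.
#' @param cb_error_rate,umi_error_rate,cdna_error_rate Per-base
#'   substitution error rates applied to the barcode, UMI and cDNA parts.
#' @param read_length cDNA read length `R`.
#' @param start_mode `"uniform"`: molecule start positions uniform over
#'   valid offsets; `"window"`: starts restricted to reference window
#'   boundaries (multiples of the stride), where error-free reads carry a
#'   provable minimum mapping score.
#' @param stride Stride used for `"window"` starts (match the pipeline's).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, isoforms_per_gene = 2L,
                       shared_block_genes = 0L,
                       transcript_length = c(250L, 500L),
                       n_cells = 50L, cb_len = 16L, umi_len = 10L,
                       min_cb_dist = 3L, mean_molecules = 2,
                       pcr_rate = 0, pcr_max_dup = 3L,
                       cb_error_rate = 0, umi_error_rate = 0,
                       cdna_error_rate = 0, read_length = 98L,
                       start_mode = c("uniform", "window"), stride = 41L) {
  start_mode <- match.arg(start_mode)
  stopifnot(
    n_genes >= 1, isoforms_per_gene >= 1,
    shared_block_genes >= 0, 2 * shared_block_genes <= n_genes,
    length(transcript_length) == 2,
    transcript_length[1] >= read_length,
    transcript_length[1] <= transcript_length[2],
    n_cells >= 1, cb_len >= 1, umi_len >= 1, min_cb_dist >= 1,
    mean_molecules > 0, pcr_rate >= 0, pcr_rate <= 1, pcr_max_dup >= 0,
    cb_error_rate >= 0, cb_error_rate <= 1,
    umi_error_rate >= 0, umi_error_rate <= 1,
    cdna_error_rate >= 0, cdna_error_rate <= 1,
    read_length >= 1, stride >= 1
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      isoforms_per_gene = as.integer(isoforms_per_gene),
      shared_block_genes = as.integer(shared_block_genes),
      transcript_length = as.integer(transcript_length),
      n_cells = as.integer(n_cells), cb_len = as.integer(cb_len),
      umi_len = as.integer(umi_len), min_cb_dist = as.integer(min_cb_dist),
      mean_molecules = mean_molecules, pcr_rate = pcr_rate,
      pcr_max_dup = as.integer(pcr_max_dup),
      cb_error_rate = cb_error_rate, umi_error_rate = umi_error_rate,
      cdna_error_rate = cdna_error_rate,
      read_length = as.integer(read_length),
      start_mode = start_mode, stride = as.integer(stride)
    ),
    class = "sim_config"
  )
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base substitution errors at the given rate; substituted bases are
# always changed (drawn from the three other bases).
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) {
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample(1:3, sum(hit), replace = TRUE)
    idx <- match(flat[hit], bases)
    ok <- !is.na(idx)
    flat[hit][ok] <- bases[((idx[ok] - 1L + shift[ok]) %% 4L) + 1L]
  }
  grp <- rep(seq_along(seqs), lens)
  list(
    seqs = vapply(split(flat, grp), paste, character(1), collapse = ""),
    n_errors = as.integer(tapply(hit, grp, sum))
  )
}

# Sample n distinct strings with pairwise Hamming distance >= min_dist.
sample_separated_codes <- function(n, len, min_dist) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- random_dna(1, len)
    if (length(out) == 0 ||
        min(cpp_hamming_cross(cand, out)) >= min_dist) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("cannot sample ", n, " codes of length ", len,
           " at pairwise distance >= ", min_dist, call. = FALSE)
  }
  out
}

#' Simulate a multi-isoform reference transcriptome
#'
#' Isoform 1 of each gene is a random sequence; further isoforms keep a
#' 60% prefix of the base isoform and get a fresh random tail, so isoforms
#' of one gene share more than half their sequence. For each of the first
#' `shared_block_genes` gene pairs, a common random block of
#' `read_length + 10` bases is implanted verbatim into isoform 1 of both
#' genes, so reads from the block are genuinely gene-ambiguous.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the reference
#'   byte-for-byte.
#' @param dir Optional directory: writes `ref.fa` and `ann.gtf`.
#' @return List with `transcripts` (tibble `id`, `sequence`, `gene`),
#'   `taxonomy`, and (if `dir` given) `paths`.
#' @export
simulate_reference <- function(config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  rows <- list()
  for (g in seq_len(config$n_genes)) {
    L <- sample(config$transcript_length[1]:config$transcript_length[2], 1)
    base <- random_dna(1, L)
    for (i in seq_len(config$isoforms_per_gene)) {
      seq_i <- if (i == 1) base else {
        keep <- ceiling(0.6 * L)
        paste0(substr(base, 1, keep), random_dna(1, L - keep))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("%s.t%d", genes[g], i),
        sequence = seq_i, gene = genes[g]
      )
    }
  }
  transcripts <- dplyr::bind_rows(rows)
  if (config$shared_block_genes > 0) {
    block_len <- config$read_length + 10L
    for (p in seq_len(config$shared_block_genes)) {
      block <- random_dna(1, block_len)
      for (g in c(2L * p - 1L, 2L * p)) {
        idx <- which(transcripts$gene == genes[g])[1]
        s <- transcripts$sequence[idx]
        # overwrite the tail so transcript length is unchanged
        transcripts$sequence[idx] <- paste0(
          substr(s, 1, nchar(s) - block_len), block
        )
      }
    }
  }
  tax <- taxonomy(transcripts$id, transcripts$gene)
  out <- list(transcripts = transcripts, taxonomy = tax)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "ref.fa")
    gtf <- file.path(dir, "ann.gtf")
    write_fasta(transcripts, fa)
    write_gtf(tax, gtf, setNames(nchar(transcripts$sequence), transcripts$id))
    out$paths <- c(fasta = fa, gtf = gtf)
  }
  out
}

#' Simulate a barcoded paired-end read set with known ground truth
#'
#' Each (cell, gene) gets a Poisson number of molecules; each molecule
#' picks a random isoform, a UMI (per-group UMIs are drawn at pairwise
#' Hamming distance >= 2 so the directional collapse can never merge two
#' true molecules -- an idealization of "unique" identifiers), and a start
#' position. Each molecule yields `1 + Binomial(pcr_max_dup, pcr_rate)`
#' reads. Mate 1 is barcode + UMI with per-base substitution errors at the
#' configured rates; mate 2 is `read_length` transcript bases, reverse
#' complemented with probability 1/2, with cDNA errors. The truth matrix
#' counts molecules, not reads.
#'
#' @param reference A [simulate_reference()] result.
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @param dir Optional directory: writes `R1.fastq.gz`, `R2.fastq.gz`,
#'   `true_barcodes.tsv` and the truth matrix (native dialect).
#' @return List with `pairs` (read-pair tibble), `truth`
#'   (a `gene_cell_matrix`), `provenance` (per-read tibble), `cb_set`.
#' @export
simulate_experiment <- function(reference, config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed + 1L)
  tx <- reference$transcripts
  cb_set <- sample_separated_codes(config$n_cells, config$cb_len,
                                   config$min_cb_dist)
  R <- config$read_length

  mols <- tidyr::expand_grid(cb = cb_set, gene = unique(tx$gene)) |>
    dplyr::mutate(n_mol = rpois(dplyr::n(), config$mean_molecules)) |>
    dplyr::filter(.data$n_mol > 0)

  mol_rows <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    n_mol <- mols$n_mol[i]
    iso_pool <- which(tx$gene == mols$gene[i])
    umis <- sample_separated_codes(n_mol, config$umi_len, 2L)
    iso <- integer(n_mol); start <- integer(n_mol)
    for (m in seq_len(n_mol)) {
      repeat { # resample transcripts shorter than the read
        cand <- sample(iso_pool, 1)
        if (nchar(tx$sequence[cand]) >= R) break
      }
      iso[m] <- cand
      L <- nchar(tx$sequence[cand])
      start[m] <- if (config$start_mode == "window") {
        config$stride * sample.int((L - R) %/% config$stride + 1L, 1L) -
          config$stride
      } else {
        sample.int(L - R + 1L, 1L) - 1L
      }
    }
    mol_rows[[i]] <- tibble::tibble(
      cb = mols$cb[i], gene = mols$gene[i], umi = umis,
      transcript = tx$id[iso], position = start,
      fragment = substr(tx$sequence[iso], start + 1L, start + R)
    )
  }
  molecules <- dplyr::bind_rows(mol_rows)

  n_reads_per_mol <- 1L + rbinom(nrow(molecules), config$pcr_max_dup,
                                 config$pcr_rate)
  reads <- molecules[rep(seq_len(nrow(molecules)), n_reads_per_mol), ]
  reads$molecule <- rep(seq_len(nrow(molecules)), n_reads_per_mol)

  rc <- runif(nrow(reads)) < 0.5
  r2 <- ifelse(rc, revcomp(reads$fragment), reads$fragment)
  cb_err <- apply_substitutions(reads$cb, config$cb_error_rate)
  umi_err <- apply_substitutions(reads$umi, config$umi_error_rate)
  r2_err <- apply_substitutions(r2, config$cdna_error_rate)

  names_ <- sprintf("read%06d", seq_len(nrow(reads)))
  pairs <- tibble::tibble(
    name = names_,
    mate1_seq = paste0(cb_err$seqs, umi_err$seqs),
    mate2_seq = r2_err$seqs,
    mate1_qual = strrep("I", config$cb_len + config$umi_len),
    mate2_qual = strrep("I", nchar(r2_err$seqs))
  )
  provenance <- tibble::tibble(
    name = names_,
    cb = reads$cb, gene = reads$gene, umi = reads$umi,
    transcript = reads$transcript, position = reads$position,
    molecule = reads$molecule, revcomp = rc,
    cb_errors = cb_err$n_errors, umi_errors = umi_err$n_errors,
    cdna_errors = r2_err$n_errors
  )
  truth <- molecules |>
    dplyr::count(.data$cb, .data$gene, name = "molecules") |>
    assemble_matrix(reference$taxonomy)

  out <- list(pairs = pairs, truth = truth, provenance = provenance,
              cb_set = cb_set)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq_pairs(pairs, file.path(dir, "R1.fastq.gz"),
                      file.path(dir, "R2.fastq.gz"))
    writeLines(cb_set, file.path(dir, "true_barcodes.tsv"))
    write_matrix(truth, file.path(dir, "truth"))
    out$paths <- c(
      r1 = file.path(dir, "R1.fastq.gz"), r2 = file.path(dir, "R2.fastq.gz"),
      barcodes = file.path(dir, "true_barcodes.tsv"),
      truth = file.path(dir, "truth")
    )
  }
  out
}
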