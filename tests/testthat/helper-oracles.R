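# Independent oracles and small fixture builders used across the suite.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

kmers_of <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  substring(seq, 1:(L - k + 1), k:L)
}

# Brute-force sketch of a window: hash every k-mer, drop invalid ones,
# deduplicate, sort, keep the s smallest. Shares only the scalar hash
# primitive with the package's windowed C++ path.
oracle_sketch <- function(window_seq, params) {
  h <- hash_kmers(kmers_of(window_seq, params$k))
  h <- sort(unique(h[!is.na(h)]))
  head(h, params$s)
}

# Brute-force per-transcript mapping scores for one read: no hash table --
# every read-window sketch is compared directly against every reference
# window sketch, hits are summed per reference window, and the range rule
# is applied by explicit sliding-window enumeration.
oracle_map_scores <- function(transcripts, read_seq, params) {
  k <- params$k
  read_windows <- if (nchar(read_seq) >= k) {
    sp <- window_spans(nchar(read_seq), params)
    lapply(seq_len(nrow(sp)), function(i) {
      oracle_sketch(substr(read_seq, sp$start[i] + 1, sp$end[i]), params)
    })
  } else list()
  vapply(transcripts, function(tx) {
    if (nchar(tx) < k) return(0L)
    sp <- window_spans(nchar(tx), params)
    hits <- integer(nrow(sp))
    for (i in seq_len(nrow(sp))) {
      ref_sketch <- oracle_sketch(substr(tx, sp$start[i] + 1, sp$end[i]),
                                  params)
      for (rw in read_windows) hits[i] <- hits[i] + sum(rw %in% ref_sketch)
    }
    best <- 0L
    for (j in seq_len(nrow(sp))) { # range start at window j-1
      upto <- min(j + params$r - 1L, nrow(sp))
      best <- max(best, sum(hits[j:upto]))
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

# Package-path mapping scores for one read against a database: sketch,
# table lookup, range accumulation.
db_map_scores <- function(db, read_seq, params = db$params) {
  hits <- lookup_hits(db, sketch_read(read_seq, params))
  n_tx <- length(db$transcript_ids)
  out <- integer(n_tx)
  if (nrow(hits) == 0) return(out)
  for (tx in unique(hits$transcript)) {
    h <- hits[hits$transcript == tx, c("window", "hits")]
    out[tx] <- best_range_score(h, params$r)
  }
  out
}

# Brute-force directional UMI collapse: explicit edge matrix + traversal.
oracle_count_molecules <- function(umis, counts, factor = 2) {
  n <- length(umis)
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(chars[i, ] != chars[j, ])
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    edge[i, j] <- i != j && d[i, j] == 1L && counts[i] >= factor * counts[j] - 1
  ord <- order(-counts, umis)
  visited <- rep(FALSE, n)
  molecules <- 0L
  for (seed in ord) {
    if (visited[seed]) next
    molecules <- molecules + 1L
    stack <- seed
    visited[seed] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[1]
      stack <- stack[-1]
      nxt <- which(edge[cur, ] & !visited)
      visited[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
  }
  molecules
}

# Small reference fixture: n_tx random transcripts over n_genes genes.
make_reference <- function(n_tx, n_genes = max(1, n_tx %/% 2),
                           len_range = c(100, 500)) {
  lens <- sample(len_range[1]:len_range[2], n_tx, replace = TRUE)
  tibble::tibble(
    id = sprintf("tx%03d", seq_len(n_tx)),
    sequence = vapply(lens, random_seq, character(1)),
    gene = sprintf("g%03d", rep_len(seq_len(n_genes), n_tx))
  )
}

make_db <- function(ref, params = sketch_params()) {
  build_database(ref[, c("id", "sequence")], taxonomy(ref$id, ref$gene),
                 params)
}
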