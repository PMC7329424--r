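test_that("canonical k-mer encoding is strand-symmetric and N-aware", {
  expect_equal(encode_canonical_kmer(strrep("A", 16)), 0)
  set.seed(21)
  kmers <- vapply(rep(16, 50), random_seq, character(1))
  expect_equal(encode_canonical_kmer(kmers), encode_canonical_kmer(revcomp(kmers)))
  expect_true(is.na(encode_canonical_kmer("ACGTNACGTACGTACG")))
  expect_error(encode_canonical_kmer(c("ACGT", "ACGTA")), "length")
  # h1 is deterministic and respects canonicalization
  expect_equal(hash_kmers(kmers), hash_kmers(revcomp(kmers)))
  expect_equal(hash_kmers(kmers), hash_kmers(kmers))
})

test_that("window spans follow the stride rule and truncate at the sequence end", {
  p <- sketch_params() # k=16, w=56, t=41
  sp <- window_spans(98, p)
  expect_equal(sp$start, c(0, 41, 82))
  expect_equal(sp$end, c(56, 97, 98))
  expect_equal(window_spans(56, p),
               tibble::tibble(window = 0L, start = 0L, end = 56L))
  short <- window_spans(10, p)
  expect_equal(short, tibble::tibble(window = 0L, start = 0L, end = 10L))
})

test_that("every k-mer start position is covered by at least one window", {
  set.seed(22)
  grid <- expand.grid(k = c(4L, 16L), w_extra = c(0L, 5L, 16L))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]
    w <- k + grid$w_extra[i]
    for (t in unique(c(1L, (w - k) %/% 2L + 1L, w - k + 1L))) {
      p <- sketch_params(k = k, w = w, t = t, read_length = 98)
      for (L in sample(k:500, 25)) {
        sp <- window_spans(L, p)
        # union of spans covers the sequence
        expect_equal(min(sp$start), 0L)
        expect_equal(max(sp$end), L)
        expect_true(all(sp$start[-1] <= sp$end[-nrow(sp)])) # no gaps
        covered <- unique(unlist(Map(
          function(s, e) if (e - s >= k) s:(e - k) else integer(),
          sp$start, sp$end
        )))
        expect_setequal(covered, 0:(L - k))
      }
    }
  }
})

test_that("window sketches equal the s smallest brute-force k-mer hashes", {
  set.seed(23)
  for (rep in 1:25) {
    p <- sketch_params(k = sample(c(5L, 11L, 16L), 1), s = sample(c(3L, 16L), 1))
    len <- sample(p$k:120, 1)
    seq <- random_seq(len)
    got <- sketch_window(seq, 0, len, p)
    expect_identical(got, oracle_sketch(seq, p))
    expect_true(!is.unsorted(got, strictly = TRUE) || length(got) <= 1)
    expect_lte(length(got), p$s)
  }
  # windows with fewer than s distinct k-mers keep them all
  p <- sketch_params()
  seq <- random_seq(20) # 5 k-mers
  expect_lte(length(sketch_window(seq, 0, 20, p)), 5)
  expect_identical(sketch_window(seq, 0, 20, p), oracle_sketch(seq, p))
  # k-mers containing N contribute nothing
  seqN <- paste0(substr(seq, 1, 10), "N", substr(seq, 12, 20))
  valid <- kmers_of(seqN, p$k)
  expect_identical(sketch_window(seqN, 0, 20, p),
                   sort(unique(hash_kmers(valid)[!is.na(hash_kmers(valid))])))
})

test_that("appending a base whose new k-mer hashes above the sketch maximum changes nothing", {
  set.seed(24)
  p <- sketch_params(k = 8L, s = 4L)
  grown <- 0L
  kept <- 0L
  for (rep in 1:200) {
    seq <- random_seq(30)
    base_sketch <- sketch_window(seq, 0, 30, p)
    for (b in c("A", "C", "G", "T")) {
      ext <- paste0(seq, b)
      new_kmer <- substr(ext, 32 - p$k, 31)
      new_hash <- hash_kmers(new_kmer)
      ext_sketch <- sketch_window(ext, 0, 31, p)
      if (new_hash > max(base_sketch)) {
        expect_identical(ext_sketch, base_sketch)
        kept <- kept + 1L
      } else {
        expect_identical(ext_sketch,
                         head(sort(unique(c(base_sketch, new_hash))), p$s))
        grown <- grown + 1L
      }
    }
  }
  expect_gt(kept, 50)
  expect_gt(grown, 50)
})

test_that("sketching is deterministic and identical across reference and read paths", {
  set.seed(25)
  p <- sketch_params()
  seq <- random_seq(150)
  a <- sketch_seqs(seq, p)
  b <- sketch_seqs(seq, p)
  expect_identical(a, b)
  # a read equal to a reference window reproduces that window's sketch
  sp <- window_spans(150, p)
  win_seq <- substr(seq, sp$start[2] + 1, sp$end[2])
  read_sk <- sketch_read(win_seq, p)
  expect_identical(read_sk$feature, sketch_window(seq, sp$start[2], sp$end[2], p))
})
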