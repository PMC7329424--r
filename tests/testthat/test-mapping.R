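test_that("a 98-base read under default parameters offers at most 33 features", {
  p <- sketch_params()
  sp <- window_spans(98, p)
  caps <- pmin(sp$end - sp$start - p$k + 1L, p$s)
  expect_equal(caps, c(16L, 16L, 1L))
  expect_equal(max_read_features(p), 33L)
  # a 16-base read has one window and at most one feature
  expect_lte(nrow(sketch_read(random_seq(16), p)), 1)
  expect_equal(nrow(sketch_read(random_seq(10), p)), 0)
})

test_that("feature lookup accumulates one hit per occurrence per location", {
  set.seed(51)
  p <- sketch_params()
  ref <- make_reference(4, 2, c(150, 400))
  db <- make_db(ref, p)

  # disjoint alphabet read: no shared features
  none <- lookup_hits(db, sketch_read(strrep("A", 98), p))
  # (an all-A read has one distinct k-mer; only matches if reference has it)
  expect_true(nrow(none) <= nrow(db$table))

  # read copied from a reference window recovers that window at full count
  sp <- window_spans(nchar(ref$sequence[1]), p)
  win_seq <- substr(ref$sequence[1], sp$start[2] + 1, sp$end[2])
  hits <- lookup_hits(db, sketch_read(win_seq, p))
  own <- hits[hits$transcript == 1 & hits$window == 1, ]
  expect_equal(own$hits, length(sketch_window(ref$sequence[1], sp$start[2],
                                              sp$end[2], p)))

  # a feature occurring in two read windows counts twice at its location
  pk <- sketch_params(k = 16, s = 64, w = 20, t = 5, read_length = 40,
                      threshold = 1)
  K <- random_seq(16)
  refk <- tibble::tibble(id = "t", sequence = K)
  dbk <- build_database(refk, taxonomy("t", "g"), pk)
  read <- paste0(K, "CCCC", K) # K owned by read windows 0 and 4
  h <- lookup_hits(dbk, sketch_read(read, pk))
  expect_equal(h$hits[h$transcript == 1 & h$window == 0], 2L)
})

test_that("range accumulation takes the best window of size r", {
  hits <- tibble::tibble(window = c(0L, 2L, 3L), hits = c(3L, 5L, 2L))
  expect_equal(best_range_score(hits, 2), 7L)
  expect_equal(best_range_score(hits, 1), 5L)
  far <- tibble::tibble(window = c(0L, 10L), hits = c(3L, 5L))
  expect_equal(best_range_score(far, 2), 5L) # spread-out hits never aggregate
  expect_equal(best_range_score(far[0, ], 3), 0L)
  # named-vector form
  expect_equal(best_range_score(c(`0` = 3, `2` = 5, `3` = 2), 2), 7L)
})

test_that("candidate selection is inclusive and gene resolution handles all cases", {
  set.seed(52)
  scores <- tibble::tibble(transcript = 1:3, score = c(30L, 27L, 28L))
  cand <- select_candidates(scores, 28)
  expect_setequal(cand$transcript, c(1L, 3L))
  expect_equal(nrow(select_candidates(scores, 40)), 0)

  ref <- make_reference(3, 2) # tx1,tx3 -> g001; tx2 -> g002
  db <- make_db(ref)
  same <- tibble::tibble(transcript = c(1L, 3L), score = c(30L, 29L))
  res <- resolve_gene(same, db)
  expect_equal(res$status, "mapped")
  expect_equal(res$gene, "g001")
  expect_equal(res$score, 30L)
  cross <- tibble::tibble(transcript = c(1L, 2L), score = c(30L, 29L))
  expect_equal(resolve_gene(cross, db)$status, "ambiguous_gene")
  expect_equal(resolve_gene(same[0, ], db)$status, "unmapped")
})

test_that("hash-table scores equal the brute-force sketch-comparison oracle", {
  set.seed(53)
  p <- sketch_params(max_locations = 10000L)
  for (inst in 1:12) {
    ref <- make_reference(sample(2:6, 1), 2, c(120, 450))
    db <- make_db(ref, p)
    for (j in 1:3) {
      src <- sample(nrow(ref), 1)
      L <- nchar(ref$sequence[src])
      read <- if (j == 1) {
        random_seq(98) # unrelated read
      } else {
        start <- sample(L - 98 + 1, 1)
        frag <- substr(ref$sequence[src], start, start + 97)
        if (j == 3) frag <- revcomp(frag)
        frag
      }
      expect_equal(db_map_scores(db, read, p),
                   oracle_map_scores(ref$sequence, read, p))
    }
  }
})

test_that("scores grow with r and candidate sets shrink with threshold", {
  set.seed(54)
  for (rep in 1:10) {
    hits <- tibble::tibble(
      window = sample(0:12, 6),
      hits = sample(1:8, 6, replace = TRUE)
    )
    s1 <- vapply(1:6, function(r) best_range_score(hits, r), integer(1))
    expect_true(all(diff(s1) >= 0))
  }
  scores <- tibble::tibble(transcript = 1:20,
                           score = sample(1:40, 20, replace = TRUE))
  sizes <- vapply(c(1, 10, 20, 30, 41),
                  function(th) nrow(select_candidates(scores, th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("map_read composes the stages with the right discard precedence", {
  set.seed(55)
  p <- sketch_params()
  cfg <- sim_config(n_genes = 4, n_cells = 5, mean_molecules = 2,
                    start_mode = "window")
  ref <- simulate_reference(cfg, seed = 5)
  db <- build_database(ref$transcripts[, c("id", "sequence")],
                       ref$taxonomy, p)
  sim <- simulate_experiment(ref, cfg, seed = 5)
  wl <- tibble::tibble(cb = sim$cb_set, n = 1L)

  # error-free read maps to its true gene and cell
  rec <- map_read(db, sim$pairs[1, ], wl, p)
  expect_equal(as.character(rec$status), "mapped")
  expect_equal(rec$gene, sim$provenance$gene[1])
  expect_equal(rec$cb, sim$provenance$cb[1])

  # a verbatim shared prefix between two genes makes its reads ambiguous
  shared <- random_seq(120)
  ref2 <- tibble::tibble(
    id = c("s1", "s2"),
    sequence = c(paste0(shared, random_seq(100)),
                 paste0(shared, random_seq(150)))
  )
  db2 <- build_database(ref2, taxonomy(c("s1", "s2"), c("gX", "gY")), p)
  pair <- tibble::tibble(mate1_seq = paste0(sim$cb_set[1], strrep("A", 10)),
                         mate2_seq = substr(shared, 1, 98))
  rec2 <- map_read(db2, pair, wl, p)
  expect_equal(as.character(rec2$status), "ambiguous_gene")

  # CB at distance >= 2 from every whitelist member -> cb_unmatched
  bad_cb <- sim$cb_set[1]
  for (pos in c(1, 5, 9)) substr(bad_cb, pos, pos) <-
      setdiff(c("A", "C", "G", "T"), substr(bad_cb, pos, pos))[1]
  pair3 <- tibble::tibble(mate1_seq = paste0(bad_cb, strrep("A", 10)),
                          mate2_seq = sim$pairs$mate2_seq[1])
  expect_equal(as.character(map_read(db, pair3, wl, p)$status), "cb_unmatched")

  # malformed beats everything else
  pair4 <- tibble::tibble(mate1_seq = "ACGT", mate2_seq = "ACGT")
  expect_equal(as.character(map_read(db, pair4, wl, p)$status), "malformed")
})

test_that("mapping output is independent of read order", {
  set.seed(56)
  p <- sketch_params()
  cfg <- sim_config(n_genes = 3, n_cells = 4, mean_molecules = 2,
                    cdna_error_rate = 0.01, start_mode = "uniform")
  ref <- simulate_reference(cfg, seed = 6)
  db <- build_database(ref$transcripts[, c("id", "sequence")],
                       ref$taxonomy, p)
  sim <- simulate_experiment(ref, cfg, seed = 6)
  wl <- tibble::tibble(cb = sim$cb_set, n = 1L)
  fwd <- map_reads(db, sim$pairs, wl, p)
  perm <- sample(nrow(sim$pairs))
  rev <- map_reads(db, sim$pairs[perm, ], wl, p)
  rev_back <- dplyr::arrange(dplyr::mutate(rev, read = perm[read]), read)
  expect_equal(dplyr::select(rev_back, -read), dplyr::select(fwd, -read))
})
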