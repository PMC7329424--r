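test_that("mate-1 splitting follows the fixed CB+UMI layout", {
  p <- sketch_params()
  s26 <- random_seq(26)
  s28 <- paste0(s26, "GG")
  out <- split_read1(c(s26, random_seq(25), s28), p)
  expect_equal(out$cb[1], substr(s26, 1, 16))
  expect_equal(out$umi[1], substr(s26, 17, 26))
  expect_true(out$malformed[2])
  expect_equal(out$cb[3], substr(s26, 1, 16)) # trailing bases ignored
  expect_equal(out$umi[3], substr(s26, 17, 26))
})

test_that("barcode counting is exact, order-free, and merge-associative", {
  set.seed(41)
  p <- sketch_params()
  cbs <- c("X", "X", "Y") |>
    vapply(function(x) strrep(x, 16), character(1)) |> unname()
  pairs <- tibble::tibble(mate1_seq = paste0(cbs, strrep("A", 10)),
                          mate2_seq = "ACGT")
  counts <- count_barcodes(pairs, p)
  expect_equal(sort(counts$n, decreasing = TRUE), c(2, 1))
  expect_equal(sum(counts$n), 3)

  expect_equal(nrow(count_barcodes(pairs[0, ], p)), 0)

  perm <- pairs[sample(nrow(pairs)), ]
  expect_equal(dplyr::arrange(count_barcodes(perm, p), cb),
               dplyr::arrange(counts, cb))

  # batch counting then merging equals single-pass counting, any split
  big <- tibble::tibble(
    mate1_seq = paste0(vapply(sample(LETTERS[1:6], 60, TRUE),
                              function(x) strrep(x, 16), character(1)),
                       strrep("A", 10)),
    mate2_seq = "ACGT"
  )
  whole <- merge_barcode_counts(list(count_barcodes(big, p)))
  for (nb in c(2, 3, 7)) {
    splits <- split(seq_len(60), sort(rep_len(seq_len(nb), 60)))
    merged <- merge_barcode_counts(lapply(splits, function(i)
      count_barcodes(big[i, ], p)))
    expect_equal(merged, whole)
  }
})

test_that("whitelist admission follows the strict inclusive prefix-sum rule", {
  counts <- tibble::tibble(cb = c("A", "B", "C", "D"), n = c(50, 30, 15, 5))
  expect_equal(build_whitelist(counts, 0.9)$cb, c("A", "B"))

  single <- tibble::tibble(cb = "Z", n = 10)
  expect_equal(nrow(build_whitelist(single, 0.5)), 0)
  expect_equal(nrow(build_whitelist(single, 1)), 0) # last CB always excluded

  two <- tibble::tibble(cb = c("X", "Y"), n = c(99, 1))
  expect_equal(build_whitelist(two, 0.995)$cb, "X")

  expect_equal(nrow(build_whitelist(counts[0, ], 0.9)), 0)
})

test_that("raising the whitelist fraction never evicts a member", {
  set.seed(42)
  for (rep in 1:20) {
    counts <- tibble::tibble(
      cb = replicate(15, random_seq(8)),
      n = sample(1:200, 15, replace = TRUE)
    )
    fr <- sort(runif(2, 0.05, 1))
    expect_true(all(build_whitelist(counts, fr[1])$cb %in%
                      build_whitelist(counts, fr[2])$cb))
  }
})

test_that("barcode correction rescues unique distance-1 neighbours only", {
  set.seed(43)
  members <- c("AAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCC", "GGGGTTTTGGGGTTTT")
  wl <- build_whitelist(
    tibble::tibble(cb = c(members, "TATATATATATATATA", "TTTTCCCCTTTTCCCC"),
                   n = c(50, 30, 20, 100, 1)), 0.999
  )
  expect_setequal(wl$cb, c(members, "TATATATATATATATA"))

  expect_equal(correct_barcode(members[1], wl), members[1]) # identity

  # every single substitution of a member corrects back to it
  for (m in members) {
    for (pos in seq_len(16)) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(m, pos, pos))) {
        mut <- m
        substr(mut, pos, pos) <- b
        got <- correct_barcode(mut, wl)
        expect_false(is.na(got))
        expect_lte(adist(got, mut)[1, 1], 1)
        expect_true(got %in% wl$cb)
      }
    }
  }

  # distance 2 from everything -> unmatched
  far <- "AAAAAAAACCCCCCCC"
  expect_true(is.na(correct_barcode(far, wl)))

  # a one-base-short barcode is still distance 1 under Levenshtein
  short <- strrep("A", 15)
  expect_equal(correct_barcode(short, wl, method = "levenshtein"), members[1])

  # distance-1 tie between equal-count members -> discard
  wl_tie <- build_whitelist(
    tibble::tibble(cb = c("AAAA", "AATA", "GGGG", "CCCC"),
                   n = c(5, 5, 90, 1)), 0.999
  )
  expect_true(is.na(correct_barcode("AACA", wl_tie))) # dist 1 to both As
  # unequal counts break the tie toward the more frequent member
  wl_freq <- build_whitelist(
    tibble::tibble(cb = c("AAAA", "AATA", "GGGG", "CCCC"),
                   n = c(8, 5, 90, 1)), 0.999
  )
  expect_equal(correct_barcode("AACA", wl_freq), "AAAA")
})

test_that("whitelist TSV export/import round-trips", {
  wl <- build_whitelist(tibble::tibble(cb = c("ACGT", "GGGG"), n = c(9, 5)), 0.99)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_whitelist(wl, path)
  back <- read_whitelist(path)
  expect_equal(back$cb, wl$cb)
  expect_equal(back$n, wl$n)
})
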