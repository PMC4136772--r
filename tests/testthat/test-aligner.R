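test_that("the read index enumerates every k-mer position in ascending order", {
  idx <- build_read_index("ACAC", k = 2)
  expect_equal(idx$table, list(AC = c(0L, 2L), CA = 1L))
  expect_equal(build_read_index("AAAA", k = 1)$table, list(A = 0:3))
  expect_equal(build_read_index("ACGT", k = 4)$table, list(ACGT = 0L))
  set.seed(201)
  for (rep in 1:10) {
    r <- rand_dna(sample(5:60, 1))
    k <- sample(1:4, 1)
    idx <- build_read_index(r, k)
    expect_equal(sum(lengths(idx$table)), nchar(r) - k + 1)
    expect_true(all(vapply(idx$table, function(p) all(diff(p) > 0), TRUE)))
  }
  expect_error(build_read_index("AC", 3), "shorter than k")
})

test_that("nearest_occurrence matches a linear scan and breaks ties low", {
  expect_equal(nearest_occurrence(c(1, 5, 9), 6), 5)
  expect_equal(nearest_occurrence(c(1, 5, 9), 7), 5) # tie -> smaller
  expect_equal(nearest_occurrence(integer(), 3), NA_integer_)
  set.seed(202)
  for (rep in 1:50) {
    pos <- sort(sample(0:100, sample(1:12, 1)))
    q <- sample(-5:105, 1)
    linear <- pos[which.min(abs(pos - q))]
    expect_equal(nearest_occurrence(pos, q), linear)
  }
})

test_that("shared k-mer window counts agree with a naive per-window recount", {
  sk <- shared_kmer_counts("ACG", "ACGT", k = 2)
  expect_equal(sk$presence, c(TRUE, TRUE, FALSE))
  expect_equal(sk$counts, c(2L, 1L))
  expect_equal(sk$max_count, 2L)
  # disjoint alphabets share nothing
  expect_equal(shared_kmer_counts("AAAA", "CCCCCCCC", k = 2)$counts,
               rep(0L, 5))
  set.seed(203)
  for (rep in 1:30) {
    read <- rand_dna(sample(5:20, 1))
    ref <- rand_dna(nchar(read) + sample(0:40, 1))
    k <- sample(1:3, 1)
    sk <- shared_kmer_counts(read, ref, k)
    rk <- kmers_of(read, k)
    naive <- vapply(seq_len(nchar(ref) - nchar(read) + 1L), function(i) {
      win_kmers <- kmers_of(substr(ref, i, i + nchar(read) - 1L), k)
      sum(win_kmers %in% rk)
    }, integer(1))
    expect_equal(sk$counts, naive)
    expect_equal(sk$max_count, max(naive))
  }
})

test_that("delta_at_window equals the direct partial sum and aborts soundly", {
  set.seed(204)
  for (rep in 1:40) {
    read <- rand_dna(sample(6:25, 1))
    ref <- rand_dna(nchar(read) + sample(0:30, 1))
    k <- sample(1:3, 1); m <- sample(c(3, 8), 1)
    i <- sample(0:(nchar(ref) - nchar(read)), 1)
    win <- substr(ref, i + 1, i + nchar(read))
    expect_equal(delta_at_window(read, ref, i, k, m),
                 delta_one_sided(win, read, k, m))
  }
  expect_equal(delta_at_window("ACGT", "TTACGTTT", 2, 2, 3), 0)
  # abort_above = 0 returns NA as soon as any k-mer is missing
  expect_true(is.na(delta_at_window("AAAA", "CCCCCC", 0, 2, 3,
                                    abort_above = 0)))
  expect_error(delta_at_window("ACGT", "ACGT", 1, 2, 3), "out of bounds")
})

test_that("the exhaustive aligner finds the leftmost minimum-distance window", {
  p <- toy_params(mode = "exhaustive")
  r <- align_exhaustive("ACGTACGT", "TTTTACGTACGTTTT", p)
  expect_equal(r$position, 4L)
  expect_equal(r$distance, 0)
  expect_true(r$aligned)
  # no shared k-mer at all: every window costs the maximum, unaligned
  # under a tight threshold
  none <- align_exhaustive("AAAA", "CCCCCCCCCC",
                           align_params(k = 2, m = 4, threshold = 11,
                                        mode = "exhaustive"))
  expect_equal(none$distance, 3 * 4)
  expect_false(none$aligned)
  set.seed(205)
  for (rep in 1:30) {
    read <- rand_dna(sample(8:20, 1))
    ref <- rand_dna(nchar(read) + sample(5:60, 1))
    k <- sample(1:3, 1); m <- sample(c(3, 6), 1)
    res <- align_exhaustive(read, ref,
                            align_params(k = k, m = m, threshold = 1e9,
                                         mode = "exhaustive"))
    oracle <- align_brute(read, ref, k, m)
    expect_equal(res$position, oracle$position)
    expect_equal(res$distance, oracle$distance)
  }
})

test_that("the hash aligner with all shortcuts off is exactly exhaustive", {
  set.seed(206)
  for (rep in 1:30) {
    read <- rand_dna(sample(10:25, 1))
    ref <- rand_dna(nchar(read) + sample(10:80, 1))
    k <- sample(2:3, 1); m <- sample(c(4, 8), 1)
    pe <- align_params(k = k, m = m, threshold = 1e9, mode = "exhaustive")
    ph <- align_params(k = k, m = m, threshold = 1e9, mode = "hash",
                       skip_fraction = 0, use_rule2 = FALSE,
                       use_abort = FALSE)
    ex <- align_exhaustive(read, ref, pe)
    ha <- align_hash(read, ref, ph)
    expect_identical(ha$position, ex$position)
    expect_identical(ha$distance, ex$distance)
  }
})

test_that("skip rules only ever discard non-optimal work", {
  set.seed(207)
  for (rep in 1:25) {
    # reads sampled from the reference with a few mutations, so good
    # windows exist alongside junk
    ref <- rand_dna(300)
    start <- sample(1:(300 - 40), 1)
    read <- mutate_positions(substr(ref, start, start + 39),
                             sample(40, sample(0:4, 1)))
    pe <- align_params(k = 3, m = 10, threshold = 1e9, mode = "exhaustive")
    ph <- align_params(k = 3, m = 10, threshold = 1e9, skip_fraction = 1,
                       use_rule2 = TRUE, use_abort = TRUE)
    ex <- align_exhaustive(read, ref, pe)
    ha <- align_hash(read, ref, ph)
    # the approximate distance can never beat the true optimum
    expect_gte(ha$distance, ex$distance)
    sk <- shared_kmer_counts(read, ref, 3)
    if (sk$counts[ex$position + 1L] == sk$max_count) {
      expect_equal(ha$distance, ex$distance)
    }
    # rule-1 boundary: S = 1 visits no more windows than S = 0
    ph0 <- align_params(k = 3, m = 10, threshold = 1e9, skip_fraction = 0,
                        use_rule2 = FALSE, use_abort = FALSE)
    expect_lte(ha$visited, align_hash(read, ref, ph0)$visited)
  }
})

test_that("rule 2's lower bound never exceeds the true window distance", {
  set.seed(208)
  for (rep in 1:20) {
    read <- rand_dna(30)
    ref <- rand_dna(sample(60:150, 1))
    k <- 3; m <- 8
    sk <- shared_kmer_counts(read, ref, k)
    n_kmers <- nchar(read) - k + 1
    for (i in seq_along(sk$counts) - 1L) {
      bound <- (n_kmers - sk$counts[i + 1L]) * m
      expect_lte(bound, delta_at_window(read, ref, i, k, m))
    }
  }
})

test_that("early abort changes the work done, never the result", {
  set.seed(209)
  for (rep in 1:20) {
    read <- rand_dna(20)
    ref <- rand_dna(sample(50:200, 1))
    base <- list(k = 2, m = 5, threshold = 1e9, skip_fraction = 0,
                 use_rule2 = FALSE)
    on_ <- align_hash(read, ref, do.call(align_params,
                                         c(base, use_abort = TRUE)))
    off <- align_hash(read, ref, do.call(align_params,
                                         c(base, use_abort = FALSE)))
    expect_identical(on_$position, off$position)
    expect_identical(on_$distance, off$distance)
  }
})

test_that("an exact substring read aligns at distance 0 for any skip fraction", {
  set.seed(210)
  ref <- rand_dna(400)
  read <- substr(ref, 101, 180)
  for (S in c(0, 0.5, 1)) {
    res <- align_hash(read, ref, align_params(k = 3, m = 12, threshold = 1e9,
                                              skip_fraction = S))
    expect_equal(res$distance, 0)
    expect_equal(res$position, 100L)
  }
})

test_that("strand fallback aligns the reverse complement only when needed", {
  set.seed(211)
  ref <- rand_dna(500)
  fwd_read <- substr(ref, 51, 130)
  rc_read <- reverse_complement(substr(ref, 201, 280))
  p <- align_params(k = 3, m = 12, threshold = 1e9, rc_factor = 0.2)
  rf <- align_with_strands(fwd_read, ref, p)
  expect_equal(rf$strand, "+")
  expect_equal(rf$position, 50L)
  expect_equal(rf$distance, 0)
  rr <- align_with_strands(rc_read, ref, p)
  expect_equal(rr$strand, "-")
  expect_equal(rr$position, 200L)
  expect_equal(rr$distance, 0)
  # rc_factor = 1 makes the forward result acceptable whenever it beats
  # the loosest internal threshold; compare against running both strands
  for (rep in 1:10) {
    read <- rand_dna(40)
    p1 <- align_params(k = 3, m = 10, threshold = 1e9, rc_factor = 1)
    both <- align_with_strands(read, ref, p1)
    fwd <- align_hash(read, ref, p1)
    rev <- align_hash(reverse_complement(read), ref, p1)
    manual <- if (fwd$distance <= p1$rc_factor * (40 - 3 + 1) * 10 ||
                  fwd$distance <= rev$distance) fwd$distance else
      rev$distance
    expect_equal(both$distance, manual)
  }
})

test_that("determinism: identical inputs give identical results across runs", {
  set.seed(212)
  read <- rand_dna(50)
  ref <- rand_dna(300)
  p <- align_params(k = 3, m = 10, threshold = 1e9)
  a <- align_with_strands(read, ref, p)
  b <- align_with_strands(read, ref, p)
  expect_identical(a, b)
})

test_that("align_reads picks the best reference and reports a tidy table", {
  set.seed(213)
  refs <- c(g1 = rand_dna(300), g2 = rand_dna(300))
  reads <- c(r1 = substr(refs[["g2"]], 41, 100),
             r2 = substr(refs[["g1"]], 11, 70),
             junk = rand_dna(60))
  res <- align_reads(reads, refs,
                     align_params(k = 3, m = 12, threshold = 100))
  expect_equal(nrow(res), 3L)
  expect_equal(res$ref_id[res$read_id == "r1"], "g2")
  expect_equal(res$ref_id[res$read_id == "r2"], "g1")
  expect_equal(res$lrd[res$read_id %in% c("r1", "r2")], c(0, 0))
  expect_false(res$aligned[res$read_id == "junk"])
  expect_true(is.na(res$position[res$read_id == "junk"]))
})

test_that("degenerate inputs are hard errors", {
  p <- toy_params()
  expect_error(align_hash("A", "ACGTACGT", p), "shorter than k")
  expect_error(align_hash("ACGTACGTACGT", "ACGT", p), "reference shorter")
  expect_error(align_hash("ACGT", "ACGTACGT",
                          align_params(k = 2, m = 10, threshold = 10)),
               "exceed the read length")
  expect_error(align_params(skip_fraction = 1.5))
  expect_error(align_params(mode = "hash",
                            partial_sum_side = "read_to_window"),
               "window_to_read")
})

test_that("the exhaustive aligner's alternate partial-sum side is exact", {
  set.seed(214)
  for (rep in 1:15) {
    read <- rand_dna(20)
    ref <- rand_dna(80)
    p <- align_params(k = 2, m = 5, threshold = 1e9, mode = "exhaustive",
                      partial_sum_side = "read_to_window")
    res <- align_exhaustive(read, ref, p)
    dists <- vapply(seq_len(61) - 1L, function(i) {
      delta_one_sided(read, substr(ref, i + 1, i + 20), 2, 5)
    }, numeric(1))
    expect_equal(res$distance, min(dists))
    expect_equal(res$position, which.min(dists) - 1L)
  }
})
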