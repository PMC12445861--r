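test_that("identity handles exact, substituted and degenerate cases", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("acgt", "ACGT"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), class = "mycomix_invalid_input")
  expect_error(pairwise_identity("ACGT", ""), class = "mycomix_invalid_input")
})

test_that("identity convention matches exhaustive alignment enumeration", {
  set.seed(67)
  for (r in 1:20) {
    a <- random_sequence(sample(1:7, 1))
    b <- random_sequence(sample(1:7, 1))
    expect_equal(pairwise_identity(a, b), oracle_identity_enum(a, b),
                 info = paste(a, b))
  }
})

test_that("identity equals the full-matrix DP oracle up to 50 nt", {
  set.seed(71)
  for (r in 1:30) {
    a <- random_sequence(sample(5:50, 1))
    b <- random_sequence(sample(5:50, 1))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 info = paste(a, b))
  }

  # 40-mer with 2 substitutions and 1 deletion
  base <- random_sequence(40)
  v <- strsplit(base, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  v[25] <- setdiff(c("A", "C", "G", "T"), v[25])[1]
  mutated <- paste(v[-33], collapse = "")
  expect_equal(pairwise_identity(base, mutated),
               oracle_identity(base, mutated))
  expect_equal(pairwise_identity(base, mutated), 37 / 40)
})

test_that("identity is symmetric and reflexive", {
  set.seed(73)
  for (r in 1:15) {
    a <- random_sequence(sample(2:30, 1))
    b <- random_sequence(sample(2:30, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("identical sequences collapse to one cluster led by top abundance", {
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = "ACGTACGTAC",
    abundance = c(5, 50, 1)
  )
  cl <- greedy_cluster(reads)
  expect_equal(cl$centroids, "r2")
  expect_true(all(cl$membership$centroid_id == "r2"))
})

test_that("well-separated families form exactly two clusters", {
  reads <- tibble::tibble(
    read_id = c("a1", "a2", "b1", "b2"),
    sequence = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA",
                 "TTGGCCAATTGGCCAATTGG", "TTGGCCAATTGGCCAATTGC"),
    abundance = c(10, 5, 9, 4)
  )
  expect_lt(pairwise_identity(reads$sequence[1], reads$sequence[3]), 0.9)
  cl <- greedy_cluster(reads, threshold = 0.9)
  expect_equal(sort(cl$centroids), c("a1", "b1"))
})

test_that("clustering equals the independently coded greedy oracle", {
  set.seed(79)
  for (r in 1:6) {
    base1 <- random_sequence(60)
    base2 <- random_sequence(60)
    mutate_seq <- function(s, k) {
      v <- strsplit(s, "")[[1]]
      idx <- sample(length(v), k)
      for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      paste(v, collapse = "")
    }
    reads <- tibble::tibble(
      read_id = sprintf("r%02d", 1:10),
      sequence = c(
        vapply(c(0, 1, 2, 3, 5), function(k) mutate_seq(base1, k), ""),
        vapply(c(0, 1, 2, 4, 6), function(k) mutate_seq(base2, k), "")
      ),
      abundance = sample(1:100, 10)
    )
    cl <- greedy_cluster(reads, threshold = 0.95)
    oracle <- oracle_greedy(reads, threshold = 0.95)
    got <- cl$membership[order(cl$membership$read_id), ]
    want <- oracle[order(oracle$read_id), ]
    expect_equal(got$centroid_id, want$centroid_id)
  }
})

test_that("input order is irrelevant and members satisfy the threshold", {
  set.seed(83)
  reads <- gen_read_set(n_families = 3, reads_per_family = 6,
                        read_length = 80, mutation_rate = 0.02, seed = 9)
  cl <- greedy_cluster(reads, threshold = 0.95)
  perm <- reads[sample(nrow(reads)), ]
  cl_perm <- greedy_cluster(perm, threshold = 0.95)
  expect_equal(cl$centroids, cl_perm$centroids)
  expect_equal(
    cl$membership[order(cl$membership$read_id), ],
    cl_perm$membership[order(cl_perm$membership$read_id), ]
  )
  seq_of <- setNames(reads$sequence, reads$read_id)
  ok <- mapply(function(r, c) {
    pairwise_identity(seq_of[[r]], seq_of[[c]]) >= 0.95
  }, cl$membership$read_id, cl$membership$centroid_id)
  expect_true(all(ok))
})

test_that("abundance ties break lexicographically by read id", {
  reads <- tibble::tibble(
    read_id = c("zz", "aa"),
    sequence = c("AAAAAAAAAA", "CCCCCCCCCC"),
    abundance = c(3, 3)
  )
  cl <- greedy_cluster(reads)
  expect_equal(cl$centroids, c("aa", "zz"))
})
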