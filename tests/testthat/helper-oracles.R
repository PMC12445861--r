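# Independent oracles, coded separately from the package internals.

# Full-matrix dynamic program for the alignment identity convention:
# maximize matches (match 1, mismatch 0, gap 0), break ties by minimal
# alignment length, identity = matches / length. Unlike the package
# kernel this keeps the complete DP matrices in R.
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  M <- matrix(0L, n + 1, m + 1)
  L <- matrix(0L, n + 1, m + 1)
  L[1, ] <- 0:m
  L[, 1] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand_m <- c(
        M[i, j] + as.integer(x[i] == y[j]),  # diagonal
        M[i, j + 1],                         # gap in b
        M[i + 1, j]                          # gap in a
      )
      cand_l <- c(L[i, j] + 1L, L[i, j + 1] + 1L, L[i + 1, j] + 1L)
      best <- max(cand_m)
      keep <- cand_m == best
      M[i + 1, j + 1] <- best
      L[i + 1, j + 1] <- min(cand_l[keep])
    }
  }
  M[n + 1, m + 1] / L[n + 1, m + 1]
}

# Exhaustive enumeration of all global alignments for tiny sequences;
# validates the convention itself (max matches, then min columns).
oracle_identity_enum <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- c(matches = -1L, len = 0L)
  rec <- function(i, j, matches, len) {
    if (i > length(x) && j > length(y)) {
      if (matches > best[["matches"]] ||
          (matches == best[["matches"]] && len < best[["len"]])) {
        best <<- c(matches = matches, len = len)
      }
      return(invisible())
    }
    if (i <= length(x) && j <= length(y)) {
      rec(i + 1, j + 1, matches + as.integer(x[i] == y[j]), len + 1)
    }
    if (i <= length(x)) rec(i + 1, j, matches, len + 1)
    if (j <= length(y)) rec(i, j + 1, matches, len + 1)
  }
  rec(1L, 1L, 0L, 0L)
  best[["matches"]] / best[["len"]]
}

# Brute-force simulation of the abundance-ranked greedy rule, written
# independently of greedy_cluster() and using the R oracle identity.
oracle_greedy <- function(reads, threshold) {
  reads <- reads[order(-reads$abundance, reads$read_id), ]
  centroids <- list()
  membership <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    membership[i] <- NA_character_
    for (ct in centroids) {
      if (oracle_identity(reads$sequence[i], ct$seq) >= threshold) {
        membership[i] <- ct$id
        break
      }
    }
    if (is.na(membership[i])) {
      centroids[[length(centroids) + 1]] <-
        list(id = reads$read_id[i], seq = reads$sequence[i])
      membership[i] <- reads$read_id[i]
    }
  }
  data.frame(read_id = reads$read_id, centroid_id = membership)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small handmade isotope fixture: two plots, one target each, clean refs.
make_tiny_survey <- function() {
  tibble::tibble(
    sample_id = c("t1", "t2", "a1", "r1", "r2", "r3", "r4"),
    group = c("orchid", "orchid", "albino", "reference", "reference",
              "reference", "reference"),
    site_id = "s1",
    plot_id = c("A", "B", "A", "A", "A", "B", "B"),
    role = c("target", "target", "target", "reference", "reference",
             "reference", "reference"),
    tissue = "leaf",
    delta13C = c(-26.7, -30.2, -26.0, -34.0, -34.8, -34.6, -34.2),
    delta15N = c(4.1, 2.7, 1.8, -4.4, -4.6, -4.3, -4.7)
  )
}
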