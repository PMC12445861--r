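#' Pairwise sequence identity under global alignment
#'
#' Fraction of identical positions in an end-to-end global alignment of
#' two nucleotide sequences: the alignment maximizes the number of
#' matching columns (match 1, mismatch 0, linear gap 0) and, among
#' alignments with that match count, uses the fewest columns; identity is
#' matches divided by alignment length, end gaps included. Clustering
#' tools differ in this definition, so the package fixes one convention
#' and tests it; the measure is symmetric and equals 1 only for identical
#' sequences.
#'
#' @param a,b Non-empty nucleotide sequences (single strings).
#' @return A single numeric identity in (0, 1].
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b)) {
    stop_invalid("`a` and `b` must be single sequences.")
  }
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop_invalid("Sequences must be non-empty.")
  }
  aligned_identity_cpp(toupper(a), toupper(b))$identity
}

#' Abundance-ranked greedy centroid clustering
#'
#' Deterministic re-implementation of the greedy centroid rule used by
#' standard OTU pickers: reads are processed in decreasing abundance
#' (ties broken lexicographically by read id); each read joins the first
#' existing centroid it matches at `threshold` identity or better,
#' otherwise it founds a new cluster with itself as centroid. The most
#' abundant read therefore represents each OTU. Input order is
#' irrelevant: the ranking is internal.
#'
#' @param reads Data frame with columns `read_id` (unique), `sequence`
#'   (non-empty, A/C/G/T), `abundance` (positive integers, e.g. parsed
#'   from `;size=N` annotations).
#' @param threshold Identity threshold in (0, 1]; default 0.97, the
#'   conventional OTU radius.
#' @return An object of class `cluster_assignment`: a list with
#'   `centroids` (read ids in founding order), `membership` (tibble
#'   `read_id`, `centroid_id`, `identity`), and `threshold`.
#' @seealso [pairwise_identity()] for the identity definition;
#'   [gen_read_set()] to simulate test reads.
#' @export
greedy_cluster <- function(reads, threshold = 0.97) {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "sequence", "abundance") %in% names(reads))) {
    stop_invalid("`reads` needs columns `read_id`, `sequence`, `abundance`.")
  }
  if (nrow(reads) == 0) stop_invalid("`reads` must be non-empty.")
  if (anyDuplicated(reads$read_id)) stop_invalid("`read_id`s must be unique.")
  if (any(nchar(reads$sequence) == 0)) {
    stop_invalid("Sequences must be non-empty.")
  }
  if (any(!is.finite(reads$abundance)) || any(reads$abundance < 1)) {
    stop_invalid("Abundances must be >= 1.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold > 1) {
    stop_invalid("`threshold` must be in (0, 1].")
  }

  ord <- order(-reads$abundance, reads$read_id)
  ids <- reads$read_id[ord]
  seqs <- toupper(reads$sequence[ord])

  centroid_ids <- character()
  centroid_seqs <- character()
  assigned <- character(length(ids))
  identity <- numeric(length(ids))

  for (i in seq_along(ids)) {
    hit <- NA_integer_
    hit_id <- NA_real_
    for (k in seq_along(centroid_ids)) {
      idk <- aligned_identity_cpp(seqs[i], centroid_seqs[k])$identity
      if (idk >= threshold) {
        hit <- k
        hit_id <- idk
        break
      }
    }
    if (is.na(hit)) {
      centroid_ids <- c(centroid_ids, ids[i])
      centroid_seqs <- c(centroid_seqs, seqs[i])
      assigned[i] <- ids[i]
      identity[i] <- 1
    } else {
      assigned[i] <- centroid_ids[hit]
      identity[i] <- hit_id
    }
  }

  structure(
    list(
      centroids = centroid_ids,
      membership = tibble(read_id = ids, centroid_id = assigned,
                          identity = identity),
      threshold = threshold
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "Greedy clustering at %.0f %% identity: %d reads -> %d cluster(s)\n",
    x$threshold * 100, nrow(x$membership), length(x$centroids)
  ))
  sizes <- table(factor(x$membership$centroid_id, levels = x$centroids))
  for (i in seq_along(x$centroids)) {
    cat(sprintf("  %s: %d read(s)\n", x$centroids[i], sizes[i]))
  }
  invisible(x)
}

#' @describeIn greedy_cluster Membership table as a tibble.
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  x$membership
}
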