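#' Read and write isotope sample tables
#'
#' CSV dialect: comma-separated, UTF-8, header required, empty fields as
#' missing. Columns: `sample_id`, `group`, `site_id`, `plot_id`, `role`,
#' `tissue`, `delta13C`, `delta15N`.
#'
#' @param path File path.
#' @return `read_isotope_samples()` returns a validated tibble;
#'   `write_isotope_samples()` returns `path` invisibly.
#' @export
read_isotope_samples <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  samples <- readr::read_csv(
    path,
    col_types = readr::cols(
      delta13C = readr::col_double(),
      delta15N = readr::col_double(),
      .default = readr::col_character()
    ),
    na = c("", "NA")
  )
  validate_isotope_samples(samples, call_fn = path)
}

#' @rdname read_isotope_samples
#' @param samples Isotope sample data frame.
#' @export
write_isotope_samples <- function(samples, path) {
  samples <- validate_isotope_samples(samples)
  readr::write_csv(samples, path)
  invisible(path)
}

#' Read and write OTU tables
#'
#' TSV dialect: a wide counts table (`sample_id` column plus one integer
#' column per OTU), a taxonomy sidecar (`otu_id`, `genus`, `family`,
#' `guild`) and an optional sample sidecar (`sample_id`, `group`).
#'
#' @param counts_path,taxonomy_path,samples_path File paths; the sample
#'   sidecar may be `NULL` (each sample then forms its own group).
#' @return `read_otu_table()` returns an [otu_table()];
#'   `write_otu_table()` returns the paths invisibly.
#' @export
read_otu_table <- function(counts_path, taxonomy_path, samples_path = NULL) {
  for (p in c(counts_path, taxonomy_path, samples_path)) {
    if (!file.exists(p)) stop_invalid(sprintf("File not found: %s", p))
  }
  counts <- tryCatch(
    readr::read_tsv(counts_path, col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_double()
    )),
    error = function(e) {
      stop_invalid(sprintf("Malformed counts TSV %s: %s", counts_path,
                           conditionMessage(e)))
    }
  )
  prob <- readr::problems(counts)
  if (nrow(prob) > 0) {
    stop_invalid(sprintf(
      "Malformed counts TSV %s at line %d: %s.",
      counts_path, prob$row[1] + 1L, prob$expected[1]
    ))
  }
  taxonomy <- readr::read_tsv(taxonomy_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  samples <- if (!is.null(samples_path)) {
    readr::read_tsv(samples_path, col_types = readr::cols(
      .default = readr::col_character()
    ))
  } else {
    NULL
  }
  otu_table(counts, taxonomy, samples)
}

#' @rdname read_otu_table
#' @param tab An [otu_table()].
#' @export
write_otu_table <- function(tab, counts_path, taxonomy_path,
                            samples_path = NULL) {
  if (!inherits(tab, "otu_table")) stop_invalid("`tab` must be an `otu_table`.")
  wide <- tab$counts |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = "count",
                       values_fill = 0)
  readr::write_tsv(wide, counts_path)
  readr::write_tsv(tab$otu_meta, taxonomy_path)
  if (!is.null(samples_path)) readr::write_tsv(tab$sample_meta, samples_path)
  invisible(c(counts_path, taxonomy_path, samples_path))
}

#' Read and write abundance-annotated FASTA read sets
#'
#' Dereplicated amplicon FASTA with cluster-tool abundance annotations:
#' headers of the form `>read_id;size=N`. Headers without a `size=`
#' annotation get abundance 1.
#'
#' @param path FASTA file path.
#' @return `read_read_set()` returns a tibble (`read_id`, `sequence`,
#'   `abundance`); `write_read_set()` returns `path` invisibly.
#' @export
read_read_set <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop_invalid(sprintf("No FASTA records in %s", path))
  ids <- names(set)
  size <- rep(1L, length(ids))
  has_size <- grepl(";size=\\d+", ids)
  size[has_size] <- as.integer(sub(".*;size=(\\d+).*", "\\1", ids[has_size]))
  ids <- sub(";size=\\d+.*$", "", ids)
  out <- tibble(read_id = ids, sequence = as.character(set), abundance = size)
  if (any(nchar(out$sequence) == 0)) {
    stop_invalid(sprintf("Empty sequence record in %s", path))
  }
  out
}

#' @rdname read_read_set
#' @param reads Tibble with `read_id`, `sequence`, `abundance`.
#' @export
write_read_set <- function(reads, path) {
  if (!all(c("read_id", "sequence", "abundance") %in% names(reads))) {
    stop_invalid("`reads` needs columns `read_id`, `sequence`, `abundance`.")
  }
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- paste0(reads$read_id, ";size=", reads$abundance)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
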