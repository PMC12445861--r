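# End-to-end runs tying the stages together. Each pipeline writes its
# tables plus a machine-readable JSON log of the parameters used, so a
# run is reproducible from its output directory alone. Logs carry no
# timestamps: identical config + seed must give byte-identical output.

write_run_log <- function(out_dir, stage, params) {
  log <- list(
    stage = stage,
    package = "mycomix",
    version = as.character(utils::packageVersion("mycomix")),
    params = params
  )
  path <- file.path(out_dir, sprintf("%s_log.json", stage))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_config(sprintf("Cannot create output directory: %s", out_dir))
  }
  out_dir
}

#' Simulate a study and write its files
#'
#' Generates a synthetic isotope survey, OTU table and read set under one
#' configuration and writes them in the same dialects the analysis
#' pipelines read, plus the generating truth as JSON for recovery checks.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synthetic_config()].
#' @return Invisibly, a named list of the files written.
#' @export
pipeline_simulate <- function(out_dir, config = synthetic_config()) {
  ensure_out_dir(out_dir)
  iso <- gen_isotope_dataset(config)
  otu <- gen_otu_table(config)
  reads <- gen_read_set(seed = config$seed)

  files <- list(
    isotope = file.path(out_dir, "isotope_samples.csv"),
    otu_counts = file.path(out_dir, "otu_counts.tsv"),
    otu_taxonomy = file.path(out_dir, "otu_taxonomy.tsv"),
    otu_samples = file.path(out_dir, "otu_samples.tsv"),
    reads = file.path(out_dir, "reads.fasta"),
    truth = file.path(out_dir, "truth.json")
  )
  write_isotope_samples(iso$samples, files$isotope)
  write_otu_table(otu, files$otu_counts, files$otu_taxonomy,
                  files$otu_samples)
  write_read_set(reads[, c("read_id", "sequence", "abundance")], files$reads)
  jsonlite::write_json(
    list(
      groups = iso$truth$groups,
      plot_effects = iso$truth$plot_effects,
      eps_fmh_true = iso$truth$eps_fmh_true,
      read_families = reads[, c("read_id", "family")]
    ),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_run_log(out_dir, "simulate", list(seed = config$seed))
  invisible(files)
}

#' Run the isotope analysis end to end
#'
#' Chains the full mixing-model analysis: plot reference means ->
#' enrichment factors -> full-mycoheterotroph baseline -> two-source
#' mixing model -> linear mixed models (delta13C and delta15N) with
#' Tukey-Kramer contrasts. Writes enrichment records, mixing results,
#' contrast tables and a per-group summary table (delta13C, delta15N and
#' %Cdf as mean +/- SD, per mil and percent to 1 decimal).
#'
#' @param samples Isotope sample data frame or path to a CSV readable by
#'   [read_isotope_samples()].
#' @param baseline_group Group label of the full-mycoheterotroph
#'   baseline individuals.
#' @param clamp Clamp individual %Cdf estimates to \[0, 100\].
#' @param out_dir Optional output directory; when `NULL` nothing is
#'   written.
#' @return A list with `plot_refs`, `enrichment`, `baseline`, `mixing`,
#'   `summary`, and per-response `lmm` and `contrasts`.
#' @export
pipeline_isotope <- function(samples, baseline_group, clamp = FALSE,
                             out_dir = NULL) {
  if (is.character(samples) && length(samples) == 1L) {
    samples <- read_isotope_samples(samples)
  }
  samples <- validate_isotope_samples(samples)
  plot_refs <- plot_reference_means(samples)
  enrichment <- enrichment_factors(samples, plot_refs)
  baseline <- fmh_baseline(enrichment, baseline_group)
  mixing <- mixing_model(enrichment, baseline, clamp = clamp)

  fits <- list(
    delta13C = fit_group_lmm(samples, "delta13C"),
    delta15N = fit_group_lmm(samples, "delta15N")
  )
  contrasts <- purrr::map(fits, tukey_kramer)

  summary_tbl <- group_summary(samples) |>
    left_join(
      select(mixing, "group", "pcdf_mean", "pcdf_sd"),
      by = "group"
    ) |>
    mutate(across(
      c("mean_delta13C", "sd_delta13C", "mean_delta15N", "sd_delta15N",
        "pcdf_mean", "pcdf_sd"),
      ~ round_half_up(.x, 1)
    ))

  if (!is.null(out_dir)) {
    ensure_out_dir(out_dir)
    readr::write_csv(enrichment, file.path(out_dir, "enrichment.csv"))
    readr::write_csv(as_tibble(mixing), file.path(out_dir, "mixing.csv"))
    readr::write_csv(summary_tbl, file.path(out_dir, "group_summary.csv"))
    for (resp in names(contrasts)) {
      readr::write_csv(
        contrasts[[resp]],
        file.path(out_dir, sprintf("contrasts_%s.csv", resp))
      )
    }
    writeLines(
      c(
        utils::capture.output(print(fits$delta13C)),
        "",
        utils::capture.output(print(fits$delta15N))
      ),
      file.path(out_dir, "lmm_summary.txt")
    )
    jsonlite::write_json(
      list(
        baseline = as.list(as_tibble(baseline)[1, ]),
        mixing = as_tibble(mixing)
      ),
      file.path(out_dir, "isotope_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_run_log(out_dir, "isotope", list(
      baseline_group = baseline_group, clamp = clamp,
      n_samples = nrow(samples)
    ))
  }

  list(
    plot_refs = plot_refs, enrichment = enrichment, baseline = baseline,
    mixing = mixing, summary = summary_tbl, lmm = fits,
    contrasts = contrasts
  )
}

#' Run the OTU community summary end to end
#'
#' Chains [filter_otu_table()] -> [relative_abundance()] ->
#' [dominance_summary()] and optionally writes the filtered table, a
#' tidy abundance CSV and a per-group dominance report.
#'
#' @param tab An [otu_table()] or a list/vector of the three TSV paths
#'   (`counts`, `taxonomy`, `samples`) for [read_otu_table()].
#' @param drop_singletons,guild_whitelist Passed to [filter_otu_table()].
#' @param out_dir Optional output directory.
#' @return A list with `filtered` (OTU table), `removed` (tibble),
#'   `abundance` (per group), `abundance_sample` (per sample),
#'   `dominance`.
#' @export
pipeline_otu <- function(tab,
                         drop_singletons = TRUE,
                         guild_whitelist = c("orchid_mycorrhizal",
                                             "ectomycorrhizal",
                                             "saprotrophic"),
                         out_dir = NULL) {
  if (!inherits(tab, "otu_table")) {
    paths <- unlist(tab, use.names = FALSE)
    if (!is.character(paths) || length(paths) < 2) {
      stop_invalid("`tab` must be an `otu_table` or counts/taxonomy paths.")
    }
    tab <- read_otu_table(paths[1], paths[2],
                          if (length(paths) >= 3) paths[3] else NULL)
  }
  filtered <- filter_otu_table(tab, drop_singletons = drop_singletons,
                               guild_whitelist = guild_whitelist)
  abundance <- relative_abundance(filtered, by = "group")
  abundance_sample <- relative_abundance(filtered, by = "sample")
  dominance <- dominance_summary(filtered)

  if (!is.null(out_dir)) {
    ensure_out_dir(out_dir)
    write_otu_table(
      filtered,
      file.path(out_dir, "filtered_counts.tsv"),
      file.path(out_dir, "filtered_taxonomy.tsv"),
      file.path(out_dir, "filtered_samples.tsv")
    )
    readr::write_csv(abundance, file.path(out_dir, "relative_abundance.csv"))
    readr::write_csv(abundance_sample,
                     file.path(out_dir, "relative_abundance_by_sample.csv"))
    readr::write_csv(dominance, file.path(out_dir, "dominance.csv"))
    report <- dominance |>
      group_by(.data$group) |>
      summarise(
        text = sprintf(
          "%s: %d OTUs; top OTU %s at %.2f %%; top-3 cumulative %.2f %%",
          .data$group[1], dplyr::n(), .data$otu_id[1], .data$percent[1],
          .data$cum_percent[min(3, dplyr::n())]
        ),
        .groups = "drop"
      )
    writeLines(report$text, file.path(out_dir, "dominance_report.txt"))
    write_run_log(out_dir, "otu", list(
      drop_singletons = drop_singletons,
      guild_whitelist = guild_whitelist
    ))
  }

  list(
    filtered = filtered, removed = attr(filtered, "removed"),
    abundance = abundance, abundance_sample = abundance_sample,
    dominance = dominance
  )
}
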