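#' Convert isotope ratios to delta notation
#'
#' Expresses a measured isotope ratio (13C/12C or 15N/14N) as a per-mil
#' deviation from an international standard (VPDB for carbon, atmospheric
#' N2 for nitrogen): delta = (R_sample / R_standard - 1) x 1000.
#'
#' @param r_sample Measured isotope ratio(s); must be positive.
#' @param r_standard Standard isotope ratio; must be positive.
#' @return Numeric vector of delta values in per mil.
#' @examples
#' delta_value(0.0112484, 0.0112372)  # ~1 per mil above VPDB
#' @export
delta_value <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop_invalid("Isotope ratios must be numeric.")
  }
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard))) {
    stop_invalid("Isotope ratios must be finite.")
  }
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    stop_invalid("Isotope ratios must be strictly positive.")
  }
  (r_sample / r_standard - 1) * 1000
}

isotope_required_cols <- c(
  "sample_id", "group", "plot_id", "role", "delta13C", "delta15N"
)

# Validate an isotope sample table. `site_id` and `tissue` are optional
# descriptive columns; the required columns carry the analysis.
validate_isotope_samples <- function(samples, call_fn = "isotope samples") {
  if (!is.data.frame(samples)) {
    stop_invalid(sprintf("%s must be a data frame.", call_fn))
  }
  missing_cols <- setdiff(isotope_required_cols, names(samples))
  if (length(missing_cols) > 0) {
    stop_invalid(sprintf(
      "%s is missing required column(s): %s.",
      call_fn, paste(missing_cols, collapse = ", ")
    ))
  }
  if (!all(samples$role %in% c("target", "reference"))) {
    stop_invalid("`role` must be 'target' or 'reference' for every sample.")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_invalid("`sample_id` values must be unique.")
  }
  bad_delta <- !is.finite(samples$delta13C) | !is.finite(samples$delta15N)
  if (any(bad_delta)) {
    stop_invalid(sprintf(
      "Non-finite delta values for sample(s): %s.",
      paste(samples$sample_id[bad_delta], collapse = ", ")
    ))
  }
  ref_no_plot <- samples$role == "reference" &
    (is.na(samples$plot_id) | samples$plot_id == "")
  if (any(ref_no_plot)) {
    stop_invalid("Reference samples must carry a `plot_id`.")
  }
  as_tibble(samples)
}

#' Per-plot means of autotrophic reference plants
#'
#' Each 2 x 2-m plot contributes the arithmetic mean delta13C and delta15N
#' of its autotrophic reference plants. These plot means are the baseline
#' against which co-occurring target plants are normalized, which removes
#' microsite effects (canopy openness, soil) shared by plants in a plot.
#' Field designs aim for at least three reference plants per plot; plots
#' with fewer produce a warning, plots with none and a target an error.
#'
#' @param samples Data frame of isotope samples with columns `sample_id`,
#'   `group`, `plot_id`, `role` (`"target"`/`"reference"`), `delta13C`,
#'   `delta15N` (per mil); `site_id` and `tissue` are carried if present.
#' @return A tibble with one row per plot: `plot_id`, `mean_delta13C`,
#'   `mean_delta15N`, `n_refs`.
#' @seealso [enrichment_factors()] which consumes these means.
#' @export
plot_reference_means <- function(samples) {
  samples <- validate_isotope_samples(samples)
  refs <- dplyr::filter(samples, .data$role == "reference")
  target_plots <- unique(samples$plot_id[samples$role == "target"])
  orphan <- setdiff(target_plots, unique(refs$plot_id))
  if (length(orphan) > 0) {
    stop_missing_reference(sprintf(
      "Plot(s) with target samples but no reference plants: %s.",
      paste(orphan, collapse = ", ")
    ))
  }
  out <- refs |>
    group_by(.data$plot_id) |>
    summarise(
      mean_delta13C = mean(.data$delta13C),
      mean_delta15N = mean(.data$delta15N),
      n_refs = dplyr::n(),
      .groups = "drop"
    )
  thin <- out$plot_id[out$n_refs < 3]
  if (length(thin) > 0) {
    warn(sprintf(
      "Plot(s) with fewer than 3 reference plants: %s. Plot means will be noisy.",
      paste(thin, collapse = ", ")
    ))
  }
  out
}

#' Plot-normalized enrichment factors
#'
#' Computes, for every sample, the enrichment factor
#' epsilon = delta_S - delta_REF, where delta_REF is the mean delta of the
#' reference plants in the sample's own plot. Reference samples receive
#' records too: their within-plot mean enrichment is exactly zero by
#' construction, a useful invariant check.
#'
#' @inheritParams plot_reference_means
#' @param plot_refs Optional precomputed tibble from
#'   [plot_reference_means()]; computed from `samples` when `NULL`.
#' @return A tibble with one row per sample: `sample_id`, `group`,
#'   `plot_id`, `role`, `eps13C`, `eps15N` (per mil), plus `site_id` and
#'   `tissue` when present in the input.
#' @examples
#' samples <- tibble::tibble(
#'   sample_id = c("t1", "r1", "r2"),
#'   group = c("orchid_target", "reference", "reference"),
#'   plot_id = "A", role = c("target", "reference", "reference"),
#'   delta13C = c(-26.7, -34.0, -34.8), delta15N = c(4.1, -4.5, -4.5)
#' )
#' enrichment_factors(samples)
#' @export
enrichment_factors <- function(samples, plot_refs = NULL) {
  samples <- validate_isotope_samples(samples)
  if (is.null(plot_refs)) {
    plot_refs <- plot_reference_means(samples)
  }
  orphan <- setdiff(unique(samples$plot_id), plot_refs$plot_id)
  if (length(orphan) > 0) {
    stop_missing_reference(sprintf(
      "No reference mean available for plot(s): %s.",
      paste(orphan, collapse = ", ")
    ))
  }
  keep <- intersect(
    c("sample_id", "group", "site_id", "plot_id", "role", "tissue"),
    names(samples)
  )
  samples |>
    left_join(plot_refs, by = "plot_id") |>
    mutate(
      eps13C = .data$delta13C - .data$mean_delta13C,
      eps15N = .data$delta15N - .data$mean_delta15N
    ) |>
    select(all_of(keep), "eps13C", "eps15N")
}

#' Group-wise mean and standard deviation summaries
#'
#' Summarises numeric columns by group as mean and sample standard
#' deviation (n - 1 denominator), the form in which isotope surveys
#' tabulate delta13C / delta15N per taxon or phenotype. Groups with a
#' single individual report the mean with `NA` SD.
#'
#' @param data Data frame of samples or enrichment records.
#' @param cols Character vector of numeric columns to summarise. Defaults
#'   to whichever of `delta13C`, `delta15N`, `eps13C`, `eps15N` are present.
#' @param by Grouping column name (default `"group"`).
#' @return A tibble with `group`, `n`, and `mean_*` / `sd_*` columns.
#' @export
group_summary <- function(data, cols = NULL, by = "group") {
  if (!is.data.frame(data)) stop_invalid("`data` must be a data frame.")
  if (!by %in% names(data)) {
    stop_invalid(sprintf("Grouping column `%s` not found.", by))
  }
  if (is.null(cols)) {
    cols <- intersect(c("delta13C", "delta15N", "eps13C", "eps15N"), names(data))
  }
  if (length(cols) == 0) stop_invalid("No summary columns found.")
  empty_groups <- is.na(data[[by]]) | data[[by]] == ""
  if (any(empty_groups)) {
    warn(sprintf("Dropping %d sample(s) with empty group label.", sum(empty_groups)))
    data <- data[!empty_groups, , drop = FALSE]
  }
  data |>
    group_by(.data[[by]]) |>
    summarise(
      n = dplyr::n(),
      across(
        all_of(cols),
        list(
          mean = ~ mean(.x),
          sd = ~ if (length(.x) > 1) sd(.x) else NA_real_
        ),
        .names = "{.fn}_{.col}"
      ),
      .groups = "drop"
    )
}
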