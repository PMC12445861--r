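#' Full-mycoheterotroph 13C enrichment baseline
#'
#' The two-source mixing model needs the 13C enrichment a plant would show
#' if it obtained 100 % of its carbon from fungi. In the field this anchor
#' comes from chlorophyll-free (albino) individuals or achlorophyllous
#' protocorms sampled alongside the targets; each is first normalized
#' against its own plot's reference plants, then the group is pooled.
#'
#' @param records Enrichment records from [enrichment_factors()].
#' @param baseline_group Group label of the full-mycoheterotroph reference
#'   individuals (e.g. the albino phenotype).
#' @return A one-row tibble of class `fmh_baseline`: `baseline_group`,
#'   `eps_fmh` (mean eps13C, per mil), `eps_sd` (`NA` when n = 1), `n`.
#' @seealso [mixing_model()]
#' @export
fmh_baseline <- function(records, baseline_group) {
  if (!is.data.frame(records) || !all(c("group", "eps13C") %in% names(records))) {
    stop_invalid("`records` must contain `group` and `eps13C` columns.")
  }
  if (!is.character(baseline_group) || length(baseline_group) != 1L ||
      is.na(baseline_group) || baseline_group == "") {
    stop_config("`baseline_group` must be a single non-empty group label.")
  }
  eps <- records$eps13C[records$group == baseline_group]
  if (length(eps) == 0) {
    stop_config(sprintf(
      "Baseline group '%s' has no enrichment records.", baseline_group
    ))
  }
  out <- tibble(
    baseline_group = baseline_group,
    eps_fmh = mean(eps),
    eps_sd = if (length(eps) > 1) sd(eps) else NA_real_,
    n = length(eps)
  )
  class(out) <- c("fmh_baseline", class(out))
  out
}

#' Two-source linear mixing model for fungal-derived carbon
#'
#' Converts 13C enrichment into the percentage of plant carbon derived
#' from fungi: %Cdf = eps13C / eps13C_FMH x 100, where eps13C_FMH is the
#' enrichment of the full-mycoheterotroph baseline. The model is a linear
#' interpolation between two end members: co-occurring autotrophic plants
#' (0 % fungal carbon, eps = 0 by construction) and the baseline group
#' (100 %). Individual estimates outside \[0, 100\] are biologically
#' informative sampling noise and are retained by default; `clamp = TRUE`
#' truncates them and flags the groups affected.
#'
#' @param records Enrichment records from [enrichment_factors()]. Only
#'   rows with `role == "target"` enter the model when a `role` column is
#'   present; reference plants define the autotrophic end member and get
#'   no %Cdf of their own.
#' @param eps_fmh Baseline enrichment: either the tibble returned by
#'   [fmh_baseline()] or a positive number in per mil.
#' @param clamp If `TRUE`, truncate individual estimates to \[0, 100\].
#' @return A tibble of class `mixing_result`, one row per group:
#'   `group`, `pcdf_mean`, `pcdf_sd` (`NA` when n = 1), `n`,
#'   `eps_fmh_baseline`, `clamped`. Per-individual estimates are attached
#'   as the `"individuals"` attribute and returned by [tidy()].
#' @export
mixing_model <- function(records, eps_fmh, clamp = FALSE) {
  if (!is.data.frame(records) || !all(c("group", "eps13C") %in% names(records))) {
    stop_invalid("`records` must contain `group` and `eps13C` columns.")
  }
  baseline_label <- NA_character_
  if (inherits(eps_fmh, "fmh_baseline") ||
      (is.data.frame(eps_fmh) && "eps_fmh" %in% names(eps_fmh))) {
    baseline_label <- eps_fmh$baseline_group[[1]]
    eps_fmh <- eps_fmh$eps_fmh[[1]]
  }
  if (!is.numeric(eps_fmh) || length(eps_fmh) != 1L || !is.finite(eps_fmh) ||
      eps_fmh <= 0) {
    abort(
      "`eps_fmh` must be a single positive enrichment (per mil).",
      class = "mycomix_invalid_baseline"
    )
  }
  targets <- if ("role" %in% names(records)) {
    dplyr::filter(records, .data$role == "target")
  } else {
    records
  }
  if (nrow(targets) == 0) stop_invalid("No target records to estimate.")

  individuals <- targets |>
    mutate(pcdf_raw = .data$eps13C / eps_fmh * 100) |>
    mutate(
      out_of_range = .data$pcdf_raw < 0 | .data$pcdf_raw > 100,
      pcdf = if (clamp) pmin(pmax(.data$pcdf_raw, 0), 100) else .data$pcdf_raw
    ) |>
    select(any_of(c("sample_id", "group", "plot_id")), "pcdf", "pcdf_raw",
           "out_of_range")

  out <- individuals |>
    group_by(.data$group) |>
    summarise(
      pcdf_mean = mean(.data$pcdf),
      pcdf_sd = if (dplyr::n() > 1) sd(.data$pcdf) else NA_real_,
      n = dplyr::n(),
      clamped = clamp && any(.data$out_of_range),
      .groups = "drop"
    ) |>
    mutate(eps_fmh_baseline = eps_fmh, .before = "clamped")

  attr(out, "individuals") <- individuals
  attr(out, "baseline_group") <- baseline_label
  class(out) <- c("mixing_result", class(out))
  out
}

#' @describeIn mixing_model Per-individual %Cdf estimates underlying the
#'   group summary.
#' @param x A `mixing_result` object.
#' @param ... Unused.
#' @method tidy mixing_result
#' @export
tidy.mixing_result <- function(x, ...) {
  as_tibble(attr(x, "individuals"))
}

#' @describeIn mixing_model One-row overview: baseline used, number of
#'   groups and individuals, and how many individual estimates fall
#'   outside \[0, 100\].
#' @method glance mixing_result
#' @export
glance.mixing_result <- function(x, ...) {
  ind <- attr(x, "individuals")
  tibble(
    eps_fmh_baseline = x$eps_fmh_baseline[[1]],
    baseline_group = attr(x, "baseline_group") %||% NA_character_,
    n_groups = nrow(x),
    n_individuals = nrow(ind),
    n_out_of_range = sum(ind$out_of_range)
  )
}
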