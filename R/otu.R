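otu_guilds <- c("orchid_mycorrhizal", "ectomycorrhizal", "saprotrophic", "other")

#' Construct an OTU table
#'
#' Bundles an amplicon OTU count matrix with per-OTU taxonomy/guild
#' annotations and per-sample group labels, the three pieces every
#' downstream summary needs. Counts may be supplied wide (one `sample_id`
#' column plus one numeric column per OTU, the usual tool output) or long
#' (`sample_id`, `otu_id`, `count`); they are stored long.
#'
#' @param counts Wide or long count data frame (see Details); counts must
#'   be non-negative integers.
#' @param otu_meta Data frame with `otu_id`, `genus`, `guild` (one of
#'   `"orchid_mycorrhizal"`, `"ectomycorrhizal"`, `"saprotrophic"`,
#'   `"other"`); `family` optional. Every OTU in `counts` needs a row.
#' @param sample_meta Optional data frame with `sample_id`, `group`; when
#'   omitted each sample forms its own group.
#' @return An object of class `otu_table`: a list with tibbles `counts`
#'   (long), `otu_meta`, `sample_meta`.
#' @export
otu_table <- function(counts, otu_meta, sample_meta = NULL) {
  if (!is.data.frame(counts)) stop_invalid("`counts` must be a data frame.")
  if (all(c("sample_id", "otu_id", "count") %in% names(counts))) {
    long <- as_tibble(counts[, c("sample_id", "otu_id", "count")])
  } else {
    if (!"sample_id" %in% names(counts)) {
      stop_invalid("Wide `counts` needs a `sample_id` column.")
    }
    otu_cols <- setdiff(names(counts), c("sample_id", "group"))
    if (length(otu_cols) == 0) stop_invalid("No OTU count columns found.")
    long <- counts |>
      select("sample_id", all_of(otu_cols)) |>
      tidyr::pivot_longer(all_of(otu_cols), names_to = "otu_id",
                          values_to = "count")
    if (is.null(sample_meta) && "group" %in% names(counts)) {
      sample_meta <- counts[, c("sample_id", "group")]
    }
  }
  long$count <- as.numeric(long$count)
  if (any(!is.finite(long$count)) || any(long$count < 0) ||
      any(long$count != floor(long$count))) {
    stop_invalid("Counts must be non-negative integers.")
  }
  if (anyDuplicated(long[, c("sample_id", "otu_id")])) {
    stop_invalid("Duplicate (sample_id, otu_id) count entries.")
  }

  if (!is.data.frame(otu_meta) ||
      !all(c("otu_id", "genus", "guild") %in% names(otu_meta))) {
    stop_invalid("`otu_meta` must contain `otu_id`, `genus`, `guild`.")
  }
  otu_meta <- as_tibble(otu_meta)
  if (anyDuplicated(otu_meta$otu_id)) stop_invalid("OTU ids must be unique.")
  if (!all(otu_meta$guild %in% otu_guilds)) {
    stop_invalid(sprintf(
      "Unknown guild label(s): %s. Use one of: %s.",
      paste(setdiff(otu_meta$guild, otu_guilds), collapse = ", "),
      paste(otu_guilds, collapse = ", ")
    ))
  }
  unknown <- setdiff(unique(long$otu_id), otu_meta$otu_id)
  if (length(unknown) > 0) {
    stop_invalid(sprintf(
      "OTU(s) in counts without metadata: %s.", paste(unknown, collapse = ", ")
    ))
  }

  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = unique(long$sample_id),
                          group = unique(long$sample_id))
  }
  sample_meta <- as_tibble(sample_meta)
  if (!all(c("sample_id", "group") %in% names(sample_meta))) {
    stop_invalid("`sample_meta` must contain `sample_id` and `group`.")
  }
  missing_samples <- setdiff(unique(long$sample_id), sample_meta$sample_id)
  if (length(missing_samples) > 0) {
    stop_invalid(sprintf(
      "Sample(s) without group metadata: %s.",
      paste(missing_samples, collapse = ", ")
    ))
  }

  structure(
    list(counts = long, otu_meta = otu_meta, sample_meta = sample_meta),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "OTU table: %d samples x %d OTUs, %s reads\n",
    length(unique(x$counts$sample_id)), nrow(x$otu_meta),
    format(sum(x$counts$count), big.mark = " ")
  ))
  tab <- table(x$otu_meta$guild)
  cat("  Guilds:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

otu_totals <- function(tab) {
  tab$counts |>
    group_by(.data$otu_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
}

#' Filter an OTU table as done for orchid mycobiont surveys
#'
#' Applies the two standard post-clustering exclusions: OTUs whose total
#' read count across all samples is exactly one (likely sequencing
#' artefacts), and OTUs whose trophic guild is not on the whitelist of
#' plausible orchid mycorrhizal partners. The whitelist is a user
#' decision — which genera count as "known orchid mycorrhizal partners"
#' depends on the literature the analyst trusts — so no default list is
#' encoded beyond "everything except `other`".
#'
#' @param tab An [otu_table()].
#' @param drop_singletons Remove OTUs with a total of exactly 1 read.
#' @param guild_whitelist Character vector of guilds to retain.
#' @return A filtered `otu_table`; removed OTU ids are reported via a
#'   message and attached as attribute `"removed"` (a tibble with
#'   `otu_id` and `reason`). An empty result warns but is returned.
#' @export
filter_otu_table <- function(tab, drop_singletons = TRUE,
                             guild_whitelist = c("orchid_mycorrhizal",
                                                 "ectomycorrhizal",
                                                 "saprotrophic")) {
  if (!inherits(tab, "otu_table")) stop_invalid("`tab` must be an `otu_table`.")
  if (!all(guild_whitelist %in% otu_guilds)) {
    stop_invalid("`guild_whitelist` contains unknown guild labels.")
  }
  totals <- otu_totals(tab)
  singletons <- if (drop_singletons) totals$otu_id[totals$total == 1] else character()
  off_guild <- tab$otu_meta$otu_id[!tab$otu_meta$guild %in% guild_whitelist]
  off_guild <- setdiff(off_guild, singletons)
  removed <- bind_rows(
    tibble(otu_id = singletons,
           reason = rep("singleton", length(singletons))),
    tibble(otu_id = off_guild,
           reason = rep("guild_not_whitelisted", length(off_guild)))
  )
  keep <- setdiff(tab$otu_meta$otu_id, removed$otu_id)
  if (nrow(removed) > 0) {
    inform(sprintf(
      "Removed %d OTU(s): %s.", nrow(removed),
      paste(sprintf("%s (%s)", removed$otu_id, removed$reason), collapse = ", ")
    ))
  }
  if (length(keep) == 0) {
    warn("All OTUs were filtered out; returning an empty table.")
  }
  out <- structure(
    list(
      counts = dplyr::filter(tab$counts, .data$otu_id %in% keep),
      otu_meta = dplyr::filter(tab$otu_meta, .data$otu_id %in% keep),
      sample_meta = tab$sample_meta
    ),
    class = "otu_table"
  )
  attr(out, "removed") <- removed
  out
}

#' Relative abundance of OTUs per sample or per group
#'
#' Read percentages per unit: `by = "group"` pools reads over the samples
#' of each group before dividing (how per-phenotype community tables are
#' reported), `by = "sample"` keeps samples separate. Percentages are
#' rounded half-up to 2 decimals and sum to 100 per unit within rounding.
#'
#' @param tab An [otu_table()], normally already filtered with
#'   [filter_otu_table()].
#' @param by `"group"` or `"sample"`.
#' @return A tibble with `group` (or `sample_id`), `otu_id`, `genus`,
#'   `guild`, `reads`, `percent`. Units with zero total reads are dropped
#'   with a warning.
#' @examples
#' tab <- otu_table(
#'   tibble::tibble(sample_id = "alb1", OTU1 = 41821, Russula = 401,
#'                  Sebacina = 75),
#'   tibble::tibble(otu_id = c("OTU1", "Russula", "Sebacina"),
#'                  genus = c("Ceratobasidium", "Russula", "Sebacina"),
#'                  guild = c("orchid_mycorrhizal", "ectomycorrhizal",
#'                            "ectomycorrhizal")),
#'   tibble::tibble(sample_id = "alb1", group = "albino")
#' )
#' relative_abundance(tab, by = "group")
#' @export
relative_abundance <- function(tab, by = c("group", "sample")) {
  if (!inherits(tab, "otu_table")) stop_invalid("`tab` must be an `otu_table`.")
  by <- match.arg(by)
  counts <- tab$counts |>
    left_join(tab$sample_meta, by = "sample_id")
  unit <- if (by == "group") "group" else "sample_id"
  pooled <- counts |>
    group_by(.data[[unit]], .data$otu_id) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  totals <- pooled |>
    group_by(.data[[unit]]) |>
    summarise(total = sum(.data$reads), .groups = "drop")
  empty <- totals[[unit]][totals$total == 0]
  if (length(empty) > 0) {
    warn(sprintf(
      "Excluding %s(s) with zero total reads: %s.",
      if (by == "group") "group" else "sample",
      paste(empty, collapse = ", ")
    ))
  }
  pooled |>
    left_join(totals, by = unit) |>
    dplyr::filter(.data$total > 0) |>
    mutate(percent = round_half_up(.data$reads / .data$total * 100, 2)) |>
    select(-"total") |>
    left_join(select(tab$otu_meta, "otu_id", "genus", "guild"), by = "otu_id") |>
    select(all_of(unit), "otu_id", "genus", "guild", "reads", "percent") |>
    arrange(.data[[unit]], desc(.data$reads), .data$otu_id)
}

#' Dominance structure of mycobiont communities per group
#'
#' Ranks OTUs by read share within each group and reports cumulative
#' percentages, quantifying how strongly a community is dominated by its
#' top partners (e.g. "the top three OTUs account for over 83 % of
#' reads").
#'
#' @inheritParams relative_abundance
#' @return A tibble with `group`, `rank`, `otu_id`, `genus`, `reads`,
#'   `percent`, `cum_percent` (cumulative percentage, rounded half-up to
#'   2 decimals).
#' @export
dominance_summary <- function(tab) {
  rel <- relative_abundance(tab, by = "group")
  rel |>
    group_by(.data$group) |>
    arrange(desc(.data$reads), .data$otu_id, .by_group = TRUE) |>
    mutate(
      rank = row_number(),
      cum_percent = round_half_up(cumsum(.data$reads) / sum(.data$reads) * 100, 2)
    ) |>
    ungroup() |>
    select("group", "rank", "otu_id", "genus", "reads", "percent",
           "cum_percent")
}
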