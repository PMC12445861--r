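default_groups <- function() {
  tibble(
    name = c("albino", "scale_leaved", "green_leaved", "large_leaved",
             "autotroph_like"),
    site_id = "site1",
    n = 4L,
    true_pcdf = c(100, 92, 65, 53, 0),
    true_eps15N = c(6.3, 8.6, 5.6, 7.2, 0)
  )
}

default_otu_profile <- function() {
  otu_meta <- tibble(
    otu_id = c("OTU1", "OTU2", "OTU3", "OTU_russula", "OTU_sebacina",
               "OTU_clitopilus", "OTU_contam"),
    genus = c("Ceratobasidium", "Ceratobasidium", "Ceratobasidium",
              "Russula", "Sebacina", "Clitopilus", "Unknown"),
    family = c("Ceratobasidiaceae", "Ceratobasidiaceae", "Ceratobasidiaceae",
               "Russulaceae", "Sebacinaceae", "Entolomataceae", "unknown"),
    guild = c("orchid_mycorrhizal", "orchid_mycorrhizal", "orchid_mycorrhizal",
              "ectomycorrhizal", "ectomycorrhizal", "saprotrophic", "other")
  )
  # One strongly dominant mycorrhizal OTU per group plus rare bycatch,
  # the typical community shape in mycoheterotroph rhizomes.
  base <- c(OTU1 = 50, OTU2 = 0.5, OTU3 = 0.3, OTU_russula = 0.2,
            OTU_sebacina = 0.1, OTU_clitopilus = 0.1, OTU_contam = 0.2)
  weights <- rbind(
    albino = base,
    scale_leaved = c(10, 12, 2, 0.1, 0.1, 1, 0.2),
    green_leaved = base,
    large_leaved = base,
    autotroph_like = base
  )
  colnames(weights) <- otu_meta$otu_id
  list(
    otu_meta = otu_meta,
    weights = weights,
    samples_per_group = 3L,
    depth_range = c(5000L, 15000L)
  )
}

#' Configuration for the synthetic study generator
#'
#' Bundles every generative parameter for synthetic isotope and OTU data
#' emulating a plot-based mycoheterotrophy survey: 2 x 2-m plots each
#' holding at least three autotrophic reference plants, target
#' individuals of several taxa/phenotypes with group-specific true
#' fungal-carbon fractions, a shared Gaussian plot effect (the microsite
#' signal that plot-wise normalization removes), and Gaussian residual
#' noise on the per-mil scale. Defaults reproduce the scale of published
#' field surveys: reference delta13C of -34.4 +/- 0.6 per mil, a
#' full-mycoheterotroph enrichment of 8.4 per mil, plot SD 1.0 per mil,
#' residual SD 0.6 per mil, 4 plots x 3 references, and group true %Cdf
#' of 100 (albino baseline), 92, 65, 53 and 0.
#'
#' @param seed Integer seed; generators are pure functions of the
#'   configuration, including this seed.
#' @param sites Tibble/data frame with one row per site: `site_id`,
#'   `n_plots`, `refs_per_plot`, `ref_mean_delta13C`, `ref_sd`,
#'   `plot_sd`, `residual_sd`, and the delta15N analogues
#'   `ref_mean_delta15N`, `ref_sd_15N`, `plot_sd_15N`, `residual_sd_15N`.
#' @param groups Tibble with `name`, `site_id`, `n` (individuals,
#'   distributed round-robin over the site's plots), `true_pcdf`
#'   (percent, in \[0, 120\]), `true_eps15N` (per mil).
#' @param eps_fmh_true True full-mycoheterotroph 13C enrichment (per mil).
#' @param otu_profile List with `otu_meta` (OTU taxonomy/guild tibble),
#'   `weights` (group x OTU Dirichlet weight matrix, all > 0),
#'   `samples_per_group`, `depth_range` (min/max reads per sample).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             sites = NULL,
                             groups = NULL,
                             eps_fmh_true = 8.4,
                             otu_profile = NULL) {
  if (is.null(sites)) {
    sites <- tibble(
      site_id = "site1", n_plots = 4L, refs_per_plot = 3L,
      ref_mean_delta13C = -34.4, ref_sd = 0.6, plot_sd = 1.0,
      residual_sd = 0.6,
      ref_mean_delta15N = -4.5, ref_sd_15N = 0.5, plot_sd_15N = 0.5,
      residual_sd_15N = 0.5
    )
  }
  sites <- as_tibble(sites)
  if (is.null(groups)) groups <- default_groups()
  groups <- as_tibble(groups)
  if (!"true_eps15N" %in% names(groups)) {
    groups$true_eps15N <- groups$true_pcdf / 100 * 6.3
  }
  if (is.null(otu_profile)) otu_profile <- default_otu_profile()

  if (any(!groups$site_id %in% sites$site_id)) {
    stop_config(sprintf(
      "Group(s) reference unknown site(s): %s.",
      paste(setdiff(groups$site_id, sites$site_id), collapse = ", ")
    ))
  }
  if (any(groups$n < 1)) stop_config("Each group needs n >= 1.")
  if (any(groups$true_pcdf < 0 | groups$true_pcdf > 120)) {
    stop_config("`true_pcdf` must lie in [0, 120].")
  }
  if (!is.numeric(eps_fmh_true) || eps_fmh_true <= 0) {
    stop_config("`eps_fmh_true` must be positive.")
  }
  sds <- unlist(sites[, c("ref_sd", "plot_sd", "residual_sd", "ref_sd_15N",
                          "plot_sd_15N", "residual_sd_15N")])
  if (any(sds < 0)) stop_config("Noise SDs must be >= 0.")
  if (any(otu_profile$weights <= 0)) {
    stop_config("Dirichlet weights must be > 0.")
  }

  structure(
    list(seed = as.integer(seed), sites = sites, groups = groups,
         eps_fmh_true = eps_fmh_true, otu_profile = otu_profile),
    class = "synthetic_config"
  )
}

#' Simulate a plot-based isotope survey
#'
#' Draws an isotope sample table under the generative model the analysis
#' assumes. Per plot p a microsite effect b_p ~ N(0, plot_sd) shifts
#' references and targets alike; a reference plant in plot p has
#' delta13C = ref_mean + b_p + N(0, ref_sd), while a target of group g
#' has delta13C = ref_mean + b_p + (true_pcdf_g / 100) x eps_fmh_true +
#' N(0, residual_sd). delta15N is generated analogously with the group's
#' true 15N enrichment. Because the plot effect is shared, plot-wise
#' normalization recovers the heterotrophy signal.
#'
#' @param config A [synthetic_config()].
#' @return A list with `samples` (an isotope sample tibble ready for
#'   [enrichment_factors()]) and `truth` (the generating quantities:
#'   `groups`, per-plot effects, `eps_fmh_true`) kept separate from the
#'   data so recovery tests cannot leak it into the analysis path.
#' @export
gen_isotope_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("`config` must be a `synthetic_config`.")
  }
  with_seed(config$seed, {
    plots <- config$sites |>
      dplyr::rowwise() |>
      dplyr::reframe(
        site_id = .data$site_id,
        plot_id = sprintf("%s_p%d", .data$site_id, seq_len(.data$n_plots))
      )
    site_of <- setNames(plots$site_id, plots$plot_id)
    site_par <- split(config$sites, config$sites$site_id)
    effects <- tibble(
      plot_id = plots$plot_id,
      site_id = plots$site_id,
      effect13C = vapply(plots$plot_id, function(p) {
        rnorm(1, 0, site_par[[site_of[[p]]]]$plot_sd)
      }, numeric(1)),
      effect15N = vapply(plots$plot_id, function(p) {
        rnorm(1, 0, site_par[[site_of[[p]]]]$plot_sd_15N)
      }, numeric(1))
    )
    eff13 <- setNames(effects$effect13C, effects$plot_id)
    eff15 <- setNames(effects$effect15N, effects$plot_id)

    refs <- purrr::map_dfr(seq_len(nrow(plots)), function(i) {
      p <- plots$plot_id[i]
      sp <- site_par[[plots$site_id[i]]]
      k <- sp$refs_per_plot
      tibble(
        sample_id = sprintf("%s_ref%d", p, seq_len(k)),
        group = "reference",
        site_id = plots$site_id[i],
        plot_id = p,
        role = "reference",
        tissue = "leaf",
        delta13C = sp$ref_mean_delta13C + eff13[[p]] + rnorm(k, 0, sp$ref_sd),
        delta15N = sp$ref_mean_delta15N + eff15[[p]] +
          rnorm(k, 0, sp$ref_sd_15N)
      )
    })

    targets <- purrr::map_dfr(seq_len(nrow(config$groups)), function(gi) {
      g <- config$groups[gi, ]
      sp <- site_par[[g$site_id]]
      site_plots <- plots$plot_id[plots$site_id == g$site_id]
      assigned <- rep_len(site_plots, g$n)
      tibble(
        sample_id = sprintf("%s_%d", g$name, seq_len(g$n)),
        group = g$name,
        site_id = g$site_id,
        plot_id = assigned,
        role = "target",
        tissue = "leaf",
        delta13C = sp$ref_mean_delta13C + unname(eff13[assigned]) +
          g$true_pcdf / 100 * config$eps_fmh_true +
          rnorm(g$n, 0, sp$residual_sd),
        delta15N = sp$ref_mean_delta15N + unname(eff15[assigned]) +
          g$true_eps15N + rnorm(g$n, 0, sp$residual_sd_15N)
      )
    })

    list(
      samples = bind_rows(refs, targets),
      truth = list(
        groups = config$groups,
        plot_effects = effects,
        eps_fmh_true = config$eps_fmh_true
      )
    )
  })
}

#' Simulate an OTU count table
#'
#' Dirichlet-multinomial read counts per sample: each sample of group g
#' draws OTU proportions from Dirichlet(weights\[g, \]) and a read depth
#' uniformly from `depth_range`, then counts from a multinomial. The
#' default weights put one overwhelmingly dominant mycorrhizal OTU in
#' most groups, mimicking the near-monodominant communities of
#' mycoheterotroph rhizomes, plus rare ectomycorrhizal, saprotrophic and
#' off-target OTUs for the filtering stage to act on.
#'
#' @param config A [synthetic_config()].
#' @return An [otu_table()].
#' @export
gen_otu_table <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("`config` must be a `synthetic_config`.")
  }
  prof <- config$otu_profile
  otu_ids <- prof$otu_meta$otu_id
  with_seed(config$seed, {
    counts <- purrr::map_dfr(rownames(prof$weights), function(g) {
      w <- prof$weights[g, ]
      purrr::map_dfr(seq_len(prof$samples_per_group), function(s) {
        gam <- rgamma(length(w), shape = w, rate = 1)
        p <- gam / sum(gam)
        depth <- as.integer(round(runif(1, prof$depth_range[1],
                                        prof$depth_range[2])))
        tibble(
          sample_id = sprintf("%s_s%d", g, s),
          otu_id = otu_ids,
          count = as.numeric(rmultinom(1, depth, p))
        )
      })
    })
    sample_meta <- counts |>
      dplyr::distinct(.data$sample_id) |>
      mutate(group = sub("_s\\d+$", "", .data$sample_id))
    otu_table(counts, prof$otu_meta, sample_meta)
  })
}

#' Simulate amplicon reads with known family structure
#'
#' Generates `n_families` random centroid sequences and, per family,
#' `reads_per_family` reads derived from the centroid by independent
#' point substitutions at `mutation_rate`. The first read of each family
#' is the unmutated centroid and carries the family's highest abundance,
#' so an abundance-ranked clusterer should pick it as representative.
#' Reads keep their true family label for accuracy checks.
#'
#' @param n_families Number of sequence families.
#' @param reads_per_family Reads per family (>= 1).
#' @param read_length Sequence length in nt.
#' @param mutation_rate Per-site substitution probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return A tibble with `read_id`, `sequence`, `abundance`, `family`,
#'   usable directly by [greedy_cluster()].
#' @export
gen_read_set <- function(n_families = 3, reads_per_family = 10,
                         read_length = 150, mutation_rate = 0.01,
                         seed = 1L) {
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop_config("`mutation_rate` must be in [0, 0.5).")
  }
  if (n_families < 1 || reads_per_family < 1 || read_length < 1) {
    stop_config("Family counts and read length must be >= 1.")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_families), function(f) {
      centroid <- sample(bases, read_length, replace = TRUE)
      purrr::map_dfr(seq_len(reads_per_family), function(r) {
        s <- centroid
        if (r > 1 && mutation_rate > 0) {
          hit <- which(rbinom(read_length, 1, mutation_rate) == 1)
          for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1)
        }
        tibble(
          read_id = sprintf("fam%d_r%03d", f, r),
          sequence = paste(s, collapse = ""),
          abundance = if (r == 1) 1000L else
            as.integer(sample(1:100, 1)),
          family = sprintf("fam%d", f)
        )
      })
    })
  })
}
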