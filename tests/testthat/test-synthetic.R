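test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_config(seed = 101)
  expect_identical(gen_isotope_dataset(cfg), gen_isotope_dataset(cfg))
  expect_identical(gen_otu_table(cfg)$counts, gen_otu_table(cfg)$counts)
  expect_identical(gen_read_set(seed = 101), gen_read_set(seed = 101))
  # and the RNG state of the session is left untouched
  set.seed(1)
  before <- .Random.seed
  invisible(gen_isotope_dataset(cfg))
  expect_identical(.Random.seed, before)
})

test_that("noise-free generation hits the mixing identity exactly", {
  sites <- tibble::tibble(
    site_id = "s", n_plots = 4L, refs_per_plot = 3L,
    ref_mean_delta13C = -34.4, ref_sd = 0, plot_sd = 0, residual_sd = 0,
    ref_mean_delta15N = -4.5, ref_sd_15N = 0, plot_sd_15N = 0,
    residual_sd_15N = 0
  )
  groups <- tibble::tibble(
    name = c("albino", "half"), site_id = "s", n = 4L,
    true_pcdf = c(100, 50), true_eps15N = c(6.3, 3.0)
  )
  cfg <- synthetic_config(seed = 5, sites = sites, groups = groups,
                          eps_fmh_true = 8.4)
  iso <- gen_isotope_dataset(cfg)
  rec <- enrichment_factors(iso$samples)
  half <- rec[rec$group == "half", ]
  expect_equal(half$eps13C, rep(0.5 * 8.4, 4))
  # full pipeline identity: estimated %Cdf equals the generating %Cdf
  m <- mixing_model(rec, fmh_baseline(rec, "albino"))
  expect_equal(m$pcdf_mean[m$group == "half"], 50)
  expect_equal(m$pcdf_mean[m$group == "albino"], 100)
})

test_that("reference marginal SD combines plot and residual variance", {
  sites <- tibble::tibble(
    site_id = "s", n_plots = 1000L, refs_per_plot = 1L,
    ref_mean_delta13C = -34.4, ref_sd = 0.6, plot_sd = 1.0,
    residual_sd = 0.6,
    ref_mean_delta15N = -4.5, ref_sd_15N = 0.5, plot_sd_15N = 0.5,
    residual_sd_15N = 0.5
  )
  groups <- tibble::tibble(name = "g", site_id = "s", n = 1L,
                           true_pcdf = 50, true_eps15N = 3)
  cfg <- synthetic_config(seed = 11, sites = sites, groups = groups)
  iso <- gen_isotope_dataset(cfg)
  refs <- iso$samples[iso$samples$role == "reference", ]
  expect_equal(nrow(refs), 1000L)
  expect_lt(abs(sd(refs$delta13C) - sqrt(1.0^2 + 0.6^2)) / sqrt(1.36), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(
    synthetic_config(groups = tibble::tibble(
      name = "g", site_id = "nowhere", n = 1L, true_pcdf = 50,
      true_eps15N = 1
    )),
    regexp = "nowhere", class = "mycomix_config_error"
  )
  expect_error(
    synthetic_config(groups = tibble::tibble(
      name = "g", site_id = "site1", n = 0L, true_pcdf = 50, true_eps15N = 1
    )),
    class = "mycomix_config_error"
  )
  expect_error(
    synthetic_config(groups = tibble::tibble(
      name = "g", site_id = "site1", n = 2L, true_pcdf = 150, true_eps15N = 1
    )),
    class = "mycomix_config_error"
  )
  expect_error(gen_read_set(mutation_rate = 0.5),
               class = "mycomix_config_error")
})

test_that("dominant Dirichlet weight produces a dominant OTU", {
  shares <- vapply(1:5, function(s) {
    cfg <- synthetic_config(seed = s)
    tab <- gen_otu_table(cfg)
    rel <- relative_abundance(tab, by = "group")
    rel$percent[rel$group == "albino" & rel$otu_id == "OTU1"]
  }, numeric(1))
  expect_true(all(shares > 90))
})

test_that("a single-OTU profile yields 100 percent everywhere", {
  prof <- list(
    otu_meta = tibble::tibble(otu_id = "only", genus = "g",
                              family = "f", guild = "orchid_mycorrhizal"),
    weights = matrix(1, 1, 1, dimnames = list("g1", "only")),
    samples_per_group = 2L,
    depth_range = c(100L, 200L)
  )
  cfg <- synthetic_config(seed = 3, otu_profile = prof)
  tab <- gen_otu_table(cfg)
  rel <- relative_abundance(tab, by = "sample")
  expect_true(all(rel$percent == 100))
})

test_that("read sets recover their families under clustering", {
  # no mutations: exactly n_families clusters
  rs0 <- gen_read_set(n_families = 4, reads_per_family = 5,
                      read_length = 100, mutation_rate = 0, seed = 13)
  cl0 <- greedy_cluster(rs0)
  expect_equal(length(cl0$centroids), 4L)

  # 1 % mutations on 150-mers at the 97 % threshold: nearly all reads
  # land in their true family's centroid
  correct <- vapply(1:5, function(s) {
    rs <- gen_read_set(n_families = 3, reads_per_family = 10,
                       read_length = 150, mutation_rate = 0.01, seed = s)
    cl <- greedy_cluster(rs, threshold = 0.97)
    truth <- setNames(rs$family, rs$read_id)
    mean(truth[cl$membership$read_id] == truth[cl$membership$centroid_id])
  }, numeric(1))
  expect_gte(mean(correct), 0.95)
})
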