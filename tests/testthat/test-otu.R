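albino_table <- function() {
  otu_table(
    tibble::tibble(sample_id = "alb1", OTU1 = 41821, Russula = 401,
                   Sebacina = 75),
    tibble::tibble(
      otu_id = c("OTU1", "Russula", "Sebacina"),
      genus = c("Ceratobasidium", "Russula", "Sebacina"),
      guild = c("orchid_mycorrhizal", "ectomycorrhizal", "ectomycorrhizal")
    ),
    tibble::tibble(sample_id = "alb1", group = "albino")
  )
}

test_that("otu_table validates counts, metadata and sample groups", {
  expect_s3_class(albino_table(), "otu_table")
  expect_error(
    otu_table(tibble::tibble(sample_id = "s", OTU1 = -1),
              tibble::tibble(otu_id = "OTU1", genus = "g",
                             guild = "other")),
    class = "mycomix_invalid_input"
  )
  expect_error(
    otu_table(tibble::tibble(sample_id = "s", OTU1 = 1.5),
              tibble::tibble(otu_id = "OTU1", genus = "g",
                             guild = "other")),
    class = "mycomix_invalid_input"
  )
  expect_error(
    otu_table(tibble::tibble(sample_id = "s", OTU1 = 5),
              tibble::tibble(otu_id = "OTU2", genus = "g",
                             guild = "other")),
    regexp = "OTU1", class = "mycomix_invalid_input"
  )
  expect_error(
    otu_table(tibble::tibble(sample_id = "s", OTU1 = 5),
              tibble::tibble(otu_id = "OTU1", genus = "g",
                             guild = "mycorrhizal")),
    class = "mycomix_invalid_input"
  )
})

test_that("singletons and off-whitelist guilds are removed", {
  tab <- otu_table(
    tibble::tibble(
      sample_id = c("s1", "s2"),
      OTU1 = c(100, 200), OTU_single = c(1, 0), OTU_plant = c(5000, 5000)
    ),
    tibble::tibble(
      otu_id = c("OTU1", "OTU_single", "OTU_plant"),
      genus = c("Ceratobasidium", "Tulasnella", "Quercus"),
      guild = c("orchid_mycorrhizal", "orchid_mycorrhizal", "other")
    )
  )
  f <- suppressMessages(filter_otu_table(tab))
  expect_equal(f$otu_meta$otu_id, "OTU1")
  removed <- attr(f, "removed")
  expect_setequal(removed$otu_id, c("OTU_single", "OTU_plant"))
  expect_equal(removed$reason[removed$otu_id == "OTU_single"], "singleton")

  # singleton kept when the flag is off
  f2 <- suppressMessages(filter_otu_table(tab, drop_singletons = FALSE))
  expect_true("OTU_single" %in% f2$otu_meta$otu_id)

  # empty result warns, not errors
  expect_warning(
    suppressMessages(filter_otu_table(tab, guild_whitelist = "saprotrophic")),
    "filtered out"
  )
})

test_that("filtering equals a brute-force set computation on random tables", {
  set.seed(53)
  for (r in 1:5) {
    n_otu <- 12
    meta <- tibble::tibble(
      otu_id = sprintf("O%02d", 1:n_otu),
      genus = sample(letters, n_otu, replace = TRUE),
      guild = sample(c("orchid_mycorrhizal", "ectomycorrhizal",
                       "saprotrophic", "other"), n_otu, replace = TRUE)
    )
    counts <- tibble::tibble(sample_id = c("s1", "s2", "s3"))
    for (o in meta$otu_id) {
      counts[[o]] <- rpois(3, lambda = sample(c(0.3, 2, 50), 1))
    }
    tab <- otu_table(counts, meta)
    wl <- c("orchid_mycorrhizal", "ectomycorrhizal")
    f <- suppressMessages(suppressWarnings(
      filter_otu_table(tab, guild_whitelist = wl)
    ))
    totals <- colSums(counts[, meta$otu_id])
    keep_brute <- meta$otu_id[totals != 1 & meta$guild %in% wl]
    expect_setequal(f$otu_meta$otu_id, keep_brute)
  }
})

test_that("relative abundance reproduces dominant-partner percentages", {
  rel <- relative_abundance(albino_table(), by = "group")
  expect_equal(rel$percent[rel$otu_id == "OTU1"], 98.87)
  expect_equal(rel$percent[rel$otu_id == "Russula"], 0.95)
  expect_equal(rel$percent[rel$otu_id == "Sebacina"], 0.18)

  proto <- otu_table(
    tibble::tibble(sample_id = "pc1", OTU1 = 26000, Russula = 58),
    tibble::tibble(otu_id = c("OTU1", "Russula"),
                   genus = c("Ceratobasidium", "Russula"),
                   guild = c("orchid_mycorrhizal", "ectomycorrhizal")),
    tibble::tibble(sample_id = "pc1", group = "protocorm")
  )
  relp <- relative_abundance(proto, by = "group")
  expect_equal(relp$percent[relp$otu_id == "OTU1"], 99.78)
  expect_equal(relp$percent[relp$otu_id == "Russula"], 0.22)

  single <- otu_table(
    tibble::tibble(sample_id = "s", OTU1 = 7),
    tibble::tibble(otu_id = "OTU1", genus = "g",
                   guild = "orchid_mycorrhizal")
  )
  expect_equal(relative_abundance(single)$percent, 100.00)
})

test_that("percentages sum to 100 per unit and survive rescaling", {
  set.seed(59)
  cfg <- synthetic_config(seed = 61)
  tab <- suppressMessages(filter_otu_table(gen_otu_table(cfg)))
  for (by in c("group", "sample")) {
    rel <- relative_abundance(tab, by = by)
    unit <- if (by == "group") rel$group else rel$sample_id
    sums <- tapply(rel$percent, unit, sum)
    expect_true(all(abs(sums - 100) <= 0.02))
    exact <- tapply(rel$reads, unit, function(x) sum(x / sum(x)) * 100)
    expect_true(all(abs(exact - 100) < 1e-9))
  }
  # scale invariance of the percentages (singleton flag off)
  scaled <- tab
  scaled$counts$count <- scaled$counts$count * 7
  tab2 <- otu_table(scaled$counts, scaled$otu_meta, scaled$sample_meta)
  expect_equal(
    relative_abundance(tab2, by = "group")$percent,
    relative_abundance(tab, by = "group")$percent
  )
})

test_that("zero-read units are excluded with a warning", {
  tab <- otu_table(
    tibble::tibble(sample_id = c("s1", "s2"), OTU1 = c(10, 0)),
    tibble::tibble(otu_id = "OTU1", genus = "g",
                   guild = "orchid_mycorrhizal"),
    tibble::tibble(sample_id = c("s1", "s2"), group = c("g1", "g2"))
  )
  expect_warning(rel <- relative_abundance(tab, by = "sample"), "zero total")
  expect_equal(rel$sample_id, "s1")
})

test_that("dominance summary ranks OTUs and accumulates shares", {
  # community with the scale-leaved morph's printed shares: ranks go by
  # reads (the saprotroph outranks OTU3), while the three Ceratobasidium
  # OTUs jointly hold 83.78 %
  tab <- otu_table(
    tibble::tibble(sample_id = "of", OTU1 = 9589, OTU2 = 10302,
                   OTU3 = 1255, Clitopilus = 3928, Other = 165),
    tibble::tibble(
      otu_id = c("OTU1", "OTU2", "OTU3", "Clitopilus", "Other"),
      genus = c("Ceratobasidium", "Ceratobasidium", "Ceratobasidium",
                "Clitopilus", "Unknown"),
      guild = c("orchid_mycorrhizal", "orchid_mycorrhizal",
                "orchid_mycorrhizal", "saprotrophic", "saprotrophic")
    ),
    tibble::tibble(sample_id = "of", group = "scale_leaved")
  )
  dom <- dominance_summary(tab)
  expect_equal(dom$otu_id[1:3], c("OTU2", "OTU1", "Clitopilus"))
  expect_equal(dom$cum_percent[3],
               round_half_up((10302 + 9589 + 3928) /
                               (9589 + 10302 + 1255 + 3928 + 165) * 100, 2))
  expect_gt(dom$cum_percent[3], 83)
  # the three Ceratobasidium OTUs jointly hold 83.78 % of group reads
  cerato <- dom$percent[dom$otu_id %in% c("OTU1", "OTU2", "OTU3")]
  expect_equal(sum(cerato), 83.78)

  # uniform shares: rank-j cumulative = j/k * 100
  uni <- otu_table(
    tibble::tibble(sample_id = "u", A = 10, B = 10, C = 10, D = 10),
    tibble::tibble(otu_id = c("A", "B", "C", "D"), genus = "g",
                   guild = "orchid_mycorrhizal")
  )
  dom_u <- dominance_summary(uni)
  expect_equal(dom_u$cum_percent, (1:4) / 4 * 100)

  # single OTU: cumulative 100 at rank 1
  one <- otu_table(
    tibble::tibble(sample_id = "u", A = 33),
    tibble::tibble(otu_id = "A", genus = "g", guild = "orchid_mycorrhizal")
  )
  expect_equal(dominance_summary(one)$cum_percent, 100)
})
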