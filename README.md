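# mycomix

Quantifies **partial mycoheterotrophy** — the fraction of a green
plant's carbon that arrives through its mycorrhizal fungi — from
stable-isotope field surveys, and summarizes the fungal communities
(mycobionts) detected by metabarcoding in the same plants. It is aimed
at plant ecologists running plot-based δ¹³C/δ¹⁵N studies of orchids and
other putatively mixotrophic plants.

## The model

Samples are collected in small plots, each containing target plants and
at least three co-occurring autotrophic **reference plants**. For a
sample with isotope value δ_S, the enrichment factor is

    ε = δ_S − δ_REF

where δ_REF is the mean over the reference plants of the *same plot*
(plot-wise normalization cancels shared microsite effects). The percent
of fungal-derived carbon comes from a linear two-source mixing model,

    %Cdf = ε¹³C_PMH / ε¹³C_FMH × 100

anchored at ε = 0 (autotrophs, 0 %) and at ε¹³C_FMH, the mean ¹³C
enrichment of a **full-mycoheterotroph baseline** group — typically
chlorophyll-free (albino) individuals, optionally protocorms. Groups
are compared with a linear mixed model, `δ ~ group + (1 | plot)`, with
single-step Tukey–Kramer contrasts; two-morph trait comparisons use
Student's t-tests.

The metabarcoding side filters OTU tables (singleton removal, trophic
guild whitelist), computes per-sample/per-group relative abundances and
dominance summaries, and includes a deterministic abundance-ranked
greedy clusterer at 97 % identity with a tested global-alignment
identity definition.

A synthetic-data generator reproduces the plot-based study design
(shared Gaussian plot effects, group-specific true %Cdf,
Dirichlet-multinomial OTU counts) so every stage is testable with known
truth.

## Worked example

```r
library(mycomix)

cfg <- synthetic_config(seed = 42)          # study-design defaults
iso <- gen_isotope_dataset(cfg)
res <- pipeline_isotope(iso$samples, baseline_group = "albino")

res$baseline
#> # A tibble: 1 × 4
#>   baseline_group eps_fmh eps_sd     n
#> 1 albino            8.30  0.636     4

res$mixing
#> # A tibble: 5 × 6
#>   group          pcdf_mean pcdf_sd     n eps_fmh_baseline clamped
#> 1 albino            100       7.66     4             8.30 FALSE
#> 2 autotroph_like      3.73   11.3      4             8.30 FALSE
#> 3 green_leaved       65.6     8.21     4             8.30 FALSE
#> 4 large_leaved       50.3     9.33     4             8.30 FALSE
#> 5 scale_leaved       93.1     7.57     4             8.30 FALSE
```

The albino group estimates its own baseline (100 % by construction, up
to noise); the other groups were generated with true %Cdf 0, 65, 53 and
92 — each recovered within sampling error. `res$contrasts$delta13C`
holds the Tukey–Kramer table, `res$summary` a publication-style
group × (δ¹³C, δ¹⁵N, %Cdf) mean ± SD table.

On the community side, feeding the read counts of a near-monodominant
albino sample through the abundance summary:

```r
tab <- otu_table(
  tibble::tibble(sample_id = "alb1", OTU1 = 41821, Russula = 401, Sebacina = 75),
  tibble::tibble(otu_id = c("OTU1", "Russula", "Sebacina"),
                 genus  = c("Ceratobasidium", "Russula", "Sebacina"),
                 guild  = c("orchid_mycorrhizal", "ectomycorrhizal", "ectomycorrhizal")),
  tibble::tibble(sample_id = "alb1", group = "albino"))
relative_abundance(tab, by = "group")
#>   group  otu_id   genus          guild              reads percent
#> 1 albino OTU1     Ceratobasidium orchid_mycorrhizal 41821   98.87
#> 2 albino Russula  Russula        ectomycorrhizal      401    0.95
#> 3 albino Sebacina Sebacina       ectomycorrhizal       75    0.18
```

A thin command-line wrapper with `simulate` / `isotope` / `otu` /
`cluster` subcommands lives at `inst/cli/mycomix.R`.

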