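# ringsync

Tree-ring network synchrony and climate–growth response analysis for
high-elevation conifer networks, built around the kind of multi-species
ring-width network archived at the ITRDB for the southeast Tibetan
Plateau: 17 site chronologies from four species whose growth shares a
common winter-temperature signal that has strengthened in recent
decades.

`ringsync` is aimed at dendroclimatologists who want a scripted,
reproducible version of this analysis chain:

1. **Chronology building** — Tucson `.rwl` reading/writing; conservative
   detrending (negative exponential `a·e^(−b·t)+k` → non-positive-slope
   line → smoothing spline with a 50% frequency-response cutoff at 67% of
   the mean segment length); ratio indices `x_t / G_t`; Tukey biweight
   robust mean; rbar, EPS, mean sensitivity; subsample signal strength
   `SSS = n(1+(N−1)r̄) / (N(1+(n−1)r̄))` with truncation at SSS < 0.85.
2. **Network synchrony** — PCA on the correlation matrix of the
   chronology network, running 50-year windows lagged by 10 years for
   the PC1 variance share, and extreme ring (mean ± 1.5 SD) frequency.
3. **Climate response** — correlation functions over the 17-month
   dendroclimatic year (previous May … current September), seasonal
   composites, 30-year moving correlations, and a Monte Carlo
   (Gershunov-style) test of moving-correlation stability against
   bivariate AR(1) surrogates.
4. **Fuzzy partition** — fuzzy C-means clustering of site index vectors
   in cold (1965–1980) vs warm (1990–2005) winters, with fuzzy
   cardinalities, pseudo-F, centroid distance and the count of years
   with significant between-cluster differences.
5. **Nonlinearity** — ensemble empirical mode decomposition (EEMD)
   trends, and a small feed-forward neural network mapping winter
   temperatures to growth, with a response surface and a piecewise-linear
   breakpoint detector for the winter-temperature sensitivity threshold.
6. **Synthetic data** — a seeded generator for ring-width networks
   (shared signal with time-varying strength, site groups, site- and
   core-level noise, age trends, staggered cores) and monthly climate
   (seasonal climatology, AR(1) anomalies, trends, coupling to the
   network signal), so every stage has a parameter-recovery test without
   any download.

## Worked example

The whole pipeline on a synthetic 17-site network (1700–2005, signal
fraction stepping 0.3 → 0.6 in 1985, winter minimum temperature coupled
to the common signal at r = 0.6):

```r
library(ringsync)
rep <- run_synthetic_demo(seed = 1)

rep$pca$shares[1:2]
#> [1] 32.64726 11.99321
tail(rep$running, 3)
#>    start  end     label pc1_share
#> 12  1935 1984 1935-1984  24.83710
#> 13  1945 1994 1945-1994  35.17631
#> 14  1955 2005 1955-2005  35.78832
subset(as.data.frame(rep$correlation_function),
       predictor %in% c("pNov", "pDec", "Jan", "season"))
#>    predictor         r
#> 7       pNov 0.4865423
#> 8       pDec 0.5332863
#> 9        Jan 0.5015986
#> 18    season 0.5797574
rep$partition[1:2, ]
#>      cluster_distance   group1   group2     pseudo_F n_significant_years
#> cold     0.0007496587 8.500195 8.499805 1.981538e-07                   6
#> warm     3.2712824108 8.522079 8.477921 5.654498e+00                   9
```

Reading: the leading component carries ~33% of the network variance and
its running share peaks in the final (anchored, 51-year) "1955-2005"
window; the winter months and their November–January composite are the
strongest climate correlates (the composite r ≈ 0.58 against a 99%
critical r of 0.34 at n = 54); and the warm-interval partition is far
cleaner than the cold one (higher pseudo-F, more contrasting years) —
the qualitative structure expected when warm winters synchronize
temperature-limited growth.

Real data go through the same functions: point
`pipeline_config(rwl_dir, climate, out_dir)` at a directory of Tucson
`.rwl` files and a monthly climate table (columns `year month tmp tmx
tmn pre`) and call `run_pipeline()`; every stage writes a tab-separated
table plus a JSON run manifest.

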