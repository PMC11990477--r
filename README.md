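# vinosense

Odor activity value (OAV) profiling and electronic-nose chemometrics for
wine aroma.

Wine aroma is driven by volatile compounds whose sensory impact is
captured by the **odor activity value**, the ratio of a compound's
concentration to its odor perception threshold (OPT):

```
OAV = concentration / OPT
```

Compounds with OAV > 0.2 are treated as aroma-active, and compounds are
grouped into eleven **odorant series** (chemical, fruity/ripe fruit,
green fruit, green, floral, creamy, citrus, herbaceous, toasty/smoky,
honey, waxy); each series score is the sum of its members' OAVs, with
multi-series compounds counted fully in every series they belong to. The
package couples this scoring with the chemometric stack used to analyse
quartz-microbalance (QMB) electronic-nose data:

- column auto-scaling, PCA (SVD, deterministic component signs);
- NIPALS PLS2 / PLS-DA with per-LV explained variance of both blocks,
  VIP scores (mean VIP² = 1, VIP > 1 flagged influential), calibration
  and venetian-blind cross-validation confusion matrices;
- principal component regression with RMSEC, RMSECV, R² (calibration and
  CV) and RPD = SD/RMSECV per response;
- Pearson correlation maps between series scores and sensor responses;
- a synthetic-data generator (class-structured profiles, linear QMB
  response model with configurable noise) so every stage can be
  exercised without instrument data;
- a config-driven pipeline (`run_all()`) and CLI that writes CSV reports
  plus an MD5 manifest, byte-identical under a fixed seed.

A packaged dataset of 57 quantified volatiles across five experimental
wines — spontaneous flora (WY), *S. cerevisiae* (SC), *M. pulcherrima*
(MP), and *L. thermotolerans* free (LT) or in biocapsules (BC) — is
included.

## Worked example

Score the packaged five-wine dataset:

```r
library(vinosense)
fx <- load_fivewine_fixture()
sm <- series_summary(series_profile(fx))
head(sm[order(-sm$mean), ], 4)
#>       series   mean    min    max     sd
#> 1   chemical 399.49 349.10 497.52 58.644
#> 7     citrus 365.73 323.80 470.90 60.591
#> 5     floral  61.32  48.13  71.02  9.677
#> 8 herbaceous  54.40  44.30  67.20  9.142

length(flag_active(fx)$active_compounds)
#> [1] 32
```

Run the full pipeline on synthetic data (5 classes × 6 replicates,
12-sensor array), with the replication profile (3 PLS-DA latent
variables, 5 PCR components, venetian blind thickness 1):

```r
cfg <- run_config(synthetic = TRUE, sim = sim_config(seed = 1),
                  seed = 1, replicate_paper = TRUE)
res <- run_all(cfg)

res$classification$confusion_cal$accuracy   # 1 (100% calibration)
res$classification$confusion_cv$accuracy    # 1 (100% cross-validation)

res$classification$vip[res$classification$vip$influential, ]
#>    sensor  vip influential
#> 3    QMB3 1.31        TRUE
#> 4    QMB4 1.46        TRUE
#> 6    QMB6 1.17        TRUE
#> 10  QMB10 1.43        TRUE

res$prediction$metrics[1:3, c("response", "sd", "rmsec", "rmsecv",
                              "r2_cal", "r2_cv", "rpd")]
#>            response    sd rmsec rmsecv r2_cal r2_cv   rpd
#> 1          chemical 60.63 3.999  4.680  0.995 0.994 12.96
#> 2 fruity/ripe fruit 11.10 1.191  1.706  0.988 0.976  6.51
#> 3       green fruit  1.32 0.418  0.547  0.896 0.823  2.42
```

Setting `out_dir` writes every table as CSV plus `manifest.csv` (MD5
checksums) and `run_log.json`; reruns with the same config and seed are
byte-identical. The same stages are available from the command line:

```sh
Rscript inst/cli/vinosense.R run-all --synthetic --seed 1 --replicate-paper --out results/
```

See `vignettes/methods.Rmd` for the mathematical conventions (NIPALS
details, VIP definition, venetian-blind folds, metric formulas) and the
synthetic data model's assumptions and limitations.

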