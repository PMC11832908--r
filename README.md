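# petsr

Sightings-based local extinction potential from multi-source species
occurrence records.

Regional species datasets — butterflies being the archetype — accumulate
over centuries from heterogeneous sources: faunistic literature and museum
collections, opportunistic citizen-science platforms, and structured expert
sampling. A species unrecorded for much of its known regional history is a
candidate for local extinction, but the strength of that signal depends on
who has been looking, where, and when. `petsr` is for ecologists and
biodiversity-informatics practitioners who need to integrate such records,
quantify the silence, and test how much of the apparent persistence of a
fauna rests on a single data source.

## What it computes

The core statistic is **PETS** (Potential Extinction upon Time Series). For
a species with first record year *y<sub>first</sub>*, last record year
*y<sub>last</sub>* and final survey year *Y<sub>end</sub>*:

```
PETS = (Y_end − y_last) / (Y_end − y_first)
```

— the fraction of the species' known regional history during which it has
gone unobserved (0 when recorded in the final year, up to 1 for a species
known from a single historical record). At community level the package
reports both the pooled ratio (summed absence spans over summed record
spans, the default) and the mean of per-species ratios, and recomputes
everything with chosen sources excluded — the built-in sensitivity analysis
for source dependence.

Around the statistic, the package provides:

* **records_io** — reading/writing delimited occurrence tables through a
  remappable column dialect, cleaning rules (yearless records dropped and
  counted, year-assigned flags tallied, resolution classes summarised) and
  per-source species inventories;
* **pets** — per-species and community PETS, source-exclusion variants,
  "last seen before year" screens, and the species-by-year
  persistence/absence timeline matrix with a plot method;
* **spatial grid** — an in-package WGS84 UTM projection and half-open
  square-cell assignment (default 10 km), per-cell per-source densities and
  occupancy percentages against an optional region mask;
* **trends** — yearly record/richness tables (zero-completed for
  smoothers) and period splits around a pivot year; the model fits
  themselves are deliberately out of scope;
* **synthetic data** — a seeded virtual-ecologist generator with known
  ground truth (effort regimes per source, per-species detectability,
  scheduled true extinctions) and a study-like 170-species preset,
  `alpine_preset()`.

## Worked example

```r
library(petsr)

sim <- generate_occurrences(alpine_preset(seed = 1))
report <- dataset_report(sim$records, end_year = 2022,
                         grid = grid_spec(zone = 32))
report
```

```
Occurrence cleaning report
  input records:      20972
  retained:           20972
  dropped (no year):  0
  year-assigned:      336
  georeferenced:      20972
  years: 1830-2022 (193 distinct record years)
  citizen_science           15001 (71.5%)
  literature_collections     3935 (18.8%)
  sampling                   2036 (9.7%)

Species: 170 overall; missing per source: literature_collections=2, citizen_science=10, sampling=139

Community extinction potential: 4.23% (all sources), 13.98% (no citizen science)
Species last seen before 1996: 10; not recorded in 2022: 10

  literature_collections   occupies 79 / 80 cells (99%)
  citizen_science          occupies 80 / 80 cells (100%)
  sampling                 occupies 18 / 80 cells (22%)

Period split at 2005 (before means year < 2005)
  before: 4570 (21.8%)   after: 16402 (78.2%)
  after-period composition:
    citizen_science           14650 (89.3%, 0 year-assigned)
    literature_collections      180 (1.1%, 0 year-assigned)
    sampling                   1572 (9.6%, 0 year-assigned)
```

Reading the output: the simulated fauna of 170 species is dominated by the
recent-onset citizen-science source (71.5% of records, 89.3% of the
post-2005 block). Pooled over species, 4.23% of the community's collective
known history is trailing silence — but removing the citizen-science
records more than triples that to 13.98%, showing how much of the apparent
persistence rests on that one source. The ten species last seen before 1996
are exactly the generator's scheduled true extinctions
(`report$last_seen_before` lists them with their first/last years), and
structured sampling covers only 18 of 80 grid cells, its spatial
restriction. `plot(timeline_matrix(sim$records, end_year = 2022))` draws
the per-species persistence (green) and absence (pink) bars with record
years coloured by source.

The same pipeline runs on any delimited occurrence table via
`read_occurrences()` (with an `occ_dialect()` to remap column names and
source tokens) and a thin command-line wrapper ships in `inst/cli/pets.R`
with `compute`, `grid`, `trends` and `simulate` subcommands.

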