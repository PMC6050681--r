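# oakpine

Multiscale caching trees for genome-browser track data.

A genome browser serves a user who pans and zooms across a chromosome.
Doing that responsively requires three things of the data layer: fetch
only what the current view needs, never re-fetch what is already held,
and fetch dense signal only at the resolution the screen can display.
`oakpine` implements that layer as a standalone R library:

* **Oak** — a weight-balanced (BB[α], α = 0.292) key/value tree caching
  sparse records (BED). Leaf keys partition the chromosome; a data key
  holds the records starting at its left coordinate plus those spanning
  it; placeholder keys mark unloaded genome.
* **Pine** — a fixed-branching (n = 20) multiscale tree caching dense
  signal (bedGraph) as five-metric summaries
  (bases, Σv, Σv², max, min). Its depth follows the viewing
  resolution r = view length / pixel width:
  `depth = ⌈log_n(chromosome length) − log_n(r)⌉`, floored at 1.
* **Withering** — life-span eviction: each query resets overlapping
  nodes (and their ancestors) to life 10, ages all others by 1, and
  demotes nodes reaching 0 to placeholders, so data untouched for ten
  queries leave memory and are re-fetched on demand.
* A **session engine** that turns each view query into minimal backend
  fetches (interval set-difference against the loaded regions), a
  **transfer ledger** that meters every simulated fetch in logical
  records and bases, and a **static SVG renderer** including a
  double-layer panel that links paired intervals (Hi-C style) between
  two independently scrolled axes on a green-to-red intensity scale.

Inputs are plain text: BED (sparse), bedGraph (dense), BEDPE-style
pairs (interactions), and a UCSC `chrom.sizes` table. A seeded fixture
generator produces all of them, so everything in the test suite is
reproducible from code.

## Worked example

```r
library(oakpine)

dir <- "tracks_demo"
gen_tracks(fixture_spec(seed = 42), dir)   # 3 x 5 kb chromosomes

be <- data_backend(file.path(dir, "chrom.sizes"))
backend_add_track(be, "peaks",  "sparse",      file.path(dir, "sparse.bed"))
backend_add_track(be, "signal", "dense",       file.path(dir, "dense.bedgraph"))
backend_add_track(be, "hic",    "interaction", file.path(dir, "interactions.bedpe"))

ses <- cache_session(be)
p1 <- session_query(ses, c("peaks", "signal"), viewport("chrI", 1000, 2000, 100))
head(p1$tracks$peaks$records[, c("chrom", "start", "end", "name", "score", "strand")], 3)
#>   chrom start  end     name score strand
#> 1  chrI   824 1055 feat0457   164      .
#> 2  chrI   937 1069 feat0497   220      -
#> 3  chrI  1089 1104 feat0142   232      +
head(subset(p1$tracks$signal$profile, !gap)[, c("pixel", "start", "end", "mean")], 3)
#>   pixel start  end   mean
#> 2     1  1010 1020 0.2578
#> 3     2  1020 1030 0.2578
#> 4     3  1030 1040 0.2578
```

The sparse payload is every record overlapping the view (records
reaching in from outside included); the dense payload is one row per
pixel with the mean (and max/min) of the signal under that pixel, `gap`
marking pixels with no covered bases. Shift the view by half a window
and the ledger shows that only the uncovered half is transferred:

```r
p2 <- session_query(ses, c("peaks", "signal"), viewport("chrI", 1500, 2500, 100))
transfer_report(ses)
#>   query_id requests records_sent bases_summarized cum_requests cum_records_sent
#> 1        1     1001           31              483         1001               31
#> 2        2      501           15              203         1502               46
#>   cum_bases_summarized
#> 1                  483
#> 2                  686
```

Query 2 summarizes 203 bases — exactly the signal-covered bases in the
new half-window (1 bp summary requests at base resolution, hence ~500
requests) — and re-sends none of the 31 records already cached. Repeating
a query produces an all-zero row. The Oak stays balanced throughout:

```r
check_weight_balance(ses$tracks$peaks$trees$chrI)
#> balanced: TRUE (worst child-weight fraction 0.333)
```

`render_tracks(p1, layout_spec(100))` returns the SVG document for the
payload; interaction payloads render as a double-layer panel
(`render_interactions()`) whose top and bottom axes may show different
chromosomes.

A command-line wrapper over the same functions ships in `inst/cli/`:
`gen` (fixtures), `trace` (replay a JSON-lines query trace; writes
payload dumps and the transfer report), `render` (one trace step to
SVG) and `audit` (verify every cache answer against brute-force file
scans). See `?cli_main`.

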