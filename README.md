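# lrnet

Directed cell-to-cell communication networks from expression data and a
curated ligand–receptor pair database.

Multicellular tissues coordinate through ligands secreted or displayed by
one cell type and receptors expressed by another. Given (i) a table of
curated ligand–receptor pairs, (ii) a genes × cells expression matrix
(single-cell or bulk) and (iii) a cell → cell-type annotation, `lrnet`
predicts every directed *cell–ligand–receptor–cell* edge, weights it,
collapses the edges into cell-type-level summary networks, compares
condition-matched networks, and quantifies autocrine / intra-organ /
inter-organ signalling against a permutation null. It is aimed at
transcriptomics analysts who already have clustered, annotated expression
data and want the communication structure between the annotated
populations.

## The model

Expression is first normalised to counts per million (CPM) per cell and
summarised per cell type *c* and gene *g* as a mean (*mean<sub>g,c</sub>*),
a total (*sum<sub>g,c</sub>* = mean × number of cells) and a detection
fraction (share of cells with a nonzero value). A ligand *L* (or receptor
*R*) counts as expressed in a cell type when its detection fraction reaches
the detection threshold (default 20%) and its mean passes the expression
threshold. For every database pair (*L*, *R*) and every ordered cell-type
pair (*s*, *r*) — autocrine edges *s* = *r* included — with *L* expressed
in *s* and *R* expressed in *r*, three edge weights are computed:

- **mean-expression weight** = mean<sub>L,s</sub> × mean<sub>R,r</sub> —
  emphasises abundant signalling, housekeeping pairs included;
- **specificity weight** = (mean<sub>L,s</sub> / Σ<sub>c</sub>
  mean<sub>L,c</sub>) × (mean<sub>R,r</sub> / Σ<sub>c</sub>
  mean<sub>R,c</sub>) ∈ [0, 1] — equals 1 exactly when ligand and receptor
  are each expressed in a single cell type; the denominators run over *all*
  cell types in the dataset, so specificity is dataset-local;
- **total-expression weight** = sum<sub>L,s</sub> × sum<sub>R,r</sub> —
  acknowledges population abundance (500 cells at mean 10 CPM total 5000
  and outweigh 10 cells at mean 80 CPM totalling 800).

Edge tables collapse into directed cell-type × cell-type
**cell-connectivity summary networks** (rows = sender, columns = receiver;
deliberately asymmetric) under three schemes: edge count above thresholds,
summed specificity, summed expression. Two condition-matched runs can be
compared edge-by-edge (shared / condition-exclusive sets, identity being
the sender–ligand–receptor–receiver tuple) and entry-by-entry (log2 fold
change and signed difference, twofold changes flagged). Rank analyses ask
whether autocrine or intra-organ edges are more specific than expected;
the null rebuilds the network under degree-preserving shuffles of the
ligand→receptor assignment.

## Worked example

Every object is a tibble (or a small S3 object with `tidy()` / `glance()` /
`autoplot()` methods), so the analysis composes with the pipe. Here on a
seeded synthetic dataset with one planted exclusive edge CT1 → CT3:

```r
library(lrnet)

fx <- generate_fixture(fixture_config(
  n_cell_types = 4, cells_per_type = 50, n_genes = 120, n_pairs = 12,
  planted_edges = tibble::tibble(sender = "CT1", receiver = "CT3",
                                 effect_size = 10),
  seed = 1))

cpm  <- normalise_cpm(fx$expression)
prof <- summarise_cell_types(cpm, fx$annotation,
                             unique(c(fx$pairs$ligand, fx$pairs$receptor)))
edges <- extract_edges(prof, fx$pairs)

edges |>
  dplyr::arrange(dplyr::desc(specificity_weight)) |>
  dplyr::select(sender, ligand, receptor, receiver,
                mean_weight, specificity_weight) |>
  head(3)
#> # A tibble: 3 × 6
#>   sender ligand receptor receiver mean_weight specificity_weight
#>   <chr>  <chr>  <chr>    <chr>          <dbl>              <dbl>
#> 1 CT1    LG01   RC01     CT3      4809743363.             1
#> 2 CT2    LG07   RC07     CT4       128172586.             0.0973
#> 3 CT4    LG03   RC03     CT2        97226295.             0.0968
```

The planted pair tops the ranking with specificity exactly 1 (its ligand
is expressed only in CT1 and its receptor only in CT3); background pairs
expressed everywhere sit near the uniform value (1/4)² ≈ 0.06. Collapsing
to the summed-specificity summary network and reading off communities from
the top edges:

```r
net <- summed_weight_network(edges, "summed_specificity")
glance(net)
#> # A tibble: 1 × 4
#>   scheme             n_cell_types n_edges total_weight
#>   <chr>                     <int>   <int>        <dbl>
#> 1 summed_specificity            4      16           12

top_summary_edges(net, 3)
#> # A tibble: 3 × 3
#>   sender receiver weight
#>   <chr>  <chr>     <dbl>
#> 1 CT1    CT3       1.64
#> 2 CT4    CT4       0.772
#> 3 CT2    CT4       0.741

connected_communities(top_summary_edges(net, 3))
#> [[1]]
#> [1] "CT1" "CT3"
#>
#> [[2]]
#> [1] "CT2" "CT4"
```

The total summed specificity across all 16 directed entries is 12 — one
unit per database pair, since each pair's specificity components sum to 1
over cell types. `autoplot(net)` draws the directed heatmap,
`plot_network_graph(net)` and `plot_circos(net)` the graph views. For
file-based workflows, `run_extract_edges()`, `run_diff_edges()` and
`run_visualise()` read and write tab-delimited inputs/outputs (shell
wrappers with `--emFile` / `--annFile` / `--refFolder` / `--targetFolder` /
`--sourceFolder` flags live in `inst/scripts/`).

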