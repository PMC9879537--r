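# crossexpress

Cross-species comparison of gene expression profiles without sample
matching: a machine-learning **Expression Score** (ES) for interspecific
gene pairs, fractionation of orthogroups into expression-consistent
**expresso-groups**, and a grouped-sample pseudo-Euclidean distance
baseline.

## The problem

Orthology inference tells you which genes in two species share ancestry,
but not which of several co-orthologs kept the ancestral function. When
high-resolution transcriptome atlases exist for both species, expression
similarity is the natural proxy — yet classical measures (Pearson
correlation, Euclidean distance) need a one-to-one matching of samples
between species, which breaks down whenever morphologies, organs or
developmental rates differ. `crossexpress` is for comparative
transcriptomics of such unmatched atlases: model-species-to-crop
transfer, duplicate-gene fate analysis, detection of expression-diverged
orthologs.

## The method

Each species' atlas is a gene × sample read-count matrix ($K_A \times
m_A$, $K_B \times m_B$). An interspecific pair $(g_a, g_b)$ is encoded as
the concatenation of the two raw count profiles, a vector of length
$m_A + m_B$. A gradient-boosted tree classifier (XGBoost,
binary-logistic) is trained on orthopairs (positive) versus random pairs
(negative, equal size, disjoint from the positives); its probability
output is the pair's ES $\in [0,1]$, with ES $> 0.5$ read as
"orthopair-like expression".

Because single training runs inherit noise from coexpressed random pairs,
the pipeline runs many independent iterations (default 100), re-drawing
the negative set each time; the final ES is the **median** over
iterations. Training pairs themselves are scored **out of fold** via a
stratified 10-fold re-classification, so every training pair's ES comes
from a model that never saw it. Orthogroups are then cut: the complete
bipartite graph of an orthogroup, weighted by ES, loses every edge $\le
0.5$, and its connected components are the expresso-groups; genes with no
surviving edge are singletons — candidates for change of function.

## Worked example

```r
library(crossexpress)

# simulate a small two-species comparison with planted structure
sim <- simulate_species_pair(simulation_config(
  n_genes_a = 500, n_genes_b = 500, seed = 1))
sim
#> <simulated_comparison> 500 + 500 genes; 253 orthogroups; 180 orthopairs

# Expression Scores: 5 iterations of train / out-of-fold re-classify / score
es <- compute_expression_scores(sim$map_a, sim$map_b, sim$orthopairs,
                                sim$orthogroups, n_iterations = 5,
                                k = 10, base_seed = 1)
glance(es)
#> # A tibble: 1 × 6
#>   n_pairs n_training_positives n_query n_iterations     k oof_auc
#>     <int>                <int>   <int>        <dbl> <dbl>   <dbl>
#> 1     382                  180     202            5    10   0.832

head(tibble::as_tibble(es), 4)
#> # A tibble: 4 × 6
#>   gene_a  gene_b  group_id    es provenance  n_iterations
#>   <chr>   <chr>   <chr>    <dbl> <chr>              <dbl>
#> 1 A_g0001 B_g0001 <NA>     0.808 out_of_fold            5
#> 2 A_g0002 B_g0002 <NA>     0.316 out_of_fold            5
#> 3 A_g0004 B_g0006 <NA>     0.563 out_of_fold            5
#> 4 A_g0005 B_g0007 <NA>     0.901 out_of_fold            5
```

`oof_auc` is the classifier's out-of-fold ROC AUC on this run's training
pairs (0.83 here — the 500-gene toy setting; the default 2000-gene
configuration reaches ≥ 0.90). Rows with provenance `out_of_fold` are
training orthopairs (A_g0002's ES of 0.32 marks a planted
expression-diverged ortholog); `full_model` rows are the remaining
orthogroup pairs.

```r
# fractionate orthogroups into expresso-groups at ES > 0.5
fr <- fractionate_orthogroups(sim$orthogroups, es, threshold = 0.5)
summ <- summarize_patterns(fr)
summ$singletons
#> # A tibble: 1 × 3
#>   n_genes n_singletons singleton_fraction
#>     <int>        <int>              <dbl>
#> 1     619           75              0.121

retention_fractions(summ$patterns)
#> # A tibble: 2 × 2
#>   shape retained_fraction
#>   <chr>             <dbl>
#> 1 1x2               0.939
#> 2 1x3               0.875
```

12% of orthogroup genes end up as expression singletons; among 1×2 (1×3)
orthogroups, 94% (88%) of co-orthologs stay connected to their
single-copy partner.

```r
# distance baseline on the same data
pairs <- dplyr::bind_rows(
  tibble::as_tibble(sim$orthopairs)[, 1:2],
  tibble::as_tibble(sample_negative_pairs(rownames(sim$map_a$counts),
    rownames(sim$map_b$counts), sim$orthopairs, seed = 2)))
d <- pseudo_euclidean(pairs, sim$map_a, sim$map_b,
                      synthetic_sample_matching(sim), repeats = 100, seed = 3)
labels <- rep(c(1, 0), each = nrow(sim$orthopairs))
roc_auc(baseline_scores(d)$score, labels)$auc
#> [1] 0.8171914
```

The grouped-sample pseudo-Euclidean baseline separates orthopairs from
random pairs (AUC 0.82 here) but stays below the classifier — the
ordering the package's acceptance checks enforce at full scale.

## Command line

A thin shell entry point wraps the same functions:

```sh
CX=$(Rscript -e 'cat(system.file("exec", "crossexpress", package = "crossexpress"))')
$CX simulate --out sim --seed 1
$CX score --map-a sim/map_a.tsv --map-b sim/map_b.tsv \
    --orthopairs sim/orthopairs.tsv --orthogroups sim/orthogroups.tsv \
    --fast --seed 1 --out es
$CX fractionate --es es/es.tsv --orthogroups sim/orthogroups.tsv --out fr
```

Every run directory gets a `manifest.json` with the options, seeds and
package version needed to replay it.

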