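# ectg

Detection of protein functional modules (complexes) in protein–protein
interaction (PPI) networks by combining network topology with gene
coexpression, for researchers in systems biology who have an interaction
network and matched expression time courses and want candidate complexes
plus the standard benchmark and enrichment read-outs.

## The method

Raw PPI networks are noisy: edges are missing, spurious, and unweighted.
The idea implemented here is to *re-weight* every interaction with two
independent lines of evidence before clustering.

**Topology.** For an edge (u, v), let `C_u` be the local clustering factor
of `u` (the fraction of `u`'s neighbour pairs that interact) and `T(u,v)` a
shared-neighbour coefficient, `min(1, (|N(u) ∩ N(v)| + 1) / min(k_u, k_v))`
(the +1 credits the direct link). These blend into a pairwise topological
coefficient

    PTC(u,v) = α · (C_u + C_v)/2 + (1 − α) · T(u,v),   α ∈ [0, 1]

**Coexpression.** The Jackknife coexpression correlation of expression
profiles `u, v` over `n` conditions is

    GEC(u,v) = min over j of r_pearson(u^(j), v^(j)),  j = 1..n

where `u^(j)` drops condition `j`. Taking the minimum over leave-one-out
correlations makes the score robust to a single shared outlier condition
that would inflate a plain Pearson correlation.

**Reconstruction.** Each edge gets `ω(u,v) = PTC(u,v) · GEC(u,v)` (negative
GEC clamped to 0 by default) and each node `ω(u) = Σ ω(u,v)` over its
incident edges.

**Detection.** Repeatedly: pick the heaviest edge whose endpoints are not
yet in any module; grow a module from its endpoints breadth first,
absorbing every neighbour connected to a member by an edge with
`ω ≥ λ`, until a sweep adds nothing; mark the members consumed. Then drop
modules smaller than `min_size` (default 3) and, in creation order, any
module whose Jaccard overlap with an earlier retained module exceeds
`OvMax`. The procedure is fully deterministic (lexicographic tie-breaks).

**Evaluation.** Against a reference catalog, a prediction hits a known
complex when the neighbourhood affinity `|A ∩ B|² / (|A|·|B|)` reaches the
matching threshold (default 0.2); the package reports precision, recall,
F-measure and the benchmark-protein coverage rate, plus hypergeometric
functional enrichment (best P per module, computed in log space).

## Worked example

Everything below is computed on a synthetic benchmark generated by the
package itself: 5 planted modules of 6–10 proteins among 100 background
proteins (intra-module edge probability 0.9, background 0.02), with
28-point expression time courses shared within modules (noise sd 0.2).

```r
library(ectg)
truth <- planted_truth(n_modules = 5, size_range = c(6, 10),
                       n_background = 100, p_in = 0.9, p_out = 0.02, seed = 42)
ppi  <- generate_network(truth)
expr <- generate_expression(truth, n_conditions = 28, noise_sd = 0.2)

fit <- ectg(ppi, expr, alpha = 0.8, lambda = 0.5, ov_max = 0.8)
fit
#> Protein functional module detection (topology x coexpression)
#> Call: ectg(ppi = ppi, expr = expr, alpha = 0.8, lambda = 0.5, ov_max = 0.8)
#> Parameters: alpha = 0.8, lambda = 0.5, ov_max = 0.8, min_size = 3
#> Network: 128 nodes, 299 weighted edges
#> Modules: 3 (sizes 3-10, median 5)

evaluate_modules(fit, truth_as_catalog(truth), match_threshold = 0.2)
#> Benchmark evaluation (affinity matching, threshold 0.2)
#>   predictions: 3, reference complexes: 5
#>   CR = 0.514  precision = 1.000  recall = 0.600  F = 0.750
```

Three of the five planted complexes are recovered exactly (precision 1,
recall 0.6); the benchmark coverage rate CR says 51% of the planted
proteins appear in some prediction. The expansion gate `λ` is the
sensitivity dial — sweeping it shows the trade-off:

```r
parameter_sweep(ppi, expr, truth_as_catalog(truth),
                alpha = 0.8, lambda = seq(0.2, 0.8, by = 0.1), ov_max = 0.8)
#>   alpha lambda ov_max n_modules fmeasure recall precision coverage
#> 1   0.8    0.2    0.8         5    1.000    1.0         1    1.000
#> 2   0.8    0.3    0.8         5    1.000    1.0         1    0.971
#> 3   0.8    0.4    0.8         4    0.889    0.8         1    0.771
#> 4   0.8    0.5    0.8         3    0.750    0.6         1    0.514
#> 5   0.8    0.6    0.8         1    0.333    0.2         1    0.229
#> 6   0.8    0.7    0.8         1    0.333    0.2         1    0.114
#> 7   0.8    0.8    0.8         0    0.000    0.0         0    0.000
```

Enrichment against the planted annotation map (each planted module is one
term) confirms the detected modules are functionally coherent:

```r
enrichment_summary(fit, truth_as_annotations(truth))
#> Functional enrichment over 3 module(s), background 135 proteins
#>   mean -log10(best P) = 8.81
#>   % of modules with best P below threshold:
#>     < 1e-15 : 0.00%
#>     < 1e-10 : 33.33%
#>     < 1e-05 : 66.67%
#>     < 1e-02 : 100.00%
```

And the robustness property that motivates the Jackknife correlation, on a
pair whose agreement is driven by one shared outlier:

```r
u <- c(1, 2, 3, 4, 100); v <- c(1, 2, 3, 4, 5)
pearson_cor(u, v)    #> 0.7249994   (inflated by the shared extreme)
jackknife_gec(u, v)  #> 0.7016156   (minimum leave-one-out Pearson)
```

## Command line

`scripts/ectg.R` wraps the package for shell use:

```sh
Rscript scripts/ectg.R simulate --modules 5 --sizes 6-10 --background 100 \
        --p-in 0.9 --p-out 0.02 --conditions 28 --noise 0.2 --seed 7 --out-prefix bench
Rscript scripts/ectg.R run --ppi bench_ppi.tsv --expr bench_expr.tsv \
        --ref bench_truth.tsv --alpha 0.8 --lam 0.5 --ovmax 0.8 --out results
Rscript scripts/ectg.R sweep --ppi bench_ppi.tsv --expr bench_expr.tsv --ref bench_truth.tsv
```

All formats are plain TSV: two-column edge lists, gene-by-condition
expression matrices, one complex per line catalogs, and
`term <tab> protein [<tab> domain]` annotation maps.

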