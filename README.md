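# lncoex

Guilt-by-association inference for long non-coding RNAs (lncRNAs) from bulk
RNA-seq co-expression.

Most lncRNAs have no experimentally characterized function. Because genes
that act together are transcribed together, a gene of unknown function can be
profiled by the company it keeps: its correlation with well-annotated genes
across thousands of expression samples. `lncoex` implements that programme as
a small, fully testable engine for anyone who has a gene × sample counts
matrix and gene-set libraries, with lncRNA biology (subcellular localization,
cis/trans action, perturbation response) as the motivating use case.

## The statistics at the core

**Prevalence-filtered correlation matrix.** Counts are log2(x+1)-transformed
and quantile-normalized across samples, then all pairwise Pearson
correlation coefficients (PCCs) r_ij are computed — but only for pairs where
at least one gene is expressed (normalized value > 0) in at least a fraction
θ of samples (default θ = 0.3); otherwise r_ij is set to exactly 0. This
suppresses the spuriously perfect correlations that genes detected in a
handful of samples would otherwise show.

**Mean-PCC gene-set association.** For a query gene g and a gene set T, the
association statistic is the mean correlation
μ(g,T) = mean over t in T of r(g,t) (the query excluded from T). Its
significance is judged against the term's own null: μ(·,T) is computed for
every background gene, and z = (μ(g,T) − mean) / SD (sample SD, n−1) is
converted to right- and left-tailed normal p-values. Each term has its own
null mean and SD, which corrects for set size and composition.

**Rank-weighted localization scores.** For each query, all genes are ranked
by r with the query and ranks scaled to [0,1]; scaled ranks are multiplied
by measured cytoplasm/nucleus relative concentration indices (CN RCI,
log-scale; positive = cytoplasmic) where available and summed. Per cell
line, the sums over all queries are min-max normalized and shifted to
[−0.5, 0.5]. AUROC against measured RCIs beyond ±1 validates each cell line.

Around these sit a deterministic hub-pruned network builder (top-100
correlates, 3-edges-per-node initialization, weight < 0.3 cut, hubs with
> 10 edges pruned until average degree < 3, the seed's top 5 edges always
kept), cis/trans classification of top correlates by shared chromosome,
up/down perturbation-signature prioritization with ranking inversion,
text-search sample labeling with per-group expression summaries, and Fisher
/ AUROC benchmarking utilities. A synthetic-data generator plants
co-expression modules, matching gene-set terms, and nuclear/cytoplasmic RCI
structure so that every claim above is verifiable without external corpora.

## Worked example

```r
library(lncoex)

cfg <- synthetic_config(random_seed = 7)   # 500 genes x 200 samples, 5 planted modules
sim <- generate_counts(cfg)
fit <- coexpression(sim$counts, theta = 0.3)
print(fit)
#> coexpression fit: 500 genes, 200 samples, theta = 0.3
#>   genes passing prevalence: 500 (100.0%)

query <- sim$truth$gene_id[sim$truth$module == 1][1]
lib <- generate_library(sim$truth, n_background_terms = 10, seed = 7)
head(predict(fit, query, lib), 3)
#>              term   mean_pcc        z      p_right    p_left neg_log10_p_right n_genes_used degenerate
#> 1 module1_planted 0.86907275 4.445699 4.380336e-06 0.9999956          5.358493           19      FALSE
#> 2   background007 0.06664209 2.524245 5.797357e-03 0.9942026          2.236770           20      FALSE
#> 3   background006 0.06710167 1.903027 2.851853e-02 0.9714815          1.544873           20      FALSE
```

The planted term — the query's true co-expression module — tops the ranking
with mean PCC 0.87 and a right-tailed p of 4.4e-06, four orders of magnitude
beyond the best random term: the guilt-by-association signal the engine is
built to detect.

```r
net <- build_network(fit, query)
print(net)
#> coex_network: 101 nodes, 55 edges (avg degree 1.09), seed GENE0001

rci <- generate_rci(sim$truth, cfg)
queries <- sim$truth$gene_id[sim$truth$module %in% 1:2]
pred <- predict_localization(fit, rci, queries)
evaluate_localization(pred, rci)[, 1:4]
#>    cell_line auroc n_pos n_neg
#> 1 CELLLINE01     1    17    20
#> 2 CELLLINE02     1    19    18
#> 3 CELLLINE03     1    16    16
#> 4 CELLLINE04     1    17    17
#> 5 CELLLINE05     1    17    20

am <- assign_modes(fit, truth_annotation(sim$truth), query, k = 100)
#> cis 8% / trans 92% of 100 partners
```

The pruned network respects the average-degree contract; localization AUROC
is 1.0 in every cell line on the planted structure (genes drawn on 10
chromosomes at random give the ~8%/92% cis/trans split expected by chance).

## Command line

Every stage is also a subcommand of the installed Rscript front end:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lncoex.R", package = "lncoex"))')
Rscript $CLI simulate --config cfg.json --out sim/
Rscript $CLI corr --counts sim/counts.tsv --theta 0.3 --out corr.tsv
Rscript $CLI predict --corr corr.tsv --gmt sim/library.gmt --query GENE0001 --out scores.tsv
```

Subcommands: `simulate`, `corr`, `predict`, `network`, `localize`,
`cistrans`, `perturb`, `label`, `tissue-stats`, `benchmark-overlap`,
`benchmark-disease`. Each run writes a `.manifest.json` with parameters and
input checksums; identical inputs and seed give byte-identical outputs.

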