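# cernet

Cross-species co-differential expression and competing-endogenous-RNA
(ceRNA) network inference, with a planted-truth simulator for end-to-end
validation.

## What problem this solves, and for whom

Comparative transcriptome studies of high-altitude adaptation contrast a
low-altitude cattle reference (LAC) against high-altitude cattle (HAC)
and yak (LWQY), across four RNA classes: mRNA, lncRNA, miRNA and
circRNA. Transcripts that respond in *both* comparisons
("co-differentially expressed") are intersected on cattle gene
identifiers — one cattle id may correspond to several yak ids — and a
ceRNA network is then assembled: transcripts sharing significantly many
repressing miRNAs, anticorrelated with those miRNAs and co-expressed
with each other, are candidate competitors for the same miRNA pool.

`cernet` is for bioinformaticians who want that analytical core as
tested, reusable R functions rather than a one-off script stack: the
class-specific differential-expression filters, the ortholog projection
and intersection, the positional lncRNA rules, the hypergeometric
sponge test, enrichment, and reporting — plus a synthetic-data generator
that plants known differential transcripts and ceRNA triplets so every
stage can be scored against ground truth.

## The statistics at the core

**Differential calling** (per comparison, per RNA class): Welch t-test
on log2(TPM + 1) with fold change log2((x̄_b + 1)/(x̄_a + 1));
mRNA/lncRNA are called at BH FDR < 0.05 and |log2FC| ≥ 1, miRNA/circRNA
at raw p < 0.05 and |log2FC| ≥ 1.

**Sponge test**: for a candidate partner pair (A, B) with regulator
miRNA sets C and D inside a universe of U miRNAs, with M = |C|,
N = |D| and x = |C ∩ D| shared regulators,

    p = P(X ≥ x) = Σ_{k=x}^{min(M,N)} C(M,k) · C(U−M, N−k) / C(U,N)

A pair enters the network iff both partners are co-differential, their
Pearson correlation (log2 scale) exceeds 0.9, they are retained targets
(Spearman < −0.7 with the miRNA, both ends differential) of ≥ 1 common
miRNA, and the sponge p is below 0.05. The same hypergeometric upper
tail drives the one-sided Fisher enrichment test.

See `vignettes/cerna-inference.Rmd` for the full model, the generative
model of the simulator, and every numerical choice.

## Worked example

```r
library(cernet)
res <- run_pipeline(sim_config(seed = 42))
print(res)
```

```
== pipeline report ==
-- differential expression --
mRNA_LAC-vs-HAC	total 41	up 23	down 18
lncRNA_LAC-vs-HAC	total 13	up 8	down 5
miRNA_LAC-vs-HAC	total 24	up 0	down 24
circRNA_LAC-vs-HAC	total 13	up 6	down 7
-- co-differential --
mRNA	co-DE 37	up 21	down 16	conflicts 0	venn 4/37/1
lncRNA	co-DE 12	up 8	down 4	conflicts 0	venn 1/12/0
miRNA	co-DE 24	up 0	down 24	conflicts 0	venn 0/24/0
circRNA	co-DE 13	up 6	down 7	conflicts 0	venn 0/13/0
-- ceRNA network --
nodes 29	edges 37	ceRNA pairs 7	miRNA-target edges 30
nodes[circRNA] 3
nodes[lncRNA] 4
nodes[miRNA] 15
nodes[mRNA] 7
-- enrichment --
significant terms 1 of 11
ALTITUDE_RESPONSE	k=37 K=45 p=6.68e-40
triplet precision 1.00 recall 0.88 | co-DE recall 0.91
```

Reading it: the simulator planted ~15% differential transcripts per
class plus 8 ceRNA triplets. The first block tallies differential calls
in the cattle LAC-vs-HAC comparison; the co-differential block
intersects them with the (ortholog-projected) LAC-vs-LWQY comparison —
the Venn triple is only-in-comparison-1 / shared / only-in-comparison-2,
and `conflicts` counts ids excluded for direction disagreement. The
network block reports the assembled ceRNA graph (each accepted pair
carries its supporting miRNA–target edges), enrichment recovers the
planted altitude-response gene set, and the last line scores the run
against the planted truth: all 7 recovered pairs are real (precision
1.00) and 7 of the 8 planted triplets were found (recall 0.88).

Individual sponge-test rows are available in `res$network$sponge`
(x, M, N, U, p, PCC per tested pair); `extract_subnetwork(res$network,
seeds, radius = 2)` pulls seed-centred neighbourhoods, and `write_sif()`
/ `write_node_attributes()` export for Cytoscape-style viewers.

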