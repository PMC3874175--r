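# intronTF

Gene-centered analysis of transcription factor (TF) binding to **first
introns** in nematode genomes, for regulatory genomicists who want to ask
whether the intron nearest the start codon behaves like a second
promoter-scale regulatory region — and whether its TF complement is
redundant with, or complementary to, the promoter's.

The package implements, as tested reusable components:

* **Gene models and fragments** — GFF3/FASTA parsing, classification of
  *conventional genes* (no 5'-UTR intron, unique first coding exon, not
  operon-downstream), promoter definition (start codon to ≤ 2 kb
  upstream, truncated at neighbours), and strand-aware exon/intron
  fragment extraction numbered 5'→3'.
* **Orthology and length conservation** — translated (3×3-frame,
  BLOSUM62) local alignment of coding exons, identical
  exon–intron-structure calls, and the intron length-conservation ratio
  max(l_A, l_B)/min(l_A, l_B) compared between first and other introns
  (Mann–Whitney U), with a random-pair null.
* **Energy-based motif scanning** — PWM → energy matrix
  ε_i(b) = ln(max_b' f_i(b')/f_i(b)), window energy E = Σ ε, occupancy
  1/(1+e^{E−μ}), sites called at occupancy ≥ 0.09 (≡ E ≤ 2.31 kT), and
  conserved predicted TF interactions between orthologous fragments.
* **ChIP assignment** — peak midpoints (`floor((start+end)/2)`) assigned
  to containing fragments, distinct-TF counts per region class,
  length–binding correlations, and the per-gene overlap/intron fraction
  O/I = |promoter ∩ intron| / |intron|.
* **PDI networks** — Jaccard PDI similarity (promoter / intron /
  combined-pooled modes), co-expression enrichment across similarity
  bins (2×2 Fisher primary, 2×3 Freeman–Halton alongside), genome
  projection by first-intron length bins, and hypergeometric + BH gene
  family enrichment.
* **In-degree models** — exponential MLE λ̂ = n/Σx per region and the
  hypo-exponential model f(x) = λ1λ2/(λ2−λ1)(e^{−λ1x} − e^{−λ2x}) for
  the promoter + first-intron sum, compared by discretised
  log-likelihood and KS distance.
* **Synthetic data generator** — a deterministic two-species genome /
  peak / network / co-expression simulator with ground truth, so the
  whole pipeline runs and validates with no external data.

See `vignettes/first-intron-tf-binding.Rmd` for the full methods
account.

## Worked example

```r
library(intronTF)

## simulate a 200-gene two-species genome pair and run the pipeline
cfg <- pipeline_config(out_dir = "introntf_out", seed = 7,
                       sim = sim_config(n_genes = 200))
res <- run_pipeline(cfg)

mean(res$conventional$is_conventional)
#> [1] 0.805

res$conservation$summary[c("median_first", "median_other", "p_value")]
#> $median_first
#> [1] 1.136948
#> $median_other
#> [1] 1.806952
#> $p_value
#> [1] 7.190438e-07

res$chip$summary$first_vs_other_ratio
#> [1] 1.486943

res$degree$winner
#> [1] "hypoexponential"
```

Reading the numbers: roughly 80% of this draw's simulated genes are
*conventional* and enter the analysis (the generator's expected fraction
is 76%); orthologous first introns have a
markedly lower length ratio (closer to 1, i.e. more length-conserved)
than other introns, and the Mann–Whitney p-value rejects equality;
first introns carry more distinct ChIP-bound TFs than other introns
(planted contrast recovered); and the combined promoter + first-intron
in-degree is better described by the hypo-exponential than by a single
exponential — the signature of two roughly independent interaction
pools per gene.

The same stages run on real inputs by passing file paths instead of
`simulate = TRUE` (see `?pipeline_config`), or from the shell via
`inst/scripts/first_intron_pipeline.R`.

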