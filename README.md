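# tctargets

Time-resolved classification of treatment-responsive genes in two-arm
bulk RNA-seq time courses.

Primary cells stimulated ex vivo superimpose two transcriptional programs:
the response to the stimulus and the response to isolation and culture that
unfolds in the solvent-control arm as well. Given a gene × sample count
matrix from a 4/8/24/48 h, treated-vs-control, replicated design, the
package produces a classified catalogue of responder genes:

* **per-time-point differential expression** against a fold-change
  threshold (TREAT-style Wald test on negative-binomial group rates with
  Cox–Reid common + shrunken tagwise dispersions): FC > 1.5 at 4/8 h,
  FC > 2 at 24/48 h, BH FDR < 0.05 per time point, plus an expression
  floor (summed per-time-point mean CPM > 25);
* **timing**: *primary* targets significant within the first 8 h,
  *secondary* targets later only;
* **direction/profile**: up, down or mixed at FC > 1.5 across time points;
  persistent, transient or discontinuous fold-change profiles;
* **mechanism**: k-means clustering (Hartigan–Wong, k = 4, 25 restarts) of
  z-scored condition-mean trajectories, each cluster auto-labelled
  *direct* (treated arm moves, control flat) or *indirect* (control arm
  drifts, treatment stabilizes), with two-sided Fisher contingency tests
  between the classification axes;
* **enrichment**: per-term one-sided Fisher over a GMT collection with the
  down:up > 2 direction rule and a minimum overlap of 5;
* **colocalization**: nearest persistent binding-site peak per gene within
  a TAD-scale window (default 1 Mb), BED in/out.

For the per-time-point test at threshold $\tau$ the p-value against the
composite null $|\log_2 FC| \le \log_2\tau$ is

```
p = min(1, P(Z > (|b| - log2 tau)/se) + P(Z > (|b| + log2 tau)/se)),
se^2 = (1/I_T + 1/I_C)/ln(2)^2,   I = sum_i mu_i/(1 + phi mu_i)
```

so that p = 1 exactly at b = 0 and the ordinary two-sided Wald test is
recovered at tau = 1.

Because catalogues of this kind derive from deep sequencing data, the
package ships a negative-binomial simulator with planted trajectory
archetypes (direct up/down, culture drift stabilized by treatment,
transient, discontinuous, mixed, null) and a per-gene truth table used as
the recovery oracle throughout the tests.

## Worked example

```r
library(tctargets)
res <- run_pipeline(list(simulate = TRUE, n_genes = 12000, seed = 1))
print(res)
```

```
pipeline_result: 456 targets from 11648 genes
 n_targets n_primary n_secondary n_up n_down n_mixed n_persistent n_transient
       456       256         200  208    171      77          391          45
 n_discontinuous n_direct n_indirect
              20      230        226
```

Of 12,000 simulated genes, 11,648 pass the expression filter and 456 are
called targets at the study thresholds (the simulation plants 1,164
responders, many with effects below or near the tested fold-change
thresholds — calling is conservative and, here, yields no false targets).
Among targets, 256 responded within 8 h (primary) and 200 later
(secondary); 208 are up-, 171 down-regulated and 77 change sign over time;
trajectory clustering splits them into 230 treatment-driven (direct) and
226 culture-driven (indirect) genes. The per-time-point summary mirrors
the time course of the response:

```
 time_h n_significant   pct_up pct_down
      4           116 83.62069 16.37931
      8           237 66.24473 33.75527
     24           197 39.08629 60.91371
     48           304 50.00000 50.00000
```

The same run, stage by stage with commentary and truth-recovery
scorecards, is available as numbered drivers:

```sh
Rscript analysis/01_simulate.R          # plant the 12,000-gene study
Rscript analysis/02_normalize_qc.R      # filter, TMM, CPM, MDS distances
Rscript analysis/03_differential_expression.R
Rscript analysis/04_classify_targets.R  # timing/direction/profile + Venn
Rscript analysis/05_cluster_trajectories.R  # k-means, direct/indirect, Fisher
Rscript analysis/06_enrichment.R        # synthetic gene sets, direction calls
Rscript analysis/07_binding_site_coloc.R    # synthetic loci/peaks, 1 Mb window
Rscript analysis/08_summary.R           # one-call pipeline + scorecard
```

All tables land under `results/`. The gene sets, loci and peaks used by
scripts 06–07 are synthetic and labelled as such: simulated genes have no
real annotation or coordinates.

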