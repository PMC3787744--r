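# siteplast

Quantifying the plasticity of functional-site locations across protein
domain superfamilies.

## The problem

Transferring functional annotations between homologues assumes that
related domains keep their functional sites — catalytic residues, and
binding sites for proteins, nucleic acids and small ligands — at
equivalent spatial positions. In large, diverse superfamilies that
assumption can fail badly: different relatives exploit different parts of
the shared fold, especially for protein–protein interfaces. siteplast
implements the measurement that makes this quantitative. For each
superfamily it selects a structurally central **representative** (the
domain with the highest cumulative structural-similarity score to the
other 60%-sequence-identity cluster representatives), structurally aligns
every member to it, and projects each member's annotated site residues
onto the representative positions they align with (residues aligned to
gaps are ignored). From the resulting per-position contributor sets it
computes:

* **coverage** — |positions with ≥ 1 contributing member| / representative
  length, per site type, with two confounder filters (representatives
  < 100 residues; any single domain covering > 50% by itself);
* **preferential colocation** — max over positions of the fraction of s60
  clusters with a site there (denominator: clusters possessing data of
  that type; included only with ≥ 10 such clusters);
* **structural diversity** — clusters at a normalised-RMSD cutoff
  (RMSD × larger length / aligned pairs; single linkage; diverse ⇔ ≥ 2
  clusters at 9.0 Å) and the one-sided rank-sum comparison of coverage in
  diverse vs similar superfamilies;
* **conservation enrichment** — Valdar-style conservation scores of
  functional-family alignments (threshold 0.7, optional removal of
  fragments < 80% of mean length), projection of conserved columns as a
  site type, and the enrichment E = Pc − Pa with its rank-sum test.

A seeded synthetic-superfamily generator with planted ground truth
(preferred site footprints used by a controlled fraction of subfamilies,
scattered subfamily-specific sites, hinge-planted structural diversity,
sequence divergence, inserted embellishments) backs every statistic with
end-to-end recovery tests. See the methods vignette
(`vignettes/siteplast-methods.Rmd`) for the model, parameters and design
choices.

## Worked example

```r
library(siteplast)

# a synthetic superfamily under the standard study condition:
# 12 s60 clusters x 2 members, 120-residue template, an interface
# footprint planted in 80% of clusters plus scattered cluster sites
sim <- make_superfamily(synth_config(), seed = 11, superfamily_id = "SF001")
sim
#> SyntheticSuperfamily SF001 - 24 domains in 12 clusters; 72 annotations; single-conformation

s60 <- cluster_s60(sim$domains)      # recovers the planted 12 subfamilies
s60
#> ClusterSet (s60): 12 clusters over 24 domains (parameter 0.6)

an <- analyse_superfamily(sim$domains, sim$annotations, run_config(), s60)
an$coverages$protein_protein
#> CoverageResult SF001 / protein_protein: 0.367
an$colocations$protein_protein
#> ColocationResult SF001 / protein_protein: max_fraction 0.833 over 12 clusters with data
an$diversity$cutoff_9
#> ClusterSet (structural): 1 clusters over 24 domains (parameter 9)

sim$truth$footprint_fraction[["protein_protein"]]
#> [1] 0.3583333
```

Reading the numbers: interface coverage of the representative is 0.367,
within a position or two of the planted union footprint (0.358 of the
template); the colocation statistic is 10/12 = 0.833, recovering the
planted preferred-site fraction of 0.8; and without a planted hinge the
superfamily forms a single structural cluster at 9 Å (not structurally
diverse). `run_all()` runs the same stages over many superfamilies from
files on disk and writes summary TSVs plus an exclusion ledger;
`inst/scripts/siteplast.R` wraps `simulate` and `run-all` for the shell.

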