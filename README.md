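# gokuphage

Discovery, excision and integration modelling of *dif*-flanked
gokushovirus prophages.

## The problem

Gokushoviruses (Microviridae, subfamily *Gokushovirinae*) are small
circular ssDNA phages that are ubiquitous in metagenomes yet encode no
integrase — so they were long assumed to be strictly lytic. Integrated
gokushovirus prophages in enterobacterial chromosomes tell a different
story: the phages co-opt the host's chromosome-dimer resolution system.
The chromosomal **dif site** — 28 bp comprising an 11-bp XerC-binding arm,
a 6-bp central spacer and an 11-bp XerD-binding arm — is recombined by the
host tyrosine recombinases XerC/XerD, and a phage genome carrying its own
*dif*-like motif is integrated there passively.

The genomic signature is sharp, and `gokuphage` turns it into a tested
pipeline for anyone mining bacterial genomes or phage MAGs for this
lifestyle:

- a prophage inserts immediately **downstream of the bacterial dif**,
  which stays intact (at most one mismatch from the canonical
  `GGTGCGCATAATGTATATTATGTTAAAT`);
- the **downstream boundary is the phage's own dif**: conserved XerC arm,
  divergent spacer and XerD arm;
- the excised circular replicative form carries the phage dif exactly
  once and the bacterial dif not at all;
- integration requires active XerC **and** XerD and an intact two-arm
  phage motif — knocking out either recombinase or either arm abolishes
  lysogeny.

## What the package provides

| Area | Functions |
|---|---|
| Sequence/interval model, FASTA/GFF3/BED I/O | `seq_record()`, `read_fasta()`, `write_outputs()`, `circular_slice()`, `canonical_rotation()` |
| dif grammar and classification | `dif_grammar()`, `classify_dif()`, `find_dif_sites()` |
| Prophage mining and excision | `find_capsid_loci()`, `find_flanking_repeats()`, `call_prophage()`, `excise()`, `mine()` |
| Integration model | `integrate_phage()`, `host_state()`, `apply_complementation()`, `delete_dif_arm()` |
| PWM motif scanning of MAGs | `build_pwm()`, `scan_pwm()`, `pwm_threshold()`, `filter_hits()`, `iterative_search()` |
| ORF calling and coding context | `find_orfs()`, `assign_roles()`, `coding_context()` |
| Comparative assays | `pairwise_ani()`, `ani_matrix()`, `cluster_clades()`, `identity_profile()`, `insilico_pcr()`, `genotype_bands()` |
| Synthetic data with ground truth | `sim_config()`, `make_host()`, `make_phage()`, `plant_integration()`, `make_mag_set()`, `verify_truth()` |

Results are tibbles throughout; fitted/model objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Simulate a lysogen, mine it back, and excise the replicative form:

```r
library(gokuphage)

cfg   <- sim_config(seed = 42, host_len = 15000)
host  <- make_host(cfg)
phage <- make_phage(cfg)
truth <- plant_integration(host$record, phage$record,
                           gokuphage:::merge_truth(host$truth, phage$truth))

calls <- mine(truth$record, vp_reference_proteins()[["VP1"]])
calls[, c("host_id", "start", "end", "length",
          "upstream_class", "downstream_class")]
#> # A tibble: 1 × 6
#>   host_id  start   end length upstream_class downstream_class
#>   <chr>    <int> <int>  <int> <chr>          <chr>
#> 1 host_s42  6942 11171   4230 bacterial_like phage_like
```

The call spans 4230 bp starting one base after the bacterial dif
(`bacterial_like` upstream boundary, ≤1 mismatch from canonical) and
ending at the last base of the phage dif (`phage_like`: intact XerC arm,
divergent spacer/XerD arm) — exactly the planted interval recorded in
`truth$truth$prophages`. Excising returns the circular phage and the
restored host, conserving length:

```r
out <- excise(truth$record, calls[1, ])
nchar(out$phage$seq)          # 4230 — the replicative form
find_dif_sites(out$phage, max_mm = 1)   # 0 rows: no bacterial dif on board
```

The integration model reproduces the lysogeny requirements directly:

```r
site <- phage$truth$dif_sites
integrate_phage(host$record, phage$record, host_state(),
                phage_dif = site)$integrated
#> TRUE
integrate_phage(host$record, phage$record,
                host_state(xerD_active = FALSE), phage_dif = site)$reason
#> "xerD inactive"
dC <- delete_dif_arm(phage$record, site, "C")
integrate_phage(host$record, dC$record, host_state(),
                phage_dif = dC$dif_site)$reason
#> "phage dif not phage_like (partial_C_missing)"
```

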