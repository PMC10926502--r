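# haplodx

Lineage delimitation from DNA barcodes and diagnostic real-time PCR assay
design, in one tested pipeline.

Invasive-insect diagnostics often hinges on two questions: *is the
intercepted specimen the regulated lineage?* and *can a lab answer that in
hours with a TaqMan assay instead of days with sequencing?* `haplodx`
covers the full path between them:

1. **Delimit** — trim a barcode alignment (CO1/ITS2-style) to its
   overlapping core, collapse identical sequences into haplotypes, build
   Tamura–Nei (TN93) distances and neighbor-joining trees with
   delete-half jackknife support, and connect haplotypes into a
   statistical-parsimony network whose step paths quantify how far apart
   putative lineages sit.
2. **Design** — scan the alignment for windows dense in fixed differences
   between the target lineage and everything else, enumerate TaqMan
   primer/probe candidates under nearest-neighbor (and salt-adjusted GC)
   melting-temperature models with structure screens, rank complete
   forward/probe/reverse sets by discriminative power, and design a
   Tm-capped control assay on a conserved companion locus.
3. **Verify** — screen every assay in silico against the full sequence
   panel (3'-anchored primer matching, IUPAC-aware), and interpret qPCR
   runs with a four-way call (positive / negative / anomalous / failed)
   built on end-RFU thresholds, a Cq window, and delta-Cq confirmation,
   plus dilution-series standard curves with amplification efficiency.

Every stage is exercised by seeded synthetic generators that plant a known
haplotype structure (a star-shaped main haplogroup with a clustered
"stem" of lineage-specific sites, a conspecific outlier, congeners, an
outgroup), so the expected network metrics and design outcomes are known
by construction and asserted exactly in the test suite.

## Worked example

```r
library(haplodx)

out <- run_pipeline(seed = 1)

# planted population structure, recovered from sequence alone:
out$metrics$separation["main", "outlier"]   # 20 mutational steps
out$metrics$subgroups                       # main: 14 haplotypes,
                                            # diameter 3, 14 variable sites

# best-ranked diagnostic assay (coordinates in trimmed alignment):
out$assay[1, c("fwd_sequence", "probe_sequence", "rev_sequence")]

# in-silico specificity: every main-group sample amplifies, no
# nontarget/outgroup sample does
table(out$specificity$predicted_amplification)

# a simulated 118-sample qPCR run classifies back to its planted truth:
out$summary$call_tally                      # 110 positive, 4 anomalous,
                                            # 3 negative, 1 failed
```

Single pieces work standalone, e.g. the published-value melting
temperatures and a standard curve:

```r
tm_salt_adjusted("GGGTCGATGAAGAACGCAGC")    # 62.5 C
sc <- fit_standard_curve(data.frame(conc = 10^(2:-2),
                                    cq = 35 - log10(2)^-1 * log10(10^(2:-2))))
sc$efficiency                               # exactly 1 (100%)
```

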