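# cdur — cytidine deaminase under-representation reporter

`cdur` asks, for a protein-coding nucleotide sequence, whether the mutation
motifs of the AID/APOBEC cytidine deaminases (WRC for AID, TC for most
APOBEC3s, CCC for APOBEC3G, the SYC coldspot, CpG) are **under- or
over-represented** relative to what the sequence could have looked like
with the same protein. It is aimed at virologists and molecular
evolutionists studying deaminase-driven selection — e.g. whether a viral
gene exposed to APOBEC3 has purged the motifs the enzyme attacks, or
specifically the occurrences where deamination would change the protein.

## The method

For a subject CDS $S$ and a motif $X$, three observables are measured on
both strands:

* $a$ = motif occurrence count (`observedX`),
* $b$ = replacement transitions: occurrences where the canonical
  deamination outcome — C>T at the target cytidine, G>A when projected from
  the bottom strand — is nonsynonymous (`repTr_observedX`),
* $b/a$ = the replacement-transition fraction (`repTrFrac_observedX`).

A null distribution is built from $r$ synonymous shuffles of $S$ (default
$r = 1000$). Each shuffle keeps codon positions 1–2 — hence the protein —
and resamples third positions under one of three schemes:

| method | third positions are… | corrects for |
|---|---|---|
| `gc3`  | drawn with G/C mass equal to the subject's third-position GC fraction $g$ | GC3 content |
| `n3`   | permuted within degeneracy classes (R, Y, H, N), without replacement | base composition, conserved **exactly** |
| `dn23` | drawn ∝ the subject's positions-2–3 dinucleotide frequencies | dinucleotide / codon bias |

The reported `belowX` is the fraction of null replicates strictly below the
observation — an empirical lower-tail p-value. `belowX < q` (0.05) flags
under-representation, `belowX > 1 − q` over-representation. For every motif
pair the replicate vectors are correlated and a bivariate-normal
approximation yields conditional p-values (`pXcondY`): depletion of X
beyond what its coupling to a confounding motif Y explains.

## Worked example

Plant a depletion and detect it — a positive control in three lines:

```r
library(cdur)
subject  <- random_cds(200, gc3 = 0.45, seed = 7, id = "demo")
depleted <- deplete_motif(subject, motif_spec("TAC"), strength = 1)
rpt <- cdur_report(depleted, method = "gc3", r = 1000, seed = 7,
                   motifs = list(motif_spec("TAC"), motif_spec("WRC")))
rpt
#> CDUR report for 'demo_depleted_TAC'
#>   method=gc3  r=1000  seed=7  q=0.05  codons=200
#>   motifs analysed: 2; non-neutral motif counts: 2
#>     TAC   below=0 (under; observed 0, expected 20.5)
#>     WRC   below=0.003 (under; observed 63, expected 75.8)
```

The depleted subject has 0 TAC occurrences against a null expectation of
20.5 ± 3.6, so `belowTAC = 0`: no shuffle had fewer TACs — under-represented
at any threshold (with r = 1000, read "0" as "< 0.001"). WRC is dragged
down too (every TAC is a WRC), which is what the bivariate layer is for:

```r
round(report_values(rpt)[c("corTACxWRC", "pTACcondWRC")], 4)
#>  corTACxWRC pTACcondWRC
#>      0.3629      0.0000
```

Even conditional on the observed WRC level, TAC remains depleted
(`pTACcondWRC ≈ 0`). A real analysis starts from a FASTA file instead:

```r
seqs <- read_fasta("my_gene.fasta")
rpt  <- cdur_report(seqs[[1]], method = "gc3", r = 1000, seed = 1)  # 23 default motifs
write_cdur_report(rpt, "my_gene_cdur.txt", format = "kv")
```

or from the shell, via the installed CLI:

```sh
exec/cdur --shuffle gc3 -r 1000 --seed 1 --out my_gene_cdur my_gene.fasta
```

`--motifs <file>` swaps in a custom motif vocabulary (one line per motif:
`PATTERN, target=<0-based C offset>, strands=top|bottom|both`).

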