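---
title: "Motif under-representation analysis with cdur: models, null distributions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif under-representation analysis with cdur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdur)
```

## The question the package answers

AID and the APOBEC3 family deaminate cytidine to uridine on single-stranded
DNA, producing C>T (and, read on the opposite strand, G>A) transitions.
Each enzyme prefers a short sequence context — a *mutation motif*: WRC for
AID, TC for most APOBEC3s, CCC for APOBEC3G, with SYC the AID coldspot. A
gene that has spent its evolutionary history exposed to one of these
enzymes may have purged the corresponding motifs, or purged specifically
those motif occurrences where deamination would change the protein.

`cdur` quantifies this. For a coding sequence it measures, per motif:

* the occurrence count on both strands,
* the number of *replacement transitions* — occurrences where the implied
  C>T (or projected G>A) change is nonsynonymous,
* the replacement-transition fraction (their ratio),

and locates each measurement in an empirical null distribution built from
`r` synonymous shuffles of the same sequence. The reported `below` value is
the fraction of null replicates strictly smaller than the observation — an
empirical lower-tail p-value. Values below a threshold `q` (0.05 by
convention) indicate under-representation; values above `1 - q` indicate
over-representation.

## The null models

All three shufflers hold codon positions 1–2 fixed and resample third
positions, so every null sequence encodes exactly the same protein. With
positions 1–2 fixed, the genetic code sorts each codon's synonymous
third-position choices into one of four degeneracy classes — R (A/G),
Y (C/T), H (A/C/T), N (any) — or leaves it FIXED (Met, Trp, and the TGA
stop). Six-codon amino acids split naturally into a two-codon and a
four-codon family because their families differ at positions 1–2. The
TAA/TAG stop pair is mutually reachable and treated as an R family; a
`freeze_stops` switch pins all stops for users who prefer never to touch
them.

The three schemes differ in which compositional covariate they correct for:

**gc3** computes `g`, the subject's third-position GC fraction, once, and
draws every mutable third position independently: total mass `g` split
uniformly over the class's G/C options, mass `1 - g` over its A/T options.
For an Ile codon (H class) at `g = 0.6` this gives P(ATC) = 0.6,
P(ATT) = P(ATA) = 0.2; for a two-codon family, P(G-or-C codon) = `g`. This
is the unique symmetric assignment that reproduces those marginal
constraints. Inspect it with `gc3_option_probs()`.

**n3** permutes the existing third-position nucleotides within each
degeneracy class, without replacement. Nothing is resampled, so the base
composition of the output equals the input's *exactly* — GC content is
conserved, not merely corrected for. We permute strictly within classes:
any cross-class exchange (say, an H slot receiving the G of an N slot)
could silently change the protein, which would defeat the design, so each
third position belongs to exactly one set.

**dn23** tabulates the frequencies of the dinucleotides formed by codon
positions 2–3 across the whole subject, then redraws each mutable third
position with probability proportional to the frequency of the resulting
(position-2, candidate) dinucleotide, normalized over the codon's options.
A codon's own dinucleotide always has positive frequency, so the
normalizer cannot vanish on real input; the uniform fallback exists only
for hand-built degenerate tables. Inspect weights with
`dn23_option_probs()`.

FIXED codons contribute to both the `g` statistic and the dinucleotide
table — they are part of the sequence's composition — but are never
altered. Whether FIXED third positions should enter `g` is genuinely
ambiguous; we include them by default and expose `gc3_include_fixed` to
flip the choice.

### What the null models conserve, exactly and approximately

* All three: the amino-acid sequence, exactly.
* n3: base counts, exactly.
* gc3: the *expected* GC3 of a replicate equals `g` at every mutable slot.
  On a sequence with Met/Trp codons the whole-sequence replicate-mean GC3
  sits slightly off the subject's, because those immutable G thirds are
  averaged into `g` but cannot respond to it. The conservation test
  therefore uses Met/Trp-free subjects, where the equality is exact; on
  real genes the residual offset is
  `(n_fixed / n) * (gc3_fixed - g)`-sized, typically well under one
  percentage point.
* dn23: dinucleotide frequencies are maintained *approximately only*.
  Because the weights are renormalized within each codon's option set, the
  aggregate expected output frequencies are biased relative to the input
  by an amount that depends on how unevenly the normalizers fall across
  codons — we measure ~0.01–0.03 per dinucleotide on 60-codon subjects,
  which is far beyond Monte-Carlo error of a 10^4-replicate mean but well
  inside the null's own per-replicate spread. The test suite asserts the
  spread-level statement (every input frequency within 3 per-replicate SDs
  of the null) and, separately, that the per-sequence sampling
  distribution matches exact enumeration; an exactness-of-the-mean check
  is retained in the acceptance suite and is expected to fail, as a
  recorded property of the method rather than a defect of the
  implementation.

## Motif scanning and the deamination simulation

A motif is an IUPAC pattern plus the 0-based offset of its target cytidine
(`motif_spec()`). Occurrences are all, possibly overlapping, matches:
deamination opportunities are per-site, and no dedup rule is applied. Both
strands are scanned by default; a bottom-strand occurrence is a match of
the reverse-complemented pattern on the stored strand and implies a G>A
change at the mirrored position. The default vocabulary is the 4 NC + 16
NNC motifs, WRC, SYC, and CG — 23 motifs.

Two conventions worth knowing:

* For multi-C patterns the default target is the 3′-most literal C (the
  deaminase-motif convention), which for CG correctly selects the C;
  override per motif via `target_index` or the config file.
* CG is its own reverse complement, so scanning both strands reports both
  cytidines of each CpG — exactly double the top-strand count. Since every
  subject and every replicate is doubled alike, `below` values are
  unaffected.

A replacement transition is counted when the single implied base change
alters the encoded amino acid; changes that create or destroy a stop codon
count as replacements (they are replacement events under any reading).
Replicates with zero occurrences of a motif contribute no
replacement-transition fraction (0/0 carries no information) and are
dropped from that null vector, with the number dropped reported; imputing
them as 0 would bias the fraction null downward.

## The statistics

`below` is the strict fraction of null values less than the observation.
Strict counting follows the standard definition but is mildly
anti-conservative on discrete counts (ties at the observation inflate
neither tail); a mid-p variant (`midp = TRUE`) counts ties at half weight.
In our own type-I calibration — 200 subjects drawn from the gc3 null of a
300-codon sequence, r = 500 each — the fraction of `belowTC` values under
0.05 was 0.075, inside the binomial 99% band [0.015, 0.095] around the
nominal rate; the excess over 0.05 is the discreteness effect just
described.

For every motif pair the replicate-level metric vectors are correlated
(Pearson), per metric family. These correlations feed a bivariate-normal
approximation to the joint null, from which conditional p-values are
computed: the lower tail of X's observation under the conditional law of X
given Y at its observed value,

$$X \mid Y = y \;\sim\; \mathcal N\!\Big(\mu_X + \rho\,
\frac{\sigma_X}{\sigma_Y}(y - \mu_Y),\; \sigma_X\sqrt{1-\rho^2}\Big).$$

This answers "is motif X depleted beyond what its coupling to motif Y
explains?" — relevant when motif definitions overlap (CCC is a subset of
SYC) or when a confounder such as CpG content is under independent
selection. Both orderings are reported (`pXcondY` and `pYcondX` differ).
The conditioning is family-matched: `pXcondRepTrY` conditions X's
replacement-transition count on Y's. Degenerate cases (zero SD, |rho| = 1)
are reported as missing rather than extrapolated.

No multiple-testing correction is applied inside the report — the 23
motifs are a vocabulary, not a hypothesis family, and the headline values
are raw empirical p-values. `bh_adjusted_below()` layers a
Benjamini–Hochberg view on top for users screening many motifs; it is kept
out of the keyword/value schema deliberately so the report keys remain the
standard inventory.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `method` | `gc3` | which covariate the null corrects for |
| `r` | 1000 | null replicates; p-value resolution is 1/r |
| `seed` | — | one seed drives the whole replicate stream |
| `q` | 0.05 | significance threshold; over-representation at 1 − q |
| `midp` | `FALSE` | tie handling in `below` |
| `freeze_stops` | `FALSE` | pin TAA/TAG instead of treating them as an R pair |
| `gc3_include_fixed` | `TRUE` | include immutable thirds in the `g` statistic |

At r = 1000 the smallest nonzero p-value is 0.001 and the Monte-Carlo SE
of a p near 0.05 is about 0.007; raise `r` for sharper tails.
Reproducibility contract: identical (method, seed, input) yields an
identical replicate stream; the CLI analyses record *i* of a multi-FASTA
with `seed + i - 1`, so per-record results do not depend on file
composition.

## The synthetic-data generator, and what passing tests do not show

`random_cds()` draws sense codons uniform over position-1–2 prefixes with
third positions weighted toward a target GC3, then applies synonymous
nudges until the realized GC3 is within ±0.05 of target — so generated
subjects have controlled composition by construction, not by luck.
`deplete_motif()` builds positive controls by greedy synonymous swaps that
strictly reduce a motif's count; because only synonymous swaps are used,
the depleted subject remains inside the support of every shuffle null and
the subsequent test is fair. `enumerate_synonymous()` lists the exact
sample space (guarded at 10^5 variants) and anchors the goodness-of-fit
oracle tests.

These generators emulate composition, not biology: no codon-pair bias, no
selection, no mutational history, no strand-asymmetric replication.
Passing calibration on them shows the machinery is statistically sound
under its own model; it does not show that a significant `below` value on
a real gene has a deaminase explanation rather than any other force
shaping synonymous-site composition. Choosing the shuffle method *is*
choosing which alternative explanations are controlled for (GC3 under gc3,
exact composition under n3, dinucleotide/codon bias under dn23); running
more than one method and comparing is the intended workflow.

## Numerical and engineering notes

* Scanning uses `Biostrings` pattern matching with IUPAC expansion; the
  test suite verifies occurrence lists against an independently written
  naive two-strand scanner, and replacement counts against full
  re-translation.
* Replicate metrics are computed set-wise (one vectorized scan over all
  replicates per motif), which is what makes r = 1000 over 23 motifs cheap.
* Problem sizes used by the heavier checks — 10^4-replicate conservation
  runs, 200 × r = 500 type-I calibration on 300-codon subjects, 50 ×
  r = 1000 depletion controls on 200-codon subjects — were chosen as the
  smallest sizes at which the binomial/Monte-Carlo bounds being asserted
  are sharp enough to be meaningful.
* Sequences containing internal stops are accepted with a warning
  (`strict = TRUE` rejects); IUPAC ambiguity codes in the *input sequence*
  are always rejected, because every downstream count would be
  ill-defined.
* Reports serialize as `key<TAB>value` lines: `kv` mode displays 3
  significant digits, `tsv` mode full precision and round-trips losslessly
  via `read_cdur_report()`.

## Known limitations

* The bivariate-normal conditional is an approximation; counts are
  discrete and mildly skewed, so conditional p-values inherit normal-tail
  error in the extreme tails.
* dn23 does not exactly conserve dinucleotide frequencies (see above), and
  gc3 conserves GC3 in expectation only — n3 is the method of choice when
  exact compositional invariance is required.
* No codon-pair-bias-preserving shuffle is provided.
* Empirical p-values are bounded below by 1/r; `below = 0` means "smaller
  than 1/r", not zero.
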