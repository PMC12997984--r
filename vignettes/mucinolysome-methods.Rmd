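---
title: "Methods: mucinolysome detection, interaction scoring, abundance and expression"
output: rmarkdown::html_document
---

This vignette documents the models and numerical procedures implemented in
`mucikit`, the default parameters and why they were chosen, what the
synthetic-data generators do and do not emulate, and the package's known
limitations. It is a methods description, not a results report: the package's
tests assert every empirical quantity the package computes, and nothing is
claimed here beyond what those computations cover.

# 1. Domain architecture

## Inputs

`parse_domtblout()` reads HMMER3 `--domtblout` tables (per-domain rows), and
`read_hits_tsv()` reads pre-tabulated hits from CAZyme/peptidase/sulfatase
annotators. All sources are normalised to one schema: `protein_id`,
`model_name`, `source_db`, `e_value` (the i-Evalue for HMMER input),
`hmm_from/to`, `hmm_length`, `ali_from/to`, `protein_length`.

## Filtering (`filter_hits`)

Defaults, applied with strict inequalities:

| source | E-value | HMM coverage |
|---|---|---|
| Pfam cohesin/dockerin | < 1e-4 | > 0.6 |
| CAZyme families | < 1e-15 | > 0.35 |
| peptidases (MEROPS-style) | < 1e-10 | — |
| sulfatases | < 1e-3 | — |

Coverage is `(hmm_to - hmm_from + 1) / hmm_length`, i.e. the fraction of the
profile matched, not the fraction of the protein. The Coh/Doc thresholds are
deliberately conservative because both modules are short (the bundled
defaults assume profile lengths near 139 and 58 residues) and spurious
partial matches are common; the coverage criterion is applied to the Pfam
cohesin/dockerin hits, where fragmentary matches would directly corrupt the
screen, and not to catalytic-domain hits, whose annotators already report
trimmed domain calls and where multi-domain fusions make full-profile
coverage an unreasonable demand. The CAZyme defaults (E < 1e-15, coverage
> 0.35) follow common dbCAN practice. All thresholds are arguments of
`build_architectures()` and can be changed per run.

## Overlap resolution (`resolve_overlaps`)

Within a protein, hits are accepted greedily in ascending E-value order
(ties broken by alignment start, then model name, for determinism); a
candidate is rejected if it overlaps an already accepted hit by more than
50 % of the shorter hit's length. This keeps adjacent tandem modules (e.g.
consecutive cohesins) while removing double calls of the same region by
related profiles.

## Classification (`classify_protein`)

From the resolved domain string:

* **scaffoldin** — ≥ 1 cohesin and no catalytic (CAZyme/peptidase/sulfatase)
  domain;
* **coh_enzyme** — cohesin together with a catalytic domain (cohesin
  takes precedence over dockerin if both are present);
* **doc_cazyme** — dockerin plus ≥ 1 CAZyme domain (`dual_role = TRUE` if a
  peptidase domain is also present);
* **doc_peptidase** — dockerin plus peptidase but no CAZyme;
* **doc_other** — dockerin without a recognised catalytic domain;
* **other** — everything else.

`extract_domain_regions()` cuts domain regions from protein FASTA with a
symmetric pad (default 10 residues, clamped to the protein) for downstream
structure prediction of individual modules.

# 2. Mucinolysome screen

`screen_genome()` calls a genome positive iff it has **both**

1. a scaffoldin carrying **at least two** cohesins, and
2. at least one dockerin-bearing CAZyme whose GH family is in the mucin-active
   set.

The two-cohesin requirement encodes the defining property of a multi-enzyme
complex: a single-cohesin scaffoldin can anchor only one enzyme and is not
distinguishable from an isolated adaptor. The mucin-GH set ships as a plain
TSV (`mucin_gh_families()`), currently 25 families covering sialidases,
fucosidases, hexosaminidases, and O-glycan core-structure hydrolases; family
matching is asymmetric so that a bare family (e.g. `GH43`) matches its
subfamilies (`GH43_24`) but a subfamily matches only itself. The weaker
co-presence filter (≥ 1 Coh and ≥ 1 Doc anywhere in the genome,
`copresence_filter()`) is exposed separately because it is a useful cheap
pre-screen; the full verdict is always a subset of it.

`homology_expand()` propagates screen hits to unannotated genomes from a
BLAST-style tabular alignment using identity ≥ 50 %, query coverage ≥ 85 %,
E < 1e-5 — a deliberately strict orthology-style cut, since the expansion is
used for prevalence claims, where false positives are costlier than misses.

# 3. Cohesin–dockerin interaction scoring

`read_complex()` loads a two-chain model (PDB or mmCIF via `bio3d`), taking
plDDT from the CA B-factor column as AlphaFold-style models store it.
`find_interface()` defines a contact as an inter-chain residue pair whose
CB atoms (CA for glycine) are within `dist_cutoff = 8` Å; this CB-based
definition is the standard one for pDockQ and is less sensitive to side-chain
placement than all-atom contact counting. `IF_pLDDT` is the mean plDDT over
the union of interface residues (each residue counted once, regardless of
how many contacts it participates in).

The confidence score is the published pDockQ sigmoid

$$\mathrm{pDockQ} = \frac{0.724}{1 + e^{-0.052\,(x - 152.611)}} + 0.018,
\qquad x = \mathrm{IF\_pLDDT}\cdot\log_{10}(\mathrm{IF\_contacts}),$$

with pDockQ defined as exactly 0 for zero contacts. Two numerical notes:
the score is bounded above by 0.742; and at `IF_contacts = 1` it is constant
in plDDT, because $\log_{10}(1)=0$ collapses $x$ to zero — so monotonicity in
plDDT holds only for two or more contacts. The implementation keeps this
behaviour rather than patching it, since it is a property of the published
functional form.

`build_ppi_matrix()` arranges per-pair scores into a cohesin × dockerin
matrix and predicts binding where pDockQ is **strictly** greater than 0.3
(the conventional "acceptable model" cut-off for pDockQ). `evaluate_ppi()`
scores predictions only over cells with an experimental `+`/`-` label;
unassayed pairs contribute nothing, and precision/recall are reported as
`NA` when their denominators are zero rather than coerced to 0 or 1.

# 4. Abundance profiling

A `depth_profile` stores per-position depth, mapped read count and
(optionally) mean read identity for one target in one sample; profiles come
from dense TSVs (`read_depth_tsv()`) or directly from indexed BAMs
(`depth_from_bam()`, via `Rsamtools::pileup` restricted to primary,
non-supplementary alignments).

* breadth of coverage `BC` = fraction of positions with depth ≥ 1,
* average read depth `ARD` = total mapped bases / target length,
* presence iff `BC >= 0.6` **and** `ARD >= 1` (inclusive bounds: a target
  covered at exactly the threshold counts as present), with an additional
  strict mean-identity requirement for 16S-style targets where mapping
  cross-talk between close taxa is the dominant error mode.

The BC criterion guards against high piles of reads on a single conserved
segment faking presence; the ARD criterion guards against trace breadth from
scattered mismapped reads. `prevalence()` aggregates presence calls per host
group plus an `overall` row; a sample is positive if any target is present.
`subsample_reads()`/`subsample_fastq()` perform deterministic, seedable
uniform subsampling (sorted `sample.int`) for depth normalisation across
samples.

# 5. Expression summaries

`tpm()` implements standard transcripts-per-million (each condition sums to
10⁶). `flag_degs()` marks a gene up/down iff `|log2fc| > 1` and
`padj < 0.05`, both strict; rows with missing adjusted p-values are flagged
`ns` with a warning rather than dropped, so table shapes are stable.
`summarize_expression()` reports per category (mucinolysome gene,
mucinolysome peptidase, other mucin-active CAZyme): gene count, up-regulated
count and percentage, optional top-decile membership (the decile is computed
over a supplied genome-wide TPM table with `ceiling(0.1 * N)` genes, ties
broken by gene id; it is `NA`, not 0, when no genome-wide table is given),
and top-vs-second TPM fold ratios per condition. The bundled
`et540_expression()` table carries the *Limousia* ET540 mucin-vs-glucose
comparison used in the examples and tests.

# 6. Synthetic data generators

All generators take an integer `seed` (< 2³¹), derive independent child
seeds per stream (`derive_seed()`), restore the caller's RNG state, and
return recorded ground truth alongside the data, so tests can assert exact
recovery rather than statistical agreement.

* `sim_genomes()` plants an exact number of mucinolysome-positive genomes;
  each negative genome records which criterion it violates (`no_coh`,
  `no_doc`, `single_coh_scaffoldin`, `non_mucin_gh`) and genomes also carry
  sub-threshold decoy hits that the filters must reject. It emulates the
  *logical* structure of annotation output — hit tables with realistic
  E-value/coverage spreads, multi-domain architectures, protein lengths —
  not sequence evolution: the optional FASTA sequences are random amino
  acids, and no attempt is made to model homology, GC content, or gene order.
* `sim_complex()`/`sim_complexes()` build CA/CB pseudo-structures with
  exactly `k` contact pairs (pairs 4 Å apart across chains, 30 Å apart
  within a chain so no incidental contacts arise, decoy residues far away),
  with closed-form truth including pDockQ. They emulate interface geometry
  and plDDT bookkeeping, not protein folds: residues are alanine-like
  two-atom stubs, adequate for exercising contact detection, PDB round-trip
  and scoring, and nothing else.
* `sim_depth()` plants exact per-host presence labels; absent profiles fail
  by low breadth or low depth specifically, and truth stores the exact
  BC/ARD of every profile. Depth is piecewise-Poisson, not a model of real
  mapping biases (GC, repeats, edge effects).
* `sim_expression()` plants exact up/down counts with a margin on both the
  fold-change and p-value thresholds, so flag recovery is exact by
  construction.

Default problem sizes in the generators (e.g. 200 genomes, 100 samples × 5
targets, 2,527 genes) are the package's own choices for testing at desk
scale and carry no external meaning.

# 7. Open choices and their resolutions

* **HMM coverage scope.** Coverage filtering applies to Pfam cohesin/dockerin
  hits only (rationale in §1); catalytic-domain sources use their own
  E-value/coverage defaults.
* **Strict vs inclusive thresholds.** Hit filters, the pDockQ cut-off, DEG
  thresholds and the 16S identity bound are strict; the BC/ARD presence
  bounds are inclusive. Each is documented at the function and configurable.
* **Undefined ratios.** Precision/recall with empty denominators, repertoire
  percentages for genomes with zero GH proteins, and top-decile counts
  without a genome-wide table are `NA`, never silently 0.
* **Overall prevalence.** The `overall` row is computed from pooled counts;
  the package reports the computed value and never adjusts it toward an
  externally quoted figure.

# 8. Limitations

* The screen is purely presence/absence of domain architectures; it does not
  verify operon structure, expression, secretion (signal-peptide annotation
  is carried through but not required for a positive call), or cell-surface
  anchoring.
* pDockQ is a confidence proxy, not a binding-affinity predictor; the 0.3
  cut-off trades recall for precision and was not re-tuned here.
* `depth_from_bam()` trusts the upstream mapper's alignments; no re-alignment
  or identity recomputation is performed, so 16S-style identity filtering
  requires identity values supplied with the profile.
* The generators validate the pipeline's logic, not its behaviour on real
  data idiosyncrasies (chimeric assemblies, fragmented MAGs, unannotated
  subfamilies); conclusions about real genomes still require inspection of
  the underlying annotations.
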