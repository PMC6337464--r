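---
title: "Section-wise PDB extraction and fuzzy C-alpha distance selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Section-wise PDB extraction and fuzzy C-alpha distance selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdblake)
```

## The problem

High-resolution macromolecular structures are distributed as fixed-width
PDB text files in which each line is a record whose first six columns name
its type. Most geometric and statistical calculations over these
structures start the same way: pull one *section* of many entries —
coordinates (`ATOM`/`HETATM`), secondary structure (`HELIX`/`SHEET`), or
chain sequences (`SEQRES`) — into a flat table. `pdblake` implements that
extraction step as a local, deterministic, parallel pipeline, plus one
worked analysis on top of it: per-chain consecutive C-alpha distances
selected by a fuzzy "around 3.81 Å" condition.

## Parsing model and its assumptions

Fields are sliced at the fixed 1-based columns of wwPDB format v3.3, the
de-facto dialect of `*.ent` files (for `ATOM`: serial 7–11, name 13–16,
altLoc 17, resName 18–20, chainID 22, resSeq 23–26, iCode 27, x/y/z
31–54, occupancy 55–60, tempFactor 61–66, element 77–78, charge 79–80).
Bytes are decoded as Latin-1: PDB files are ASCII in practice and Latin-1
decoding can never fail, so a stray byte cannot abort a batch job for
encoding reasons.

A line is *malformed* when it is shorter than the last mandatory column of
its kind (column 54, the z coordinate, for coordinate records) or carries
non-numeric text in a mandatory numeric column. The default is strict:
extraction stops with a classed error carrying the line number and file,
because silently dropping rows corrupts downstream statistics. Lenient
mode (`strict = FALSE`, `--lenient`) skips malformed lines and reports a
count, for salvage runs over damaged corpora. Optional numeric fields
(occupancy, temperature factor, helix length) may be blank; they become
`NA` in memory and empty fields in CSV.

Two contextual attributes are attached to every coordinate row. The
`proteinId` is the HEADER idCode (columns 63–66, uppercased — idCodes are
case-insensitive) with the file stem or sequential-record index as
fallback, so entries without a HEADER remain traceable. The `modelId`
tracks `MODEL`/`ENDMDL` blocks and defaults to 1, matching single-model
X-ray entries that omit MODEL records entirely. Alternate locations are
retained unfiltered: the extractor is lossless, and what to do with
altLocs is an analysis decision, not a parsing one.

## Sequential files

Processing many small files has a fixed per-file cost, so the store
supports *sequential files*: plain concatenations of entries, bit-exact
with `cat` of member files, in which a record ends at the first line whose
first token is exactly `END`. `ENDMDL` is a distinct record type and never
terminates a record — an adversarial multi-model test pins this down.
Records are capped at 4 MiB (binary megabytes, `4 * 2^20` bytes) of
*decompressed* text, since records are parsed decompressed; the same cap
drives `partition_inputs()`, which splits a collection into files small
enough to concatenate and larger ones to process individually. Entries
lacking a final `END` are normalized at build time by appending one; at
iteration time a trailing END-less block is an error in strict mode and a
final record in lenient mode. Blank lines between entries are tolerated
and belong to no record. Compression is whole-file gzip, detected by magic
bytes rather than extension; per-record compression is deliberately not
supported.

## Deterministic parallelism

The unit of work is one entry — never part of one — and results are
aggregated by (input position, record index, line order). Determinism is a
design choice where the aggregation order was genuinely open: it makes
worker-count invariance a testable contract (`workers` ∈ {1,2,4,8} produce
byte-identical CSV) and costs nothing at this scale. Workers are forked
processes (`parallel::mclapply`); on platforms without fork the engine
falls back to serial execution with identical output.

## The distance analysis

Within each `(proteinId, modelId, chainId)` group the C-alpha atoms
(`atomName == "CA"`, record name `ATOM` only — which excludes calcium
HETATM records of the same name; first altLoc per residue wins) are taken
in file order, and each adjacent pair yields one distance

$$d_{i,i+1} = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2 + (z_{i+1}-z_i)^2},$$

the explicit Euclidean form of the vector norm $\lVert a_i - a_{i+1}
\rVert$; the two formulations agree to 1e-12 relative tolerance, which the
suite checks on 10^5 random pairs. Adjacency is file order, not residue
numbering, so insertion codes and numbering gaps do not silently split or
pair residues; every pair carries a `seqGap` annotation
(`resSeqTo - resSeqFrom`) so the user can drop pairs spanning missing
residues if their analysis requires it. That deferral is deliberate:
whether a gap-spanning pair is meaningful depends on the question asked.

Selection is fuzzy rather than a hard window: the membership function

$$\mu(d) = \exp\!\left(-\frac{(d - c)^2}{2\sigma^2}\right)$$

grades how well a distance matches "around $c$", and a pair is kept when
$\mu(d) \ge \lambda$. Defaults: $c = 3.81$ Å, the ideal consecutive
C-alpha spacing of trans peptides; $\lambda = 0.5$, the conventional
half-height cut. The width $\sigma$ is the one genuinely open parameter:
the defining behaviour — 3.78 Å satisfies the condition at $\lambda=0.5$
while 3.87 Å does not — bounds $\sigma$ to (0.0255, 0.0510) Å, because the
half-height half-width of a Gaussian is $\sigma\sqrt{2\ln 2}$ and must
fall between 0.03 and 0.06 Å. The default 0.04 Å sits in the middle of
that interval; it is an exposed parameter, not a constant. The comparison
is `>=` (not `>`) so that $\lambda = 1$ keeps exactly the center, and
raising $\lambda$ can only shrink the kept set — a property the suite
tests over generated cases.

```{r fuzzy}
fs <- fuzzy_set()
gaussian_membership(c(3.78, 3.81, 3.87), fs)
```

## What the synthetic generator emulates — and what it does not

`make_polypeptide()` writes column-valid entries: HEADER, SEQRES (13
names per line, correct `numRes`), optional HELIX/SHEET annotations,
optional MODEL blocks, N/CA/C ATOM records, TER, one HETATM water, END.
C-alpha atoms walk along randomly chosen coordinate axes with fixed step
length (default 3.81 Å); axis-aligned steps survive the format's 0.001 Å
coordinate quantisation exactly, so a noise-free fixture parses back to
distances *equal* to the spacing — the property the end-to-end
deterministic tests rely on. With `noise_sd > 0`, iid isotropic Gaussian
noise is added to each placed C-alpha, so a consecutive displacement is
$N(\mu, 2\sigma_n^2 I_3)$ with $\lVert\mu\rVert$ = spacing and the distance
follows the 3-D noncentral chi law
$d^2/(2\sigma_n^2) \sim \chi'^2_3(\text{ncp} = s^2/(2\sigma_n^2))$. That
closed form gives the parameter-recovery test its analytic target (kept
fraction under the fuzzy cut) with no circularity: the target comes from
`pchisq`, the measurement from the full generate → write → parse →
distance → filter pipeline.

Defaults (10 entries, 50 residues, one chain, one model, noise 0.02 Å,
seed 42) are a deliberately small stand-in for a curated corpus slice —
noise of a few hundredths of an Å keeps distances in the fuzzy set's
sensitive region without being geometrically absurd. The generator is
*not* a structure simulator: no side chains, no realistic backbone
torsions, residue identities simply cycle the 20 standard codes, and the
HELIX/SHEET annotations are positional placeholders. A green test
establishes that parsing, storage layout, parallel aggregation and the
distance/fuzzy mathematics are correct on format-valid input; it says
nothing about chemistry, and real-corpus quirks (nonstandard records,
negative residue numbers with insertion codes, multi-character chain IDs
of mmCIF origin) are exercised only to the extent the parsers' unit tests
construct them.

## Numerical and edge-case choices

* Residue numbers and `numRes` are 4-column fields, so one generated chain
  is capped at 9999 residues; the 10^4-residue statistical tests use two
  chains of 5000.
* Distances are computed from parsed (3-decimal) coordinates; coordinate
  quantisation contributes at most ~5e-4 Å per axis and is negligible
  against the default noise and fuzzy width.
* A chain with fewer than two C-alpha atoms emits no pairs; an empty
  extraction returns a zero-row table with the full column schema, so
  downstream code never branches on emptiness.
* Derived generator seeds stay below 2^31 − 1; generation saves and
  restores the caller's RNG state.
* CSV output is RFC-4180-style with minimal quoting, `NA` written empty,
  and a newline-terminated final line.

## Known limitations

Only the five listed sections are parsed — no CONECT, REMARK or CRYST1 —
and mmCIF/PDBML inputs are out of scope. Sequential files support neither
random access nor deduplication. The fuzzy machinery is exactly one
Gaussian membership with a lambda-cut; other membership shapes or fuzzy
operators, and other interaction geometries (aromatic, ionic, disulfide),
are not provided. Wall-clock performance at repository scale depends on
hardware and is not part of the tested contract.
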