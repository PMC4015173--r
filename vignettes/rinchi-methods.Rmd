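---
title: "Reaction identifiers: model, canonical form and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction identifiers: model, canonical form and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinchi)
```

## The identifier model

A reaction identifier should satisfy one property above all others: two
scientists filing the same reaction must produce the same string, whatever
order they drew the molecules in and whichever way round they wrote the
arrow. The construction here achieves that with three moves.

1. **Molecule canonicalization is inherited, not reinvented.** Every
   species is represented by its standard InChI (version 1S), produced by
   the official InChI algorithm via Open Babel. The engine's output is
   treated as ground truth and never re-canonicalized; this package only
   ever manipulates the strings.
2. **Group structure.** The molecules are placed in three groups: the two
   sides of the arrow, and the agents — species present on both sides,
   i.e. solvents and catalysts. Within a group, InChI bodies are sorted
   byte-wise (the `LC_ALL=C sort` order, implemented with R's radix
   sort, which is locale-independent). The two *sides* are then compared
   byte-wise as concatenated strings and the smaller becomes group 1.
   Group 3 never participates in that comparison.
3. **Direction as a layer, not as group order.** Because group order is
   decided by sorting, a `/d+`, `/d-` or `/d=` layer records whether the
   reactants sit in group 1, in group 2, or whether the reaction is an
   equilibrium. A reaction of unknown direction simply omits the layer and
   is still a valid identifier.

Serialization is `RInChI=0.02.1S/` + groups joined with `//`/`///` + the
direction layer. The per-molecule `InChI=1S` prefixes are stripped: the
version is declared once in the label. We emit no trailing slash and omit
trailing empty groups, making serialization injective — string equality is
identifier equality, which is what makes text-sort deduplication sound.

### Degenerate and boundary cases

* **One empty side.** Byte-wise comparison would always sort an empty
  side first. We instead put the populated side in group 1, so a reaction
  with no known product shows only its first group (with `/d+`).
* **Identity reactions** (both sides equal): `/d+` versus `/d-` would be
  meaningless, so the direction layer is forced off.
* **Duplicates within a group are preserved** (`A//A`), never collapsed:
  the identifier carries no stoichiometry, and a duplicate is the only
  stoichiometry-like signal left.
* **Parsing validates rather than repairs**: unsorted groups, a group 1
  that compares after group 2, or a bad direction token are validation
  errors. Both header spellings seen in practice (`0.02.1S`, `0.02.1.S`)
  and one trailing slash are accepted on input; output is always the
  single canonical form.
* An empty group *between* populated groups (e.g. no products but agents
  present) serializes as consecutive separators; parse inverts this
  exactly.

### RAuxInfo

The companion string `RAuxInfo=0.02.1/...` mirrors the identifier group
for group and molecule for molecule, holding each molecule's AuxInfo body
(the `AuxInfo=1/` prefix is stripped into the label, symmetrically with
the InChI treatment; the exact label text is this package's choice and is
documented here because no external fixture exists for it). AuxInfo is
what makes decoding drawable: its `rA`/`rB`/`rC` layers record the
original atom symbols, bonds (including wedge direction, with the anchor
atom encoded by letter case) and coordinates. Decoding with a RAuxInfo
therefore reconstructs the original connection tables directly, and the
result is verified by re-deriving each InChI. Decoding without one emits a
0D connection table with every atom at the origin; tetrahedral
stereochemistry survives in the atom-parity column, which the InChI
engine honours for 0D tables. 2D layout generation is deliberately out of
scope.

## Hashed keys

Long keys list each molecule's 27-character standard InChIKey in RInChI
order, `-` within groups and `--` at group boundaries, after two header
blocks: the version block (`aSA`/`bSA`: version letter plus two letters
identifying the constituent keys as standard) and a hash of the
additional reaction layers. Version B replaces that hash's first letter
with the direction letter `F`/`B`/`E`/`U`.

Short keys are fixed-length. Version A hashes each group's concatenated
bodies into one 15-letter block (empty groups included — an absent agent
group still contributes its constant block, so two agent-free reactions
agree there). Version B splits every body into its **major part**
(formula, `/c`, `/h`, `/q` — composition, skeleton, hydrogens, charge)
and **minor part** (everything else: stereo, isotopes), producing three
10-letter major blocks and three 5-letter minor blocks whose first letter
flags the group's net protonation (`N` = 0, `O`,`P`,… = +1,+2,…,
`M`,`L`,… = −1,−2,…, clamped with a warning beyond the alphabet). The
payoff of the split: enantiomeric reactions differ *only* in the minor
blocks of the two reaction sides, so a major-level scan treats them as
the same skeleton transformation while the full key still distinguishes
them.

All reaction-level blocks are SHA-256 digests of the hashed text, mapped
to letters by the same base-26 triplet encoding the official InChIKey
uses, then truncated (truncation is prefix-stable). Block lengths (5; 1+4;
15; 10; 1+4) are read off the published example keys. Since the original
tooling never disclosed its hash, keys produced here cannot byte-match
historically printed keys; printed examples are used structurally
(block counts, lengths, equality patterns), and that limitation is
accepted and documented.

The per-molecule `inchikey()` is this package's own implementation of the
official algorithm — SHA-256 over the major and minor layer parts with
the official base-26 triplet/doublet tables, the minor part self-appended
once when shorter than 255 bytes, `/p` excluded from the hash and encoded
in the final protonation letter. It is tested byte-for-byte against the
official engine on every fixture molecule; a hash-level reimplementation
is the only way the reaction keys can be computed from identifier strings
alone without shelling out per molecule.

## The connectivity-layer analytics

The ring tool never touches a structure file: a molecule's InChI `/c`
layer *is* its heavy-atom graph. The layer grammar (numbers are atoms in
canonical order, `-` chains, parentheses branches, `,` sibling branches,
a repeated number a ring closure) is decoded into an explicit edge list,
and the independent ring count is the cyclomatic number
`edges − atoms + 1` per connected component. Multi-component InChIs
(`;`-separated sublayers, `n*` repetition) are split so that each
component counts as one molecule — consistent with "rings per molecule" —
and hydrogen-only components (zero heavy atoms) contribute nothing.
Tests cross-check every fixture against an igraph cycle-rank oracle run
on the source molfiles.

Stereocentre counts are the number of `/t` designations plus, by default,
`/b` designations (double-bond stereo is stereochemical information too);
a `t_only` mode restricts to tetrahedral centres. Deltas are product side
minus reactant side, oriented by the direction layer; `/d=` and
direction-less entries have no preferred side, so their deltas are
reported as magnitudes with a `direction_unspecified` flag. Ratios with
an empty denominator (no molecules, or no cyclic molecules on a side)
are reported as 0 with an `empty_denominator` flag rather than erroring,
keeping corpus scans total.

## Multistep combination

Steps are combined on *sets* of InChI bodies (the identifier carries no
stoichiometry, so multiset bookkeeping across steps would be false
precision). With steps oriented — `/d-` steps flip themselves,
equilibrium steps must be given an orientation, direction-less steps are
read as written unless overridden — the overall reaction uses endpoint
semantics: a species opens the reaction if it is consumed before it is
ever produced, closes it if it is produced after it is last consumed, and
cancels if it lives only in the middle. All step agents merge into group
3: once combined, the identifier cannot distinguish reagents, solvents
and catalysts of intermediate steps. A species that qualifies as both
endpoint reactant and endpoint product (a catalyst consumed in the first
step and regenerated in the last) goes to group 3 as well, so no species
ever appears in more than one of groups 1/2. Under these semantics,
combination is associative for chains with disjoint agents. Intermediates
that are *also* net-present at an end are resolved by the same
first/last-appearance rule; that choice is this package's documented
"endpoint semantics".

## Corpus analytics

A corpus is a vector of identifier strings plus an inverted index from
InChI body to (entry, group, role). Roles honour the direction layer (for
`/d-`, group 1 holds products); both sides of an equilibrium match
reactant and product searches. Entries without a direction layer get the
role `unspecified-participant` — the role vocabulary needed a value for
them, and matching both sides (like equilibria) is the conservative
choice for search, since neither side can be excluded. "Equilibrium
agent" is interpreted as the agent group of `/d=` entries.

Duplicate means byte-identical identifier string, exactly what a text
sort finds; records differing only in free-text comments are duplicates
by construction because comments never enter the identifier. An opt-in
`core` mode additionally ignores group 3 and the direction layer.

## RXN/RD input, agents and variations

The RD reader supports `$RFMT`/`$RXN` records with `$DTYPE`/`$DATUM`
fields. Which data fields hold agent structures is vendor-specific, so
the agent-field name list is configuration, defaulting to names containing
*catalyst*, *solvent*, *reagent* or *agent* (case-insensitive).
`VARIATION(k)` tags in field names expand one record into one identifier
per agent variation sharing the core reaction. Species appearing
identically on both sides of an embedded RXN are reclassified into the
agent group on this path (group 3 is *defined* as molecules on both
sides); the plain RXN reader leaves sides untouched so that write/read
round-trips preserve them. A malformed record fails alone — remaining
records are still returned, with per-record errors attached. V3000
tables are rejected with a clear error; the supported dialect is V2000.
Agents cannot be written to a strict RXNfile; they are dropped with a
warning unless the non-standard third-count dialect is requested.

## The synthetic corpus generator

`make_corpus()` emulates the *shape* of vendor reaction databases, not
their chemistry: many small reactions, a fraction of exact duplicate
records distinguished only by a free-text comment, and per-record agent
variations. Base reactions are a homologous series of alcohol
dehydrations (chain lengths 2, 3, 4, …), so every base reaction is
structurally distinct by construction and the manifest's expected unique
count, duplicate groups, molecule counts and per-entry ring/stereo deltas
are exact ground truth rather than re-derived quantities. Default
conditions — 500 entries, 10% duplicates, 20% of base reactions with two
catalyst variations — are fixed once here; the test suite runs the same
generator at 30–60 entries for unit checks and at 500 for the end-to-end
pipeline check, and `scripts/acceptance.R` at 500. Generation is
deterministic for a fixed seed (RNG state is restored around it).

What passing these tests shows — and does not show — about real data:
the pipeline's bookkeeping (dedup, counting, role indexing, deltas) is
exact on a corpus whose ground truth is known by construction, and the
identifier layer is canonical under permutation and role swaps. The
generator does not emulate drawing-style variance (tautomer choices,
charge conventions, 2D layout differences) that makes distinct real-world
records of the same reaction differ in their *InChIs*; robustness to
that lives in the InChI algorithm itself, which this package inherits
rather than tests.

## Numerical and implementation notes

* Byte-wise sorting uses R's radix method; it is locale-independent by
  construction, so identifiers are identical across sessions and
  platforms.
* All hashes are SHA-256 (`digest`); base-26 letter tables are computed
  once at load. `hash_block("", n)` is a legitimate value (empty groups
  are hashed like any text) and is pinned in the tests.
* Engine calls are batched (one `obabel` process per conversion request)
  and memoised on exact molfile text; corpus-scale runs touch the engine
  once per distinct molecule.
* An optional `major_then_minor` sort mode orders groups by major-layer
  substring with the full body as tie-break, anticipating that sorting on
  full strings lets minor-layer edits reorder groups; the default remains
  the byte-wise 0.02 behaviour.
* Problem sizes in the shipped checks: 1000 generated reactions for the
  grammar/round-trip property, full permutation sets (up to 4! per side)
  for canonicality, a 500-entry corpus for the pipeline; these sizes are
  where the properties stabilise while keeping the whole suite in a few
  minutes.

## Known limitations

* Reaction-condition layers and atom–atom mapping are out of scope by
  design; stoichiometry is not represented, so "2 A" and "A" differ only
  if the duplicate body survives in a group.
* Printed historical keys cannot be byte-matched (hash never disclosed);
  only their structure is reproduced.
* Charged or isotopically labelled species decode correctly, but AuxInfo
  reconstruction covers symbols, bonds, wedges, charges and coordinates —
  exotic CTAB properties beyond those fall back to the engine's 0D path.
* The RD reader targets the `$RFMT`/`$DTYPE`/`$DATUM` dialect; molecule
  registry (`$MFMT` top-level) records and V3000 tables are not
  supported.
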