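# rinchi

Canonical reaction identifiers (RInChI 0.02) for R: build, hash, decode,
combine and analyse.

## The problem

A molecule has a canonical text identifier — the IUPAC InChI — so two
chemists drawing the same structure always write down the same string. A
*reaction* has no such luxury: the same transformation can be filed with
its molecules in any order, with or without solvents and catalysts, drawn
left-to-right or right-to-left. This package implements the reaction-level
identifier that fixes those choices, so reaction databases can be
deduplicated, indexed and searched with nothing more than text tools.

A RInChI arranges the standard InChIs (version 1S) of the participating
molecules into three groups — the two sides of the arrow plus the agents
present on both sides (solvents, catalysts) — sorts each group byte-wise,
sorts the two reaction sides against each other byte-wise, and joins them
with `//` inside a group and `///` between groups under a single version
label:

```
RInChI=0.02.1S/<group1>///<group2>///<group3>/d<+,-,=>
```

Because the group order is decided by sorting rather than by chemistry, a
direction layer records where the reactants ended up: `/d+` (reactants in
group 1), `/d-` (reactants in group 2), `/d=` (equilibrium); the layer is
omitted when the direction is unknown — the string is still a valid
identifier. A companion `RAuxInfo` string, aligned group-by-group and
molecule-by-molecule, carries the auxiliary information (2D coordinates,
wedge bonds) needed to regenerate a drawable reaction file.

Since full identifiers grow with the reaction, four hashed **RInChIKeys**
are provided: long keys A/B (one standard InChIKey per molecule, `--` at
group boundaries) and fixed-length short keys A/B (SHA-256 blocks in the
InChIKey's base-26 letter encoding). The B variants spell the reaction
direction as a leading `F`/`B`/`E`/`U` letter, and short-B splits each
group into separately hashed major layers (formula, connectivity,
hydrogens, charge) and minor layers (stereo, isotopes) with a protonation
flag letter — so, for example, two enantiomeric reactions share every
block except the minor blocks of the two reaction sides.

Structure/InChI interconversion is delegated to Open Babel's `obabel`
(which embeds the official IUPAC InChI library); everything downstream —
layer parsing, canonicalization, hashing, multistep combination, corpus
analytics — operates on identifier strings alone. The package's own
InChIKey implementation reproduces the official engine's keys byte for
byte, and is tested against it.

## Worked example

Ethyl acetate pyrolysis (one reactant, two products), read from an
RXNfile and converted:

```r
library(rinchi)

rxn   <- read_rxn(write_rxn(fixture_reactions()$ester_pyrolysis))
built <- build_rinchi(rxn)
cat(rinchi_serialize(built$rinchi), "\n")
print(rinchikey_bundle(built$rinchi))
```

```
RInChI=0.02.1S/C2H4/c1-2/h1-2H2//C2H4O2/c1-2(3)4/h1H3,(H,3,4)///C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3/d-
Long-RInChIKey-A = aSA-TUDVR-VGGSQFUCUMXWEO-UHFFFAOYSA-N-QTBSBXVTEAMEQO-UHFFFAOYSA-N--XEKOWRVHYACXOJ-UHFFFAOYSA-N
Long-RInChIKey-B = bSA-BUHFF-VGGSQFUCUMXWEO-UHFFFAOYSA-N-QTBSBXVTEAMEQO-UHFFFAOYSA-N--XEKOWRVHYACXOJ-UHFFFAOYSA-N
Short-RInChIKey-A = aSA-TUDVR-IOXLBHDKTQMGBWN-XEKOWRVHYACXCVL-UHFFFADPSCTJKWU
Short-RInChIKey-B = bSA-BUHFF-IOXLBHDKTQ-XEKOWRVHYA-UHFFFADPSC-NAZYK-NUHFF-NUHFF
```

Reading the output: the two *products* (ethene, acetic acid) sorted
byte-wise ahead of the reactant, so they form group 1 and the direction
layer is `/d-` — the long-B key accordingly starts its second block with
`B` (backward). Group 3 is absent (no agents), which is why the long keys
contain a single `--` boundary and the short keys' third group block is
the hash of the empty group. The ring-change tool, working purely on the
connectivity layers, reports the Diels–Alder fixture forming one ring:

```r
ring_change(build_rinchi(fixture_reactions()$diels_alder)$rinchi)$ring_count_delta
#> [1] 1
```

A command-line front end mirroring these operations (subcommands
`create`, `decode`, `combine`, `search`, `rings`, `stereo`, `stats`) is
installed at `system.file("cli", "rinchi_tool.R", package = "rinchi")`.

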