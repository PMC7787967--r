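---
title: "The 1:1:1 curation engine: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 1:1:1 curation engine: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(chemregistry)
```

## The identity model

Public chemical data is indexed by three partially redundant identifier
families: CAS Registry Numbers, chemical names, and structures. In a clean
world these would agree; in practice names are reused, deleted CAS RNs
circulate for decades, representative structures get attached to mixtures,
and the three identifiers of a single record routinely point at two or
three different chemicals. The engine's whole design follows from one
invariant, the **1:1:1 rule**: each registered substance has exactly one
active CAS RN (or a minted `NOCAS_#####` placeholder), one preferred name,
and at most one structure, and each of those values is unique across the
registry. The rule is deliberately conservative — it cannot certify
correctness, but any violation of it implies that at least one mapping is
wrong, so violations are never silently repaired: registration refuses
them, bulk loads quarantine them, and list curation bins them for a human.

Three identifier families get first-class types:

* **CAS RN** — three numeric segments `##…##-##-#` (registry part 2–7
  digits, middle part 2 digits, final check digit). The check digit is a
  weighted sum of the preceding digits: weights 1, 2, 3, … assigned from
  the rightmost digit of the middle part leftward, summed and reduced
  modulo 10. This is a bijection in the final digit, so exactly one of the
  ten candidate endings validates for any prefix — a property the test
  suite verifies exhaustively on random prefixes. CAS-shaped strings that
  *fail* the checksum are classified as names, not errors: public lists
  contain malformed registry numbers, and the engine must still ingest
  them as searchable source identifiers.
* **Structure key** — the standard InChIKey of the canonical structure,
  computed through Open Babel. Any system of this kind only needs the key
  to be a stable, order-invariant, stereo-aware hash of structure identity;
  the standard InChIKey is the open, reproducible choice, and every
  contract in the data model depends only on key equality, never on the
  specific hash.
* **Names** — uniqueness is enforced on a normalized form (Unicode NFC,
  case-folded, whitespace collapsed). Punctuation, digits and stereo
  descriptors are preserved: `1,2-` vs `1,3-` and `(R)-` vs `(S)-` name
  different chemicals, so normalization must never touch them. Display
  casing is kept as entered.

Substances, structures and raw source records carry separate identifier
sequences (`DTXSID`, `DTXCID`, `DTXRID`), minted sequentially with no
embedded check digit. A structure may exist without a substance pointing at
it only transiently; a substance may legitimately have *no* structure
(mixtures, polymers, UVCBs — substances of unknown or variable
composition), in which case it participates in CAS and name uniqueness but
not structure uniqueness, and typed relationships
(`component_of_mixture`, `monomer_of_polymer`, `salt_to_parent`,
`representative_structure_of`) link it to structurable relatives.

## Query resolution

`resolve_query()` runs four steps strictly in order and stops at the first
applicable outcome: (1) exact match on an active identifier; (2) reroute
through the deleted-CAS-RN table or the synonym table to a single
substance; (3) an ambiguous synonym returns *all* candidate substances;
(4) not found. Two open points were settled as follows. When the deleted
CAS table and the synonym table disagree about the same query, both
candidates are surfaced as a `multiple` outcome rather than trusting either
table — the engine never guesses. SMILES queries are converted to a
structure key and resolved purely by key equality; a SMILES matching no
registered structure is `not_found` and never falls through to name
matching, because a structure query that accidentally matches a name is
exactly the class of silent mis-mapping the registry exists to prevent. In
`auto` mode only strings containing structural punctuation (brackets,
bonds, ring-closure syntax) are tried as SMILES; plain-letter SMILES such
as `CCO` must be submitted with `type = "smiles"`, a deliberate asymmetry
that keeps short names from being parsed as molecules.

## The sequential quality-filtered load

`autoload_sequence()` models the ingestion of several public databases of
*decreasing curator trust*. Trust is encoded in five quality-control
levels, best first: `DSSTox_High`, `DSSTox_Low`, `Public_High`,
`Public_Medium`, `Public_Low`; quarantined content carries the
out-of-registry marker `Public_Untrusted` and never enters a uniqueness
index. Each database passes three screens:

1. **Internal consistency** — within the database, a record is conflicted
   when its own alternative structure renderings disagree, when its CAS
   maps elsewhere to a different key (or its key to a different CAS), when
   the same CAS appears on both structured and structureless records, or —
   among structureless records — when the CAS↔name pairing is not
   one-to-one. Names of structured records are advisory only: public names
   are too noisy to be uniqueness-bearing at this stage.
2. **Next-level comparison** — each surviving structured record is checked
   against the next (less trusted) database in the chain; a contradiction
   in either direction (CAS → other key, key → other CAS) sets the record
   aside. Records absent from the next level *cannot be evaluated* and
   pass through; the last database has no next level and skips the screen.
3. **Core overlap audit** — records whose CAS or key already occurs in the
   core either agree with the core's mapping (`already_present`, their raw
   name harvested as a `source_name` synonym) or disagree (`conflicted`,
   quarantined). The conflict fraction of the overlap estimates the
   residual mapping-error rate of the incoming database; both the
   CAS-based and the CAS-or-structure overlap denominators are reported
   since the notion of "overlap" is genuinely ambiguous.

Survivors are registered at the database's assigned qc level. Because
names are advisory, a new record can still collide on normalized preferred
name with core content; such collisions are disambiguated
deterministically as `"name (CAS RN)"` with the raw name kept as a
synonym, rather than quarantining a record whose CAS and structure are
perfectly consistent. Each database's load is transactional: a snapshot is
taken first and restored if registration ever leaves the core in violation
of its invariants. Loading is idempotent (re-loading the same chain
registers zero substances) and the final CAS content is invariant to
permuting disjoint, conflict-free databases — only the qc assignment is
order-sensitive, which is the intended semantics of trust ordering.

## List curation

`bin_source_list()` resolves each record's CAS, name and structure key
*independently* against the core and bins records by the pattern of
agreement. A record is auto-mapped only when every identifier it carries
that the core recognizes agrees on one substance; an identifier the core
has never seen is treated as absence of evidence, except that a
present-but-unknown CAS alongside a resolving name (and vice versa) is
flagged (`name_only_hit` / `cas_only_hit`) for curator attention. There is
no "best guess" fallback — the design position is that silent best-guessing
is how public mappings rotted in the first place. After a curator resolves
every record (`map_to`, `register_new`, `reject`, `defer`), re-binning the
same list yields 100% `auto_mapped`, a property the suite tests. Quality
elevation (`elevate_qc()`) is strictly monotone; demotion is refused as a
distinct operation so that accidental downgrades cannot hide in review
workflows.

## Derived structure forms

QSAR models and mass-spectrometry matching want different simplifications
of a registered structure:

* `qsar_ready()` removes counterions (a small, extensible dictionary of
  alkali/alkaline-earth cations, halides, water and common small
  counterions), neutralizes charges, strips stereo descriptors and isotope
  labels, and returns the single surviving organic component. When the
  survivors are all themselves dictionary species (sodium acetate leaves
  only acetate), the largest of them — by average then monoisotopic mass,
  ties broken lexicographically by key — is the parent. A record that
  cannot be reduced to one organic component (a salt of two active
  organics, purely inorganic content) is *excluded* with a reason, never
  truncated to an arbitrary component.
* `ms_ready()` applies the same desalting and stripping but keeps genuine
  mixtures: every distinct surviving component is returned, with duplicate
  components (equal key, e.g. two equivalents of one anion) collapsed, in
  canonical key order.

One consequence of placing common organic counterions in the dictionary is
that a true binary mixture containing, say, acetate desalts to the other
component; mixtures of two non-dictionary organics are preserved. Both
derivations are idempotent.

## Congener enumeration

`enumerate_markush()` materializes a family of chemicals defined by a
scaffold, a single-atom substituent and a range of substitution counts —
the classic example being the polychlorinated biphenyls: biphenyl, Cl,
counts 1–10, exactly 209 distinct congeners. Naively there are
$\sum_k \binom{10}{k} = 1023$ placements, but placements related by a
symmetry of the scaffold are the same molecule. The implementation
computes the scaffold's automorphism group (igraph/BLISS generators,
closed under composition), reduces patterns to orbit representatives, and
then renders each representative as a molfile and deduplicates by
InChIKey — the registry's structure identity remains the final arbiter,
and the symmetry reduction can only merge patterns that are provably the
same molecule. Two numerical details matter:

* *Kekulé symmetry.* Aromatic rings are perceived from the MOL2 rendering
  and aromatic bonds form one bond class; otherwise the alternating
  single/double bonds of a Kekulé structure would spuriously break ring
  symmetry (benzene would lose its 12-fold graph symmetry).
* *Independent counting.* The test suite cross-checks enumeration sizes
  against a Burnside (cycle-index) orbit count over the automorphism group
  enumerated by a different algorithm (VF2 isomorphism search): for
  biphenyl's group of order 8, $\frac{1}{8}\sum_{g}2^{c(g)}$ over the
  cycle counts $c(g)$ on the ten substitutable positions gives 210
  patterns including the empty one, hence 209 congeners.

Enumeration is bounded at 16 positions (exhaustive generation); variable
chain lengths and repeating units are out of scope.

## The synthetic fixtures

Real public-database snapshots are neither redistributable nor stable, so
the test suite runs on seeded synthetic fixtures with a **ground-truth
ledger**: every generated record carries its intended disposition (clean,
internal conflict of either archetype, cross-database contradiction,
core-overlap agreement or conflict), and every pipeline output is compared
against the ledger exactly. Structures come from an internal combinatorial
library of ~540 difunctionalized alkyl chains — chemically dull on
purpose; the fixtures test the conflict *mechanism*, not chemical realism —
and CAS RNs are minted with valid check digits from a reserved
high-numbered registry range that cannot collide with real CAS RNs used in
documentation. Default fixture sizes (60 clean records, 5 internal
conflict pairs, 6 cross-database contradictions, structure fraction 0.8)
were chosen once to mirror, at desk scale, the double-digit conflict
percentages that quality screens typically report when large public
chemical databases are compared; the three-database scenario
(`generate_autoload_fixture()`) uses 40 core + 30/25/20 clean records per
database so that the full pipeline, including every screen, runs in
seconds inside the test suite. What passing these tests shows is that the
filters implement their definitions exactly (they agree with quadratic
brute-force oracles and recover planted rates perfectly); what they cannot
show is how often real databases conflict — that depends on the snapshots
loaded, and the engine reports, rather than assumes, those rates.

## Persistence and other design notes

* The registry is an in-memory environment with hash indexes; persistence
  is a single JSON file (`save_registry()` / `load_registry()`), which
  doubles as the transactional snapshot format. A relational store would
  add a dependency without changing any contract at this scale.
* Registration is check-then-commit: a conflict report implies a
  bit-identical registry, verified in the tests by state comparison.
* Deleted CAS RNs live in their own index and are checked at registration,
  so a new substance can never adopt a CAS RN that historically redirects
  elsewhere.
* The invariant scanner recomputes uniqueness from the substance records
  themselves rather than trusting the lookup indexes, so corruption
  injected past the public API (as the curation-backlog simulations do) is
  detected.
* All randomness in fixtures flows through a single integer seed;
  generation is byte-deterministic given the spec.

## Known limitations

* Name normalization does not attempt synonym chemistry (no
  stereo-descriptor parsing, no systematic-name generation); names are
  identity keys and search redirects only.
* Tautomers are distinct structures (distinct InChIKeys where the standard
  InChI distinguishes them); no tautomer canonicalization is attempted,
  and inorganic/coordination chemistry is keyed as drawn.
* QSAR/MS-ready derivation operates on SMILES semantics; enhanced
  stereochemistry beyond R/S and E/Z is out of scope.
* The Markush module enumerates substitution patterns of a single-atom
  substituent only.
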