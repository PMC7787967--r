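# chemregistry

An R engine for building and maintaining a **curated chemical substance
registry** under the strict *1:1:1 identifier rule*: every substance carries
exactly one active CAS Registry Number (or a `NOCAS_#####` placeholder when
none exists), one preferred name, and — whenever a single defined structure
exists — one structure, each unique across the whole registry. The rule does
not guarantee that a record is correct, but whenever it is violated an
identifier mapping error is virtually guaranteed, which makes it a sharp,
cheap error detector for the notoriously noisy public reservoir of
substance–structure data.

The package is aimed at cheminformaticians and data curators who assemble
chemical lists and databases for structure-based modeling (QSAR) and
non-targeted mass-spectrometry work, where a wrong CAS-to-structure mapping
silently corrupts every downstream data linkage.

## What it implements

* **Identifier layer** — CAS RN validation with the public checksum rule
  (digits of the first two segments weighted 1, 2, 3, … from the rightmost
  digit leftward, summed, reduced mod 10; the result must equal the final
  digit), NOCAS and `DTXRID`/`DTXSID`/`DTXCID` identifier minting, query
  classification and Unicode-aware name normalization.
* **Registry core** — registration transactions that refuse any CAS, name
  or structure collision (including collisions with *deleted* CAS RNs),
  typed substance-to-substance relationships, representative-structure
  repair, four-step query resolution (exact → redirected via deleted CAS RN
  or synonym → multiple for ambiguous names → not found), and an exhaustive
  invariant scanner.
* **Structure identity** — standard InChIKeys (via Open Babel) as the
  structure key; QSAR-ready forms (desalted, stereo- and isotope-stripped,
  neutralized single organic component) and MS-ready forms (same, with
  duplicate mixture components collapsed).
* **Sequential quality-filtered autoload** — loading a chain of source
  databases in decreasing trust order through three screens (internal
  consistency, next-level cross-database comparison, core-overlap audit),
  assigning each loaded record one of five qc levels
  (`DSSTox_High` … `Public_Low`) and quarantining every conflicted record
  as `Public_Untrusted` with full provenance.
* **List curation** — typed conflict binning (`auto_mapped`,
  `cas_name_split`, `deleted_cas_hit`, `ambiguous_name`, …) and curator
  resolution actions with partial-registration support.
* **Markush/congener enumeration** — all distinct substitution patterns of
  a scaffold up to scaffold symmetry, e.g. the 209 polychlorinated
  biphenyls from a single biphenyl + chlorine specification.
* **Seeded fixtures** — synthetic source databases and registries with
  planted conflicts and a ground-truth ledger, used by the property-based
  test suite.

## Worked example

```r
library(chemregistry)

reg <- registry_new()
s <- register_substance(reg, "Bisphenol A", "80-05-7",
                        "CC(C)(c1ccc(O)cc1)c1ccc(O)cc1", qc = "DSSTox_High")
s
#> <substance> DTXSID0000001 | Bisphenol A | 80-05-7 | DTXCID0000001 | DSSTox_High

# the same normalized name under a different CAS RN is refused outright
register_substance(reg, "bisphenol a ", "1675-54-3")
#> <conflict> name_collision with DTXSID0000001

# deleted CAS RNs act as redirecting synonyms
add_deleted_casrn(reg, s$dtxsid, "212837-91-7")
resolve_query(reg, "212837-91-7")
#> <resolution> redirected -> DTXSID0000001 (via deleted_cas)

# a perturbed final digit fails the checksum
validate_casrn("25068-38-5")
#> <invalid CAS RN> 25068-38-5 - rule failed: checksum

# enumerate the polychlorinated biphenyls: 10 ring positions, 1-10 Cl
kids <- enumerate_markush(markush_spec("c1ccccc1-c1ccccc1", "Cl"))
nrow(kids)
#> 209
head(kids, 3)
#>                           key               smiles n_subst positions
#> 1 LAXBNTIAOJWAOP-UHFFFAOYSA-N   Clc1ccccc1c1ccccc1       1         1
#> 2 NMWSKOLWZZWHPL-UHFFFAOYSA-N Clc1cccc(c1)c1ccccc1       1         2
#> 3 FPWNLURCHDRMHC-UHFFFAOYSA-N Clc1ccc(cc1)c1ccccc1       1         3

# QSAR-ready derivation desalts to the organic parent
qsar_ready("CC(=O)[O-].[Na+]")
#> <QSAR-ready> CC(=O)O  key: QTBSBXVTEAMEQO-UHFFFAOYSA-N
```

The 209 rows are the full congener family: each row is one distinct
chlorination pattern of biphenyl, deduplicated by InChIKey so that
symmetric placements (e.g. 2-chloro drawn on either ring) count once.

A command-line interface mirroring these operations is installed as
`exec/chemregistry` (`validate-cas`, `register`, `resolve`, `load-source`,
`curate-list`, `list-overlap`, `enumerate-markush`, `gen-fixtures`,
`check`).

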