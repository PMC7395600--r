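# taxobridge

Taxon-concept curation and translation across biodiversity
monitoring-program checklists.

Regional monitoring programs (Pollard-walk butterfly transects and their
kin) each record data under their own stable species checklist. The same
scientific name can mean different circumscribed taxa under different
authorities, and the same taxon can hide behind different names — so
integrating counts across programs by string matching silently merges
non-equivalent concepts and manufactures spurious zeros. taxobridge
implements a curation system that solves this while letting every program
keep its list:

* a **mapping file** (Darwin Core Taxon style CSV) in which every program
  name is the child of a holder in the program's declared **base
  authority** list, and every holder is the child of a fine-grained
  concept node on a master **switchboard**; authorities that lump several
  taxa under one name get one *duplicated holder* per concept;
* a **translator** that answers "program R wants data for taxon X from
  program D": it ascends the parent chain to the switchboard, descends
  through D's base, and labels the outcome `PM` (perfect), `CM`
  (compatible, different nomenclature or reading), `MM` (donor splits the
  request; all names returned), `CM+` (donor lumps; combinable only
  together with listed receiver siblings) or `Zero` (absent from the
  donor's monitored range), with complexity and asymmetry warning flags;
* a **diff engine** classifying checklist discrepancies into the
  six-type typology (genus / species / spelling / conglomerate /
  unmatched / subfamily) with curator-table support;
* **integration matrices** per species complex, plus a comparison harness
  that certifies the translator against a curated expected matrix;
* the curated ***Celastrina ladon* complex fixture** (7 concepts, 3
  authorities, 10 programs) and a seeded **synthetic network generator**
  with exact ground truth.

The key modelling idea is the split between a name's *occurrence set*
(concepts the program actually monitors under it — what it can donate)
and its *interpretation set* (everything the program's authority files
under the name — what it means when it asks). The two differ whenever an
authority lumps, which is why translation requests are not symmetric and
why the package flags them.

## Worked example

Iowa follows a broad authority and records both *ladon* and *neglecta*
azures under the single name *Celastrina ladon*; Ohio splits them.

```r
library(taxobridge)
m <- celastrina_fixture()

translate(m, "Iowa", "Celastrina ladon", "Ohio")
```

The request returns a multiple match — Iowa must take *both* Ohio taxa:

```
match_type  MM
donor_names Celastrina ladon, Celastrina neglecta
flags       complexity: taxon concept interpretations differ across authorities ...
            complexity: donor separates this request into several taxa; assess compatibility ...
            asymmetry:  reverse request (Ohio 'Celastrina ladon' from Iowa) is CM+, not MM
```

The reverse direction is the lump side of the same relationship: Ohio
asking Iowa gets `CM+` with
`required_receiver_siblings = "Celastrina neglecta"` — Iowa's pooled data
are usable only against Ohio's *ladon* + *neglecta* combined. A concept
the donor never monitors comes back as a presumed absence, not an error:

```r
translate(m, "Colorado", "Celastrina humulus", "Florida")
#> match_type Zero
#> message    There is no match in this list (species presumed absent)
```

The whole complex at once, against the curated expectation:

```r
mx <- build_matrix(m, celastrina_complex_id())
compare_matrix(mx, expected_celastrina_matrix())
#> <matrix_comparison> 126/126 cells agree (100.0%)
```

`format_matrix(mx)` renders the familiar receiver × donor grid
(`*` marks flagged cells), `autoplot(mx)` draws it, and
`tidy()`/`glance()` on a comparison give mismatch rows and the agreement
summary as tibbles.

A shell interface wraps the same functions:

```sh
exec/taxobridge translate --receiver Iowa --taxon "Celastrina ladon" --donor Ohio
exec/taxobridge matrix --complex celastrina-ladon \
    --expected inst/extdata/celastrina-expected-matrix.csv
exec/taxobridge validate --mapping inst/extdata/celastrina-mapping.csv
```

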