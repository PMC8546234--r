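---
title: "Operational principle checks: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational principle checks: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obodash)
```

## The evaluation model

`obodash` evaluates an ontology project against two sources that
deliberately stay separate: the curated **registry record** (who maintains
the ontology, under what license, where it lives) and the **ontology
document** itself (its IRIs, labels, definitions, version header). Each of
the 13 automatable community principles is an operational rule over one or
both sources, returning a status from the ordered vocabulary

```
PASS < INFO < WARN < ERROR      (NA = not evaluated)
```

with human-readable findings and metric counts. A dashboard row is the
vector of the 13 outcomes; its Summary is the worst status in the row, with
`NA` cells excluded. Published dashboards of this kind show binary
pass/fail cells; we keep the graded vocabulary because it preserves
information (an unprobed homepage is not the same as a dead one) and
degrades to pass/fail by thresholding at `WARN`.

Checks never throw on bad input data: a malformed ontology, a missing
license, a dead homepage are all *results*. R errors are reserved for
misuse of the API (unknown principle id, empty relations index, unreadable
path).

## Conventions the checks encode

**Openness (FP1).** Accepted licenses are CC0 1.0 and Creative Commons
Attribution 3.0 and 4.0. "CC BY 3.0 or later" is implemented as exactly
{3.0, 4.0} until later versions are added to the table — an open-ended
regex would silently accept licenses nobody reviewed. Registry and ontology
must state the *same* license; to keep that comparison robust both URLs are
canonicalized first (scheme and host lowercased, `http` upgraded to
`https` and `www.` dropped for `creativecommons.org`, trailing slashes
stripped; the function is idempotent). Label-to-URL correspondence is
case-, hyphen- and whitespace-insensitive, so `"CC-BY 4.0"` and
`"CC BY 4.0"` both match the 4.0 URL: registries in the wild use both
spellings and the distinction carries no information.

**Common format (FP2).** Loadability *is* the test: if the document parses,
it is assumed to be in good format. No profile validation, no reasoning.

**Term IRIs (FP3).** Within the ontology's own namespace
(`http://purl.obolibrary.org/obo/` + prefix), the character after the
prefix must be an underscore and the local id must be all digits.
Annotation properties are excluded (legacy OBO conversions legitimately use
words and hashtags there), and IRIs outside the namespace are skipped
because term reuse across ontologies is encouraged, not penalized. The
canonical prefix defaults to the uppercased registry id and can be
overridden (`preferred_prefix`) for the mixed-case idspaces that exist in
the wild; a prefix matching only case-insensitively is reported as a
violation rather than silently accepted or silently skipped.

**Versioning and maintenance (FP4, FP16).** Both read the same fact: the
version IRI and its optional `YYYY-MM-DD` path segment. A date segment must
be a *real* calendar date — `2021-02-30` does not identify a release; the
parser requires the formatted round-trip to reproduce the segment exactly,
which rejects impossible dates without hand-rolling calendar rules.
Maintenance compares that date with the reference date: within
`warn_years` (default 2) is PASS, within `error_years` (default 3) is
WARN, older is ERROR, with transitions exactly on the calendar-year
boundary (the same month/day `n` years earlier; Feb 29 anchors to Feb 28).
The cutoffs are non-normative — nothing in the principle fixes "timely" —
so they live in the configuration profile. A future-dated release and an
undated version IRI are both WARN: recency simply cannot be assessed.
Because the two checks share one fact, seeding a version-IRI fault moves
both cells; this coupling is intrinsic, not an artifact.

**Definitions and labels (FP6, FP12).** One engine tallies three faults
over all entities except annotation properties: *missing* (no value),
*multiple* (≥ 2 values on one entity), *duplicate* (identical value shared
across entities; every sharing entity is counted). Deprecated entities are
exempt from the missing counter only — they are historical artifacts kept
for identifier stability, and demanding definitions for them generates
noise — but they still participate in multiple/duplicate counting, since a
deprecated term polluting the shared label space is a real fault. Default
severities: duplicate and multiple are ERROR for both checks; a missing
definition is WARN while a missing label is ERROR (an unlabeled term is
unusable, an undefined one merely undocumented). All severities are
overridable via the profile.

**Relations (FP7).** Properties are classified against a shipped Relations
Ontology index (IRI + label, two-column TSV): an IRI in the index is reuse;
a property in the ontology's own namespace is fine unless its lowercase
label exactly shadows an RO label (the finding suggests the RO IRI); any
other property is flagged. Findings are WARN-only: the principle asks for
comparison and encouragement, and states no hard failure condition. An
empty index is a configuration error because the check would be vacuous.

**Registry-side checks (FP5, FP8, FP9, FP11, FP20).** Scope compares the
`domain` tag by case-insensitive exact string equality against active,
non-obsolete peers — a tag comparison, nothing semantic — and reports
sharing ontologies as INFO. Documentation requires homepage and
description; resolution is probed only online (HEAD with GET fallback, at
most 5 redirects, 10 s timeout, behind a function contract that tests stub)
and fails at HTTP status ≥ 400, with transport failures treated as
non-resolution. Users, authority and responsiveness reduce to the presence
and well-formedness of `usages`, `contact` and `tracker`.

## The registry rule catalogue

The minimal registry model has 11 fields; the validator implements 12 rules
because the id field carries two independent assertions (lowercase;
alphanumeric without spaces) that can fail independently — `"OBI 2"`
genuinely breaks both. License label/URL correspondence fires only when the
URL is one of the recognized license URLs; judging an unrecognized URL is
the openness check's job, and double-reporting would break the
one-fault/one-violation property the test matrix relies on. An empty
products list is the products-format rule's ERROR: the model presumes at
least the canonical `id.owl` artifact. Unknown registry fields are always
preserved, never rejected — real registry files carry far more than the
minimal model.

## Document I/O

Ontology documents are consumed at the RDF fact level. Both serializations
feed one triple table into one fact builder, which guarantees the two
readers agree: entities come from declaration axioms (plus subjects of
label/definition annotations in sloppy inputs, defaulted to class), blank
nodes are never entities, deprecation is the standard OWL annotation with
literal `true`, and a malformed header with several version IRIs keeps the
first in document order with a loader warning — checks must still run on
imperfect inputs. The RDF/XML reader walks the striped syntax via xml2; the
Turtle reader is purpose-built and covers the subset release files use
(prefix declarations, IRIs, prefixed names, `a`, quoted literals with
escapes, language tags and datatypes, `;`/`,` lists, comments). Blank-node
property lists `[...]` and collections `(...)` are outside the subset and
surface as a format error rather than silently dropped triples. OBO
flat-file format is out of scope: dashboards consume released `.owl`/`.ttl`
products.

## The fixture generator

Test inputs are generated, not stored. A fixture spec (idspace, entity
counts, seed) produces a registry record, an ontology document, two peer
registry entries (domains "anatomy" and "health") and the expected outcome
map. The default fixture — 5 classes of which one deprecated, one reused RO
property, one annotation property, a CC BY 4.0 license stated identically
on both sides, a release dated 60 days before the reference date of
2021-05-01 — passes everything except FP8, which is INFO because the
default context is offline. The seed varies only surface wording (via an
integer mixer, never R's global RNG state), so identical specs are
byte-identical and different seeds are structurally identical; sizes are
deliberately small since every check is per-entity linear and nothing new
is learned from volume.

Each of the 24 catalogue kinds seeds exactly one fault. For 21 kinds the
seeded fixture flips exactly its target principle's cell. Three kinds
cannot be single-cell by construction, and their expected maps say so: a
truncated file (`malformed_file`) fails every ontology-dependent check, and
the two version-IRI kinds move FP4 and FP16 together because the checks
share the version IRI. Homepage resolution faults are realized through the
stubbed prober contract — the generator never touches the network.

What the fixtures do *not* emulate: import closures, reasoning-dependent
faults, OBO-format products, blank-node axioms, non-ASCII idspaces, and
randomly fuzzed malformed RDF (one deterministic truncation case stands in
for the malformed class). Passing the suite therefore demonstrates the
checks' decision logic, not robustness against every serialization corner
of real released ontologies.

## Verification approach

The central oracle is self-consistency: for every catalogue kind, running
the full suite on the seeded fixture must reproduce the generator's
expected map cell by cell. Independent cross-checks back the two places
where logic could drift silently: the definition/label counters are
compared against a brute-force per-entity tally (pairwise sharing loops,
written independently of the engine) on 100 randomly generated documents of
up to 20 entities, and the version-date parser is audited against explicit
month-length/leap-year arithmetic, including the `2021-02-30` rejection.
End-to-end determinism is checked at the byte level: with a pinned
reference date and offline context the whole pipeline is a pure function of
its input files, which is also why timestamps live only in the run
metadata.

## Limitations

Checks run one ontology at a time; cross-ontology consistency is out of
scope. Conformance statistics over a live registry depend on the registry's
state at a point in time and are not reproducible from this package alone —
the suite is designed so that its own correctness does not depend on them.
Scope comparison is string equality, not semantics; relations coverage is
only as good as the shipped RO index; and the recency cutoffs encode a
review convention, not a community norm.
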