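# obodash

Automated principle checks for communities of interoperable biomedical
ontologies, in the style of the OBO Foundry dashboard.

Federated ontology collections (the OBO Foundry being the canonical case)
govern themselves through shared principles: an ontology must be openly
licensed, available in a common format, use well-formed term IRIs, release
dated versions, state its scope, define and label its terms, reuse shared
relations, be documented, used, maintained and responsive. Reviewing these
principles by hand does not scale and is hard to standardize. `obodash`
implements each automatable principle as an operational check over two
inputs — the curated registry metadata record for an ontology and the
ontology document itself — and assembles the outcomes into a dashboard grid
with per-ontology drill-down reports.

## What is checked

Two layers:

**Registry validation** — 12 rules over the minimal registry model (title,
id, homepage, contact, products, description, license, activity status,
obsoletion status). Each broken rule yields one violation record with a
stable rule id; a fully conformant record yields none.

**Principle checks** — the 13 automatable Foundry principles, each producing
a status in the ordered vocabulary `PASS < INFO < WARN < ERROR` (plus `NA`
for unchecked rows):

| Principle | Operational check |
|---|---|
| FP1 Open | registry license is CC0 1.0 / CC BY 3.0+ and identical (after URL canonicalization) to the ontology's `dcterms:license` annotation |
| FP2 Common Format | the document loads (RDF/XML or Turtle); loadability is the test |
| FP3 URI/Identifier Space | every class/relation IRI in the ontology's namespace is OBO PURL base + prefix + `_` + numeric local id; annotation properties excluded, foreign term reuse skipped |
| FP4 Versioning | a version IRI is present; a dated `YYYY-MM-DD` path segment identifies the release |
| FP5 Scope | a registry `domain` tag exists; shared domains are reported with the sharing ontologies |
| FP6 Textual Definitions | no missing, multiple or duplicate definitions (deprecated terms exempt from the missing count) |
| FP7 Relations | object/data properties reused from the Relations Ontology; local label shadowing and foreign properties flagged |
| FP8 Documentation | `homepage` and `description` present; online, the homepage must not return HTTP ≥ 400 |
| FP9 Plurality of Users | non-empty `usages` |
| FP11 Locus of Authority | a contact with one well-formed name and email |
| FP12 Naming Conventions | exactly one unique `rdfs:label` per entity |
| FP16 Maintenance | dated release within the configured recency cutoffs (2 / 3 years by default) |
| FP20 Responsiveness | a URL-shaped issue `tracker` |

FP10 (Commitment to Collaboration) cannot be automated and appears nowhere.
A row's Summary is the worst status across its cells.

Everything runs offline by default; homepage resolution is only probed when
explicitly requested, through a stubbable prober contract.

## Worked example

The package ships a deterministic fixture generator that produces a
registry record, an ontology document, and the expected outcome of every
check — clean, or with exactly one named fault seeded:

```r
library(obodash)

fx  <- generate_fixture(fixture_spec(violations = "def_duplicate"))
row <- evaluate_fixture(fx)
print(row)
#> <dashboard row> exf summary: ERROR
#>   FP1=PASS FP2=PASS FP3=PASS FP4=PASS FP5=PASS FP6=ERROR FP7=PASS
#>   FP8=INFO FP9=PASS FP11=PASS FP12=PASS FP16=PASS FP20=PASS

print(row$results$FP6)
#> [ERROR] FP6 (Textual Definitions)
#>   - duplicate definition (2): http://purl.obolibrary.org/obo/EXF_0000001,
#>     http://purl.obolibrary.org/obo/EXF_0000002; make each definition distinct
#>   metrics: missing_definition=0, multiple_definitions=0, duplicate_definition=2
```

The seeded duplicate definition turns exactly the FP6 cell red (FP8 is INFO
because the offline run does not probe the homepage), and the finding names
the offending terms with a fix suggestion. On the registry side:

```r
e <- parse_registry(text = fx$registry_yaml)[[1]]
e$id <- "OBI 2"
for (v in validate_entry(e)) print(v)
#> [ERROR] id_lowercase (id): id 'OBI 2' must be lowercase
#> [ERROR] id_characters (id): id 'OBI 2' must be alphanumeric with no spaces
```

A full pipeline run takes a registry file and a directory of ontology
documents and writes `dashboard.html` / `.json` / `.tsv` plus
`reports/<id>.html` per ontology:

```sh
Rscript inst/cli/obodash.R dashboard \
  --registry registry.yml --ontologies ontologies/ --out dash \
  --today 2021-05-01
```

The exit status is nonzero exactly when some ontology has an ERROR-level
finding, which makes the tool usable as a CI gate.

## Package layout

- `R/registry.R` — registry parsing, serialization, the 12-rule validator
- `R/ontology-read.R`, `R/ontology-write.R`, `R/ontology-facts.R` — OWL
  document I/O at the RDF fact level (RDF/XML via xml2, a purpose-built
  Turtle reader) and fact extraction
- `R/checks.R`, `R/check-context.R` — the 13 principle checks and their
  context/configuration
- `R/reporting.R` — grid assembly, HTML/JSON/TSV renderers, detail pages
- `R/fixtures.R` — the deterministic fixture generator and violation
  catalogue
- `R/cli.R`, `inst/cli/obodash.R` — pipeline commands and the shell wrapper
- `vignettes/principle-checks.Rmd` — the methods vignette: model,
  conventions, tunables and limitations
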