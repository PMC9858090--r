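---
title: "Mining microbial habitat, phenotype, and use relations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining microbial habitat, phenotype, and use relations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habmine)
```

## The problem and the data model

Descriptions of where microbes live, what traits they show, and what they
are used for reach the literature and the databases as free text. To make
them searchable at any level of generality, `habmine` normalizes every
statement onto two controlled references and stores it as one of three
typed relations:

* **lives_in** — taxon × habitat concept,
* **exhibits** — taxon × phenotype concept,
* **studied_for** — taxon × use concept.

The concept side is a three-branch ontology (habitat, phenotype, use) in
OBO flat-file dialect. Branches are disjoint by construction: a concept
reachable from two branch roots is rejected at parse time. The ontology is
a DAG (multiple `is_a` parents are legal); the taxonomy, in NCBI-taxdump
dialect, is a strict tree in which every node carries exactly one
scientific name plus any number of synonyms, vernacular names, and — for
strains — culture-collection catalog names. Because "microorganism" is a
phenotypic notion with no single ancestor clade, the working taxonomy is
the union of user-selected high-level subtrees re-rooted under a reserved
synthetic super-root (`select_microbial_subtree()`).

## Extending the taxonomy with strain catalogs

Strain coverage in general-purpose taxonomies is thin, so catalog entries
are merged in by name matching with three outcomes: (i) if any variant of
an entry's designations equals an existing strain-rank name, the entry's
names become synonyms of that strain and the identifiers are treated as
equivalent; (ii) otherwise, if the species (or its genus token) is
identifiable, a fresh strain node (`EXT000001`, ...) is created under it;
(iii) otherwise the entry is left out. Variants close over the common
typography of collection numbers — spacing and hyphenation between code and
number, case, quotes, superscript markers — via a single comparison key
(lower-cased, non-alphanumerics removed). Entries are processed
sequentially so a strain listed by two catalogs merges rather than
duplicating; an entry whose names hit two distinct strain nodes is recorded
as ambiguous and left out, since silently picking one would corrupt the
equivalence table.

## Entity recognition

Taxon names are regular enough for lexicon matching: every name of every
node is indexed under a token-normalized key, and multinomial scientific
names get generated genus-initial variants (*Bacillus subtilis* → *B.
subtilis* and *B subtilis*; only the genus token is abbreviated, so
trinomials keep their epithets). Matching is longest-first within
sentences; the genus initial is compared case-sensitively (so sentence-
initial "It" cannot hit a genus abbreviation) while the remainder is
case-insensitive. A key resolving to several taxa prefers scientific over
synonym over vernacular over catalog names; remaining ties are dropped
rather than guessed. Strain designators adjacent to a species mention (or
introduced by the word "strain") are resolved against catalog names of
strains below that species through the same variant key; an unresolvable
designator keeps the mention linked to the species, which loses strain
precision but never invents a node.

Habitats and phenotypes are too variable for lexicon lookup, so candidate
terms come from a deliberately small self-contained chunker: maximal runs
of adjectives and nouns (closed-class words and determiners excluded,
internal hyphens kept), one optional "of" attachment, the head at the
rightmost noun before the "of" (English compounds are right-headed:
"milk" heads "dairy cow milk"). Suffix sub-chunks are emitted alongside
each maximal chunk because the ontology may name the embedded term, and
components of hyphenated compounds are emitted so adjectival phenotype
coordinations ("mesophilic-thermophilic") surface as two candidates. Word
classes come from a closed-class list plus suffix heuristics — a declared
approximation of a full term extractor, not a statistical tagger.
Candidate terms overlapping a taxon mention are discarded. Use mentions
are exact, case-insensitive matches of use-branch labels *and* synonyms
(matching synonyms too is a recall-oriented choice the interface makes
configurable by editing the ontology, and the exactness keeps the use
layer high-precision while it matures).

## Head-anchored normalization

A candidate term maps only to concepts with a label or synonym sharing its
syntactic head; each such pair is scored by the Jaccard index of word
sets, and the concept's score is its best label's score. Word comparison
inside the score is case-folding plus plural-s stripping, nothing else: no
stemming and no stop-word removal, so the computation is transparent and
reversible, and the head always sits in both sets. A term whose head
matches no label head is ignored — mapping "stainless steel" anywhere
would be worse than mapping it nowhere. Equal scores break toward the
candidate with fewer label tokens (the tighter fit), then the smallest
concept id; both rules exist purely to make results deterministic and
testable. Overlapping same-branch entities (a sub-term versus its
enclosing term) resolve by score, then span length, then position — which
is what lets an exact embedded label ("cow milk" inside "frobby cow milk")
beat its diluted enclosing term. Declarative post-hoc heuristics (drop or
remap by surface/sentence pattern) handle recurring ambiguities as data,
not code.

## Relation extraction

Two entities are linked when they occur in one sentence and the sentence
contains a trigger expression for the relation type ("isolated from" for
lives_in). Extraction is a cross product over the sentence's taxa and
branch-matching objects with no syntactic attachment — a recall-oriented
rule whose characteristic error mode (every taxon of an enumeration gets
every coordinated phenotype) is reproduced deliberately and verified in
the tests, because it is a well-known property of recall-oriented co-occurrence systems.
The trigger list ships as configuration; `exhibits` additionally fires on
a copular verb or a culture/strain noun phrase when the sentence holds a
phenotype term, since adjectival phenotype attributions rarely carry a
dedicated verb. Whether a trigger must lie *between* the entities is left
open by the sentence-containment rule; we require containment only and
note the ambiguity. Pronoun ("it", "they") and sortal ("this bacterium")
anaphora are resolved to the nearest preceding taxon mention within a
2-sentence window (configurable); plural anaphors collect every taxon of
the nearest taxon-bearing sentence. Unresolvable anaphors are dropped.

## Structured sources

Sequence records pass a four-clause filter: a 16S rRNA feature (matched on
gene or product, since annotation practice varies — the code logs which
fired), length ≥ 800 bp (the threshold is inclusive: a "minimum size of
800" admits 800), a non-empty isolation source, and an organism inside the
selected microbial subtree. Fielded catalog records route through YAML
field mappings (taxon/strain/habitat/ignore per field) so adding a source
is a configuration change; geographic fields map to ignore because mixed
address/landscape/country content needs analysis this version does not
attempt. Relation extraction is skipped for structured records — the
taxon-habitat pairing is the record — and structured sources feed habitats
only. Habitat field text still runs through term extraction and
normalization, one lives_in per normalized concept.

## Fusion, indexing, and queries

Relations deduplicate per source — never across sources, so source
complementarity stays measurable — into records carrying their evidence
list and count. The store materializes (entity, ancestor) closure pairs
for both references, making every record retrievable at its concept/taxon
and all ancestors ("hierarchical paths"). Queries are boolean trees over
taxon/habitat/phenotype/use/QPS/source leaves with descendant expansion on
both sides, answered with per-leaf supporting records, and exportable as
RFC-4180 CSV. Taxon expansion runs over the merged (extended) tree, so
catalog-derived strain nodes are retrieved uniformly with original nodes.
The store also computes the profile tables used to sanity-check content:
per-source × per-type counts, subject rank bands, top-level habitat
volumes, habitat frequency versus taxon diversity, and the phenotype
co-occurrence matrix (Jaccard between taxa sets), whose diagonal dominance
is a useful global consistency indicator.

## Synthetic references and gold corpora

The generators exist to make the pipeline measurable, not to imitate any
particular corpus. `make_toy_references()` builds a three-branch ontology
with the heavy habitat skew of real microbial vocabularies (roughly
70/20/10 across habitat/phenotype/use), habitat concepts as modifier
chains over shared head nouns (which is exactly the structure head-anchored
mapping must handle), phenotypes with noun labels plus adjectival synonyms,
and a taxonomy down to strain rank with catalog names. All words are
pronounceable nonce words drawn without replacement and screened against
the chunker's closed-class and suffix heuristics, so fixture vocabularies
cannot collide with template filler — that disjointness is what makes
perfect recovery a designed property rather than luck.
`make_gold_corpus()` assembles documents from nine templates (trigger
sentences, genus abbreviations, strain designators, trigger-free
distractors, pronoun and sortal anaphora, 3-taxon coordinations with
hyphenated phenotype pairs, use and copular-exhibits sentences) and records
every span at generation time.

What passing means, and what it does not: precision = recall = 1 on an
in-grammar corpus shows the implementation matches its own declared rule
set exactly — no more. Real abstracts contain constructions the grammar
does not license (long-distance relations, unseen name typography,
ambiguous heads), so real-corpus recall will be lower; the distractor and
out-of-grammar tests show such misses are detected and itemized rather
than hidden.

## Numerical and procedural choices

* Offsets are 0-based, half-open, character positions; every mention's
  surface must equal the document slice at its span (fuzz-tested).
* Scores lie in (0, 1]; 1 iff token sets are equal. Jaccard on an empty
  set is an error, not 0.
* Determinism everywhere: sorted group-bys, lexicographic tie-breaks, one
  seeded RNG stream per generator call (the global RNG state is saved and
  restored). Identical inputs give byte-identical store dumps.
* Fresh extension taxids are a prefixed counter disjoint from input
  namespaces.
* Degenerate inputs: empty corpora yield empty stores with vacuous
  precision defined as 1; empty rule sets are identities; an empty strain
  name has no variants.
* Problem sizes in the tests and the acceptance script (fixture ontologies
  ≤ 500 labels, stores ≤ 1,000 records, 200-document gold corpora, ≥ 200
  random query trees) were chosen as the smallest sizes at which every
  code path — DAG closure, per-source merging, descendant expansion, all
  nine templates — is exercised repeatedly.

## Known limitations

* The chunker is a rule approximation; it does not attempt statistical
  tagging or parsing, and its word classes are heuristic.
* Relation extraction has no argument attachment; the cross product
  over-generates on enumerations by design.
* Use-entity recognition is exact-match only.
* Non-English field content, obsolete ontology terms, and taxdump
  merged/deleted-node reconciliation are out of scope.
* The GenBank reader covers the qualifier subset needed for ingestion
  (LOCUS length, accession, source qualifiers, rRNA product), not the full
  flat-file grammar.
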