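---
title: "Extracting miRNA-disease associations from text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting miRNA-disease associations from text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdex)
```

## The extraction problem

Most newly reported microRNA (miRNA)-disease associations exist only as
sentences in the biomedical literature. Turning them into database-ready
facts requires three coupled steps at sentence level:

1. **Named entity recognition (NER):** find miRNA and disease mentions as
   typed character spans.
2. **Entity linking (EL):** normalize mentions to registry identifiers —
   miRBase mature accessions (`MIMAT...`) for miRNAs and MeSH descriptors
   (`D...`) for diseases.
3. **Relation extraction (RE):** decide, for each (miRNA, disease) mention
   pair in a sentence, whether the sentence asserts an association.

`mirdex` implements this workflow end to end: corpus readers and writers,
a rule grammar and linker for miRNA names, a trainable IOB tagger and a
dictionary MeSH linker for diseases, a distant-supervision corpus builder,
an entity-masked relation classifier with single-task (STM) and multi-task
(MTM) training modes, evaluation utilities, and a batch inference stage
with confidence filtering and novelty comparison against a reference
association database.

The working assumption throughout is that associations are expressed
within one sentence. Cross-sentence assertions are invisible to the
pipeline; this is a known limitation shared by sentence-level relation
extractors generally, and the main reason recall against full-text
curation can lag.

## Rule-based miRNA recognition and normalization

miRNA nomenclature is unusually regular, which makes a grammar both
precise and auditable. A mention must contain a family keyword (`miR`,
`mir`, `miRNA`, `microRNA`, `let`, `lin`) followed by a number, with
optional species prefix, letter suffix, paralog index, and arm (`-5p`/
`-3p`):

```{r}
str(parse_mirna_name("hsa-miR-501-3p"), give.attr = FALSE)
```

Because a number is mandatory, generic mentions ("miRNAs", "microRNA")
and gene-like symbols ("GFAP", "Stat3", "BRCA1") never match. Enumerations
such as `miR-200b/c` expand into one mention per alternative, sharing the
numeric stem.

Normalization is a pure lexicon lookup on the canonical serialized name
with three defaulting rules, each configurable:

* **Species** defaults to `hsa` (human) when the mention has no prefix;
  the extraction target is human disease.
* **Arm**: a mention without `-5p`/`-3p` resolves to the armless mature
  name when the lexicon has one (`hsa-miR-133b`), otherwise to the `-5p`
  mature by default. The published worked examples map the arm-less
  mention `let-7b` to the `-5p` accession, which fixed this default;
  `arm_policy = "both"` returns the full arm inventory instead.
* **Precursor**: the lowercase `mir-` spelling is looked up among
  precursor (`MI...`) names first and falls through to the mature table.

Unknown names yield an empty result — the linker never guesses, so an
unmapped mention can be counted and audited downstream rather than
silently mislinked.

## Disease linking

Disease name variation is too irregular for a grammar, so disease NER is
either model-based (the IOB tagger below) or dictionary-based, and linking
is a dictionary lookup with case/punctuation folding plus in-document
abbreviation expansion: when a document defines an abbreviation with the
`"temporal lobe epilepsy (TLE)"` pattern, later occurrences of the short
form inherit the long form's descriptor. This dictionary linker is a
deliberately simple, fully offline component; the linker interface (a
function from mentions to mentions with identifiers) accepts any
replacement normalizer.

## The trainable encoder

Both the tagger and the relation classifier consume a shared encoder
contract: text in, one vector per subtoken out. The package ships a small
trainable encoder designed to run on one CPU in seconds to minutes:

* a fixed wordpiece-like subtokenizer (case-folding, splitting at hyphens,
  chunking to four characters) over a hashed vocabulary (521 ids by
  default, two reserved for the entity placeholders);
* subtoken embeddings (width 24), a context-window layer concatenating the
  previous/current/next embedding, and two dense `tanh` layers (widths 32
  and 32);
* explicit analytic gradients (verified against finite differences in the
  test suite) and Adam updates.

All training entry points are deterministic under `config$seed` and
restore the caller's RNG state. Any other encoder honoring the contract —
including a large pretrained transformer — can be substituted behind the
same training and prediction functions; nothing downstream depends on this
particular architecture.

**Pooling.** For sentence classification the per-subtoken vectors are mean
pooled by default (`pooling = "first"` is available). A first-position
("CLS"-style) summary is only informative when an attention mechanism can
move sentence content into that position; a windowed encoder has no such
mechanism, so mean pooling is the sensible default here.

## Sequence tagging

Token labels follow the IOB scheme (`O`, `B-class`, `I-class`). Three
conventions keep the pipeline total and lossless:

* **Subtoken alignment**: the first subtoken of a token carries the
  token's label; continuation subtokens carry an `IGNORE` mark excluded
  from the loss and from decoding. This is the standard alignment for
  wordpiece NER.
* **Repair**: an `I-x` with no legal predecessor is promoted to `B-x`, so
  decoding never fails, including on raw model output.
* **Truncation**: sequences beyond `max_length` subtokens are truncated
  with a warning counter (no sliding windows — abstract sentences fit
  comfortably in the default 96).

Evaluation is at entity level (exact span + class match), with micro
scores pooling true/false positives and negatives across classes and the
0/0 precision-recall convention reported as 0.

## Distant supervision

Manual relation annotation is expensive; the corpus builder instead
aligns annotated sentences with knowledge-base triples (miRNA, disease,
PMID):

1. annotate documents with both entity detectors and keep only sentences
   containing at least one miRNA and one disease mention;
2. sentences with exactly one mention of each class are auto-labeled:
   **positive** iff the normalized pair occurs in the KB for that
   document's PMID, otherwise a closed-world **negative candidate**
   (flagged in provenance for optional review);
3. sentences with multiple miRNA or disease mentions, or with an
   unnormalizable mention, are never auto-labeled — they enter a curation
   queue with a machine-readable reason.

Negative generation is the open design point here: co-occurrence absent
from the KB does not prove non-association. PMID-scoped matching (the
default) is stricter and less noisy than global pair matching, which is
available as `scope = "global"`. The accounting invariant — every kept
sentence becomes exactly one instance or one queue item — is enforced and
tested, so corpus sizes always reconcile.

## Entity-masked relation classification

Each candidate pair becomes one instance in which the two mentions are
replaced by the atomic placeholders `@MIRNA$` and `@DISEASE$` (other
mentions stay verbatim), so the classifier sees the assertion context, not
the identity of the entities — a standard guard against memorizing
frequent pairs. Per sentence, the number of instances is exactly
`#miRNA x #disease` mentions, and provenance reconstructs the original
sentence.

The classifier is a single linear head over the pooled encoder output,
trained with cross-entropy: two logits + softmax by default, or a single
logit through a sigmoid (`head = "sigmoid1"`). The positive-class
probability is the confidence score used downstream; the high-confidence
cutoff of 0.9 is **inclusive** (a score of exactly 0.9 is kept).

In multi-task mode one encoder is shared by several binary tasks, each
with its own head; batches mix tasks in proportion to corpus size within
each epoch (seed-controlled), which prevents a large auxiliary corpus from
dominating updates. Whether per-task losses should instead be alternated
in blocks is genuinely unsettled; proportional mixing was chosen as the
least surprising scheduler and is confined to one function. The returned
classifier always scores with the primary head.

Hyperparameter search is an interface (suggest / report / prune): the
shipped backend is seeded random search with a median pruner on
intermediate reports, and any Bayesian optimizer can be dropped in behind
the same contract. Pruned and failed trials are logged and never returned
as best.

## Evaluation choices

* **AUROC** is computed from ranks (Mann-Whitney), with ties counted one
  half; the test suite pins it to a brute-force O(n^2) concordance oracle
  to 1e-12.
* **AUPR** is step-wise average precision, not trapezoidal interpolation,
  which avoids the optimistic bias of interpolating precision between
  recall points; it is invariant under monotone score transforms.
* **Cross-validation** is stratified on the binary label, deterministic
  per seed, and reports mean and standard deviation over folds.

## What the synthetic fixtures do and do not show

The generator emits documents built from the template
`"X <cue> in patients with Y"`, with synthetic miRNA names
(`miR-9001-5p`, ...) and diseases (`synthetic cortical syndrome`, ...)
drawn from lexicon-backed vocabularies, a knowledge base consistent with
the planted positives, and a configurable fraction of three-miRNA
enumeration sentences. The positive/negative signal is **lexical** (cue
phrases, disjoint by construction), chosen deliberately so that even the
small encoder can separate the classes quickly and learning-sanity
thresholds are stable across seeds.

Default study conditions: 50 documents of 3 sentences for the
distant-supervision checks; 170 documents (about 460 labeled single-pair
instances, 400 train / 60 held out) for classifier training; an
80-document auxiliary corpus for the multi-task run; 12 epochs, batch 16,
learning rate 0.01. On these conditions the held-out AUROC of the
single-task classifier reaches the high nineties within seconds on one
CPU, and the multi-task variant stays within 0.05 of it.

Passing these tests demonstrates that the machinery is correct — masking,
training, scoring, accounting, and the distant-supervision logic — not
that the small encoder matches transformer-scale accuracy on real
abstracts, where the association signal is syntactic and long-range
rather than lexical. Real-literature performance requires fine-tuning a
pretrained biomedical encoder behind the same contract, on the real NER
corpora and a curated relation corpus.

## Numerical and degenerate-input conventions

* All character offsets are 0-based, half-open, sentence-relative; every
  reader re-validates that mention surfaces equal their text slice.
* Stratified splitting uses largest-remainder allocation per label, so
  proportions hold within one instance per split; a label rarer than the
  number of splits is an error, not a silent empty stratum.
* `epochs = 0` returns an untrained model (near-chance scores) rather
  than an error, which gives tests an honest baseline.
* Ontology subclass expansion uses a visited set, so cyclic mapping rows
  terminate; reference pairs whose identifiers cannot be bridged to MeSH
  are reported in an `unmapped` bucket, never dropped.
* Sentence segmentation is rule-based (sentence punctuation plus an
  abbreviation blacklist including `Fig.`, `et al.`, species
  abbreviations; a sentence may open with a lowercase miRNA-style token
  such as `miR-21`) and pluggable; corpora read from annotated files keep
  their given boundaries and are never re-split.

## Known limitations

* Sentence-level scope misses cross-sentence and table-borne assertions.
* The dictionary disease linker resolves only exact folded matches and
  locally defined abbreviations; it has no semantic similarity component.
* The rule grammar does not attempt cross-species orthology or miRBase
  version migration.
* Closed-world negatives inherit knowledge-base incompleteness; the
  provenance flag exists precisely so they can be audited.
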