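# mirdex

Sentence-level text mining of **miRNA–disease associations** from
biomedical literature, for curators and bioinformaticians who need to keep
association databases current without reading every new abstract.

The pipeline mirrors how such facts are expressed in papers: within a
sentence, a miRNA mention and a disease mention, plus an assertion
connecting them. `mirdex` implements the three coupled tasks:

* **NER** — miRNA mentions via a rule grammar over the miRBase
  nomenclature (`[species-]FAMILY-NUMBER[letter][-paralog][-5p|-3p]`);
  disease mentions via a trainable IOB sequence tagger or a dictionary
  scanner.
* **Entity linking** — rule-based normalization of miRNA names to miRBase
  mature accessions (`MIMAT...`, with species/arm/precursor defaulting
  rules) and dictionary linking of disease terms to MeSH descriptors
  (`D...`), including in-document abbreviation expansion
  ("temporal lobe epilepsy (TLE)").
* **RE** — each candidate pair is turned into an *entity-masked instance*
  (`"Overexpression of @MIRNA$ inhibited ... @DISEASE$ ..."`) and scored
  by a linear head over a pooled, trainable text encoder:
  P(association | sentence) = softmax(W·pool(encoder(x)) + b). Training
  runs in single-task (STM) or multi-task (MTM) mode, where MTM shares
  one encoder across several task heads.

Training data is built by **distant supervision**: sentences that contain
exactly one miRNA and one disease mention are auto-labeled positive iff
the normalized pair occurs in a knowledge base for that PMID (negative
candidates otherwise); multi-mention or unlinkable sentences go to a
curation queue, never into the training set. At inference time,
associations classified positive with confidence ≥ 0.9 (inclusive) and
with both entities normalized are emitted as `(MIMAT, MeSH)` records,
deduplicated to unique pairs, and compared against a reference database
after disease-ontology subclass expansion to find novel associations.

The package ships a small trainable encoder (hashed subtoken embeddings,
a context-window layer, two dense tanh layers, analytic gradients) that
fine-tunes in seconds on one CPU; any encoder honoring the
text → per-subtoken-vector contract, including pretrained biomedical
transformers, can be substituted behind the same functions. A
synthetic-fixture generator produces reproducible corpora, lexicons and
knowledge bases with known ground truth. See the methods vignette
(`vignettes/mirdex-methods.Rmd`) for the design rationale.

## Worked example

```r
library(mirdex)

# lexicons: miRBase-style names -> accessions, MeSH terms -> descriptors
lex <- generate_lexicons()

txt <- paste("Overexpression of let-7b inhibited hippocampal glial cell",
             "activation, inflammatory response and epileptic seizures by",
             "targeting Stat3.")
ms <- annotate_mirna(txt, lex$mirbase)
ms[[1]]
#> <mirna [18,24) 'let-7b' MIRBASE:MIMAT0000063>
ds <- detect_disease_mentions(txt, lex$mesh)
ds[[1]]
#> <disease [96,114) 'epileptic seizures' MESH:D012640>
```

The arm-less mention `let-7b` resolves to the `-5p` mature accession
`MIMAT0000063` (the documented arm default), and the disease term maps to
the seizures descriptor `D012640`. Masking the pair produces the
classifier input:

```r
s <- sentence(txt, mentions = c(ms, ds))
inst <- make_instances(s, doc_id = "32648622")
inst[[1]]$masked_text
#> [1] "Overexpression of @MIRNA$ inhibited hippocampal glial cell
#>      activation, inflammatory response and @DISEASE$ by targeting Stat3."
```

Fine-tune the single-task classifier on the synthetic separable corpus
and score held-out instances:

```r
corpus <- generate_corpus(generator_config(n_documents = 170, seed = 7))
instances <- generate_separable_instances(corpus)
clf <- fine_tune_stm(instances[1:400], config = tiny_encoder_config(seed = 7))

pos <- masked_instance("@MIRNA$ was upregulated in patients with @DISEASE$.")
neg <- masked_instance("@MIRNA$ was unchanged in patients with @DISEASE$.")
round(predict_proba(clf, list(pos, neg)), 3)
#> [1] 1 0

labs <- sapply(instances[401:460], function(i) i$label)
auroc(labs, predict_proba(clf, instances[401:460]))
#> [1] 1
```

The positive-cue sentence scores ~1, the negative-cue sentence ~0, and
held-out AUROC on the synthetic corpus is 1.0 — the corpus is separable
by construction, so this checks the machinery, not real-literature
accuracy (see the vignette for what these fixtures do and do not show).

A thin CLI over the same functions lives at
`inst/scripts/extract_associations.R` (train on a relation TSV, extract
associations from plain-text or PubMed-XML documents).

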