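<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>36454178</PMID>
      <Article>
        <ArticleTitle>Synaptosomal miRNA profiling (synthetic abstract fixture).</ArticleTitle>
        <Abstract>
          <AbstractText>The miR-501-3p, miR-502-3p, and miR-877-5p were identified as potential synaptosomal miRNAs upregulated with disease progression based on AD Braak stages.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>32648622</PMID>
      <Article>
        <ArticleTitle>let-7b in temporal lobe epilepsy (synthetic abstract fixture).</ArticleTitle>
        <Abstract>
          <AbstractText>Overexpression of let-7b inhibited hippocampal glial cell activation, inflammatory response and epileptic seizures by targeting Stat3.</AbstractText>
          <AbstractText>LncRNA H19 could competitively bind to let-7b to promote hippocampal glial cell activation and epileptic seizures by targeting Stat3 in a rat model of TLE.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>99999999</PMID>
      <Article>
        <ArticleTitle>Entry without an abstract (skipped by the reader).</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
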