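Package: PrefixSuffixScreen
Title: Alignment-Free Detection of Recurrent Structural Variation and
    Deletion-Born Fusion Genes in Bacterial Genome Collections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens bacterial genome collections for recurrent structural
    variation at query gene loci without alignment, by locating exact
    prefix and suffix k-mer anchors of each gene and measuring the
    genomic distance between them in every genome. Multimodal distance
    distributions are detected with one-dimensional density clustering,
    candidate loci are classified as ancestrally split (deletion-born
    fusion) or ancestrally intact (insertion-disrupted) by Fitch
    parsimony on a rooted min-hash sketch distance tree, and candidates
    are further characterised by mobile-element coverage of the
    intervening sequence and weighted dN/dS against both the observed
    fusion allele and a reconstructed surrogate of the pre-deletion
    state. A forward-time Wright-Fisher simulator of gene loss versus
    functionalization under genetic hitchhiking, and a synthetic genome
    collection generator with planted deletion and insertion events,
    support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StructuralVariation, Genetics, Phylogenetics, Alignment,
    SequenceMatching, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PrefixSuffixScreen-package.R'
    'ancestry.R'
    'annotation.R'
    'clustering.R'
    'kmer-screen.R'
    'pipeline.R'
    'selection.R'
    'synthetic.R'
    'utils.R'
    'wf.R'
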