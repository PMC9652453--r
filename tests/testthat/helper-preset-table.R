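## Expected barcode/UMI lengths for every bundled chemistry preset
## (NA = the chemistry has no UMI). The reference for registry fidelity.
PRESET_LENGTHS <- tibble::tribble(
  ~token, ~barcode, ~umi,
  "10x-v1", 14L, 10L,
  "10x-v2", 16L, 10L,
  "10x-v3", 16L, 12L,
  "bravo", 16L, NA,
  "bd-rhapsody", 27L, 8L,
  "fluidigm-c1", 16L, NA,
  "c1-cage", 16L, NA,
  "c1-ramda-seq", 16L, NA,
  "celseq", 8L, 4L,
  "celseq2", 6L, 6L,
  "dropseq", 12L, 8L,
  "icell8-v2", 11L, NA,
  "icell8", 11L, 14L,
  "icell8-5-prime", 10L, NA,
  "icell8-full-length", 16L, NA,
  "indrops-v1", 19L, 6L,
  "indrops-v2", 19L, 6L,
  "indrops-v3", 16L, 6L,
  "nadia", 12L, 8L,
  "marsseq-v1", 6L, 10L,
  "marsseq-v2", 7L, 8L,
  "microwell", 18L, 6L,
  "quartz-seq", 6L, NA,
  "quartz-seq2-1536", 15L, 8L,
  "quartz-seq2-384", 14L, 8L,
  "ramda-seq", 6L, NA,
  "sciseq2", 30L, 8L,
  "sciseq3", 40L, 8L,
  "scifiseq", 27L, 8L,
  "scrbseq", 6L, 10L,
  "seqwell", 12L, 8L,
  "smartseq", 16L, NA,
  "smartseq2", 16L, NA,
  "smartseq2-umi", 16L, 8L,
  "smartseq3", 16L, 8L,
  "splitseq", 18L, 10L,
  "strt-seq", 6L, NA,
  "strt-seq-c1", 8L, 5L,
  "strt-seq-2i", 13L, 6L,
  "surecell", 18L, 8L
)
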