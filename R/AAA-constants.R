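## Package-wide constants.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

STRUCTURAL_ELEMENTS <- c("acceptor_stem", "d_arm", "anticodon_arm",
                         "variable_region", "t_arm", "discriminator", "cca")

## T7 run-off transcription cassette flanks: promoter upstream, constant
## tail carrying the BsaI site downstream.
T7_PROMOTER <- "GCGTAATACGACTCACTATA"
T7_TAIL <- "TGAGACCGGATCCGGATCCCCGCTGAGCAATAACTAGC"

## Standard 3' ligation adapter for small-RNA single-end libraries.
DEFAULT_ADAPTER <- "CTGTAGGCACCATCAAT"
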