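Package: oncointerpret
Title: Clinical Interpretation of Tumor/Normal Whole-Genome Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-variant-calling interpretation for tumor/normal whole-genome
    sequencing: high-confidence somatic SNV/indel and structural-variant
    filtering, mutational catalog construction (SBS96, ID83, SV32) with
    non-negative least-squares signature refitting and cosine-driven
    signature-set refinement, genome phenotyping (tumor mutational burden,
    whole-genome duplication, homologous recombination deficiency score,
    microsatellite instability call), driver classification for oncogenes and
    tumor suppressor genes including copy-number drivers relative to ploidy,
    gene fusions and germline second hits, and rule-based mapping of findings
    to clinical actionability and clarity categories. Ships a deterministic
    synthetic tumor/normal call-set generator with ground-truth manifests so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
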