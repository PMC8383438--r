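#' Published LOAD GWAS worked example
#'
#' Loads the bundled worked-example tables: the distinct LOAD GWAS tag SNPs
#' printed with their 200-kb windows, and the differential accessibility
#' sites reported to overlap them (neuronal panel: 5 sites in 4 regions;
#' female-glia panel: 9 sites in 7 regions). Only the tag SNPs printed with
#' the overlapping sites are available; the remaining loci of the 25-locus
#' catalogue carry no reported overlap.
#'
#' @return List: `snps` (tibble `snp_id`, `chrom`, `pos`, `label`, printed
#'   window bounds), `peaks` (tibble `panel`, `direction`, `chrom`, `start`,
#'   `end`, `gene`, `snp_id`, `peak_id`).
#' @export
load_gwas_examples <- function() {
  snps <- readr::read_tsv(
    system.file("extdata", "load_gwas_tag_snps.tsv", package = "atacdiff"),
    show_col_types = FALSE
  )
  peaks <- readr::read_tsv(
    system.file("extdata", "load_differential_gwas_peaks.tsv",
                package = "atacdiff"),
    show_col_types = FALSE
  )
  peaks$peak_id <- peak_id(peaks)
  list(snps = snps, peaks = peaks)
}
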