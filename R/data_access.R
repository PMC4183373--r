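#' Published occupancies of Anabaena PCC 7120 promoter macrostates
#'
#' The published per-macrostate occupancy probabilities `P`, pooled
#' nonspecific weight `P_NS`, free energy differences and entropies for the
#' nine Anabaena PCC 7120 promoters (alr0705, argC, nifB, conR, furA, furB,
#' petH, petF, ntcA). Positions are signed labels relative to the ATG
#' (+1 at the 'A', no 0). These printed values serve as reference inputs for
#' the closed-form consistency check of [free_energy_difference()]:
#' `ln(P / P_NS)` reproduces every published `dF_kBT` entry within the
#' rounding of the three-decimal occupancies.
#'
#' @return A data.frame with columns `sequence`, `state` (TSS-labeled or
#'   other relevant site), `label`, `P`, `dF_kBT`, `S`, `P_NS`.
#' @examples
#' occ <- anabaena_occupancies()
#' max(abs(free_energy_difference(occ$P, occ$P_NS) - occ$dF_kBT))
#' @export
anabaena_occupancies <- function() {
  path <- system.file("extdata", "anabaena_tss_occupancies.tsv",
                      package = "breathscan", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
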