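# Preset family scenarios with deterministic meiosis layouts.
#
# Both presets place a 1 Mb disease-locus interval (gene plus immediately
# linked region) mid-chromosome and give the reference child crossover-free
# gametes carrying the mutation-linked haplotype (haplotype 1), so the
# affected reference carries every transmitted mutation. Embryo meioses are
# fixed so the scenario truth is known by construction; WGA artifacts on the
# embryos remain stochastic under the seed.

PRESET_NAMES <- c("family1_dominant", "family2_recessive")

#' Preset simulation scenarios
#'
#' `"family1_dominant"`: autosomal dominant, maternally transmitted locus,
#' 8 embryos; truth is 4 embryos carrying the maternal mutation, 3 free of it,
#' and 1 with a crossover inside the locus (recombinant no-call).
#'
#' `"family2_recessive"`: autosomal recessive, both parents transmitting,
#' 4 embryos; truth is each embryo carrying exactly one parental mutation
#' (two paternal-only, two maternal-only), i.e. 4 unaffected carriers.
#'
#' @param name Preset name.
#' @param seed RNG seed for sites, haplotypes, random paternal meioses and WGA
#'   artifacts.
#' @return A [simulation_config()].
#' @export
simulation_preset <- function(name = PRESET_NAMES, seed) {
  name <- match.arg(name)
  no_xo <- list(start_hap = 1L, breakpoints = numeric(0))
  locus_start <- 45e6
  locus_end <- 46e6

  if (name == "family1_dominant") {
    locus <- disease_locus("chr16", locus_start, locus_end,
                           mode = "autosomal_dominant",
                           transmitting_parents = "maternal")
    mk <- function(start, bp = numeric(0)) {
      list(paternal = NULL, # paternal meiosis random; not diagnosed
           maternal = list(start_hap = start, breakpoints = bp))
    }
    embryos <- list(
      mk(1L),                      # E1 carrier
      mk(1L, 72.5e6),              # E2 carrier (crossover past locus)
      mk(2L),                      # E3 free
      mk(1L, 15.2e6),              # E4 free (hap2 at locus)
      mk(1L, c(60e6, 80e6)),       # E5 carrier
      mk(2L, 78e6),                # E6 free
      mk(2L, 20.4e6),              # E7 carrier (hap1 at locus)
      mk(1L, 45.5e6))              # E8 recombinant inside locus
    simulation_config(n_embryos = 8,
                      fixed_meioses = list(
                        reference = list(paternal = no_xo, maternal = no_xo),
                        embryos = embryos),
                      locus = locus, seed = seed)
  } else {
    locus <- disease_locus("chr16", locus_start, locus_end,
                           mode = "autosomal_recessive",
                           transmitting_parents = c("paternal", "maternal"))
    mk2 <- function(pat_start, mat_start, pat_bp = numeric(0),
                    mat_bp = numeric(0)) {
      list(paternal = list(start_hap = pat_start, breakpoints = pat_bp),
           maternal = list(start_hap = mat_start, breakpoints = mat_bp))
    }
    embryos <- list(
      mk2(1L, 2L),                 # E1 paternal-only carrier
      mk2(2L, 1L),                 # E2 maternal-only carrier
      mk2(1L, 2L, pat_bp = 80e6),  # E3 paternal-only carrier
      mk2(2L, 1L, mat_bp = 75e6))  # E4 maternal-only carrier
    simulation_config(n_embryos = 4,
                      fixed_meioses = list(
                        reference = list(paternal = no_xo, maternal = no_xo),
                        embryos = embryos),
                      locus = locus, seed = seed)
  }
}
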