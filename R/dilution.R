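#' Template copies per allele in a DNA pool
#'
#' When equal masses of genomic DNA from every pool member are combined and a
#' fixed mass enters the PCR, each individual contributes
#' `mass / 2C / pool_size` haploid genome copies. With 10 ng per individual
#' and a flax genome of 2C = 0.764 pg this gives 204.5 copies per allele for
#' a 1-in-64 pool and 136.3 for a 1-in-96 pool, comfortably above the ~40
#' copies below which allele sampling fluctuation threatens detection.
#'
#' Following the source arithmetic, the 2C picogram value is used directly as
#' the per-genome mass (no additional factor of two at the allele level).
#'
#' @param dna_mass_ng DNA mass per individual entering the pool, in ng.
#' @param genome_2c_pg 2C genome mass in pg (flax default 0.764).
#' @param pool_size Number of individuals in the pool.
#' @return Copies per allele, rounded to one decimal.
#' @examples
#' copies_per_allele(10, 0.764, 64) # 204.5
#' copies_per_allele(10, 0.764, 96) # 136.3
#' @export
copies_per_allele <- function(dna_mass_ng = 10, genome_2c_pg = 0.764, pool_size = 96) {
  if (any(c(dna_mass_ng, genome_2c_pg, pool_size) <= 0)) {
    abort("`dna_mass_ng`, `genome_2c_pg` and `pool_size` must all be positive.")
  }
  round((dna_mass_ng * 1000 / genome_2c_pg) / pool_size, 1)
}

#' Expected pool allele frequency of a single carrier
#'
#' A diploid pool of `n` individuals carries `2n` alleles, so one homozygous
#' carrier contributes `1/n` of the alleles and one heterozygous carrier
#' `1/(2n)`: about 1% and 0.5% respectively in a 96-member pool. These are
#' the frequencies the caller must resolve above the platform's ~0.1%
#' substitution error.
#'
#' @param pool_size Number of individuals in the pool.
#' @param zygosity `"HET"` or `"HOM"`.
#' @return Expected variant allele frequency (fraction).
#' @examples
#' expected_variant_frequency(96, "HOM") # ~0.0104
#' expected_variant_frequency(96, "HET") # ~0.0052
#' @export
expected_variant_frequency <- function(pool_size, zygosity = c("HET", "HOM")) {
  zygosity <- match.arg(zygosity)
  pool_size <- check_count(pool_size, "pool_size")
  if (zygosity == "HOM") 1 / pool_size else 1 / (2 * pool_size)
}

#' Convert a molar DNA concentration to molecules per microliter
#'
#' `molecules/uL = pM * 1e-12 mol/L * N_A / 1e6 uL/L`. Note that 26 pM
#' converts to 1.566e7 molecules per microliter; library-preparation guides
#' sometimes quote 15.5e6 for the same concentration, a rounding the physical
#' conversion does not reproduce.
#'
#' @param concentration_pM Concentration in picomolar (>= 0).
#' @return Molecules per microliter.
#' @examples
#' molecules_per_microliter(26) # 1.566e7
#' @export
molecules_per_microliter <- function(concentration_pM) {
  if (any(concentration_pM < 0)) abort("`concentration_pM` must be non-negative.")
  avogadro <- 6.02214076e23
  concentration_pM * 1e-12 * avogadro / 1e6
}
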