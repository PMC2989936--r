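# Fixture builders shared across test files.  Everything is generated
# in code; no stored data.

# Short single-chromosome map.
tiny_map <- function(pos = c(0, 25, 50, 75, 100), chrom = "1",
                     prefix = "M") {
  linkage_map(rep(chrom, length(pos)), paste0(prefix, seq_along(pos)), pos)
}

# Hand-built three-generation pedigree: one F0 couple, one F1 couple
# (full sibs), and n_f2 offspring split over two litters.
toy_pedigree <- function(n_f2 = 4) {
  rbind(
    data.frame(id = "D1", sire = NA, dam = NA, generation = "F0",
               breed = "Duroc", sex = "M", litter = NA, group = NA),
    data.frame(id = "P1", sire = NA, dam = NA, generation = "F0",
               breed = "Pietrain", sex = "F", litter = NA, group = NA),
    data.frame(id = c("S1", "M1"), sire = "D1", dam = "P1",
               generation = "F1", breed = NA, sex = c("M", "F"),
               litter = NA, group = NA),
    data.frame(id = sprintf("X%d", seq_len(n_f2)), sire = "S1",
               dam = "M1", generation = "F2", breed = NA,
               sex = rep(c("M", "F"), length.out = n_f2),
               litter = rep(c("L1", "L2"), length.out = n_f2),
               group = "G1"))
}

# Genotype table from "a/b" strings: geno is a named list, one character
# vector per individual, in marker order; "./." for missing.
toy_genotypes <- function(markers, geno) {
  n <- length(geno)
  a1 <- a2 <- matrix(NA_integer_, n, length(markers),
                     dimnames = list(names(geno), markers))
  for (i in seq_len(n)) {
    parts <- strsplit(geno[[i]], "/", fixed = TRUE)
    for (j in seq_along(markers)) {
      if (parts[[j]][1] != ".") {
        a1[i, j] <- as.integer(parts[[j]][1])
        a2[i, j] <- as.integer(parts[[j]][2])
      }
    }
  }
  genotype_table(a1, a2)
}

# Assembled toy dataset; phenotype defaults to a zero trait.
toy_dataset <- function(map, geno, ped = NULL, pheno = NULL) {
  if (is.null(ped)) {
    n_f2 <- sum(grepl("^X", rownames(geno)))
    ped <- toy_pedigree(n_f2)
  }
  if (is.null(pheno)) {
    f2 <- ped$id[ped$generation == "F2"]
    pheno <- data.frame(id = f2,
                        sex = ped$sex[match(f2, ped$id)],
                        litter = ped$litter[match(f2, ped$id)],
                        y = 0)
  }
  f2_dataset(map, ped, geno, pheno)
}

# Simulation config with a single short chromosome; breed-disjoint
# marker alleles give fully informative meioses when disjoint = TRUE.
quick_cfg <- function(n_f2 = 120, n_litters = 20, pos = c(0, 25, 50, 75, 100),
                      qtl = NULL, disjoint = FALSE, traits = NULL, ...) {
  freqs <- if (disjoint)
    list(d = c(0.5, 0.5, 0, 0), p = c(0, 0, 0.5, 0.5))
  else list(d = c(0.5, 0.3, 0.15, 0.05), p = c(0.05, 0.15, 0.3, 0.5))
  if (is.null(traits))
    traits <- list(trait_config("y", 0, 1, sex_effect = 0.3,
                                litter_sd = 0.25))
  sim_config(map = tiny_map(pos), n_f2 = n_f2, n_litters = n_litters,
             n_groups = 2, freq_duroc = freqs$d, freq_pietrain = freqs$p,
             qtl = qtl, traits = traits, ...)
}
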