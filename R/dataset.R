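#' Linkage map constructor
#'
#' Build a validated linkage map of microsatellite markers with
#' sex-averaged Haldane cM positions.
#'
#' @param chrom Chromosome label per marker.
#' @param marker Marker name; must be unique genome-wide.
#' @param pos_cM Position in Haldane centiMorgans; strictly increasing
#'   within each chromosome, first marker at >= 0.
#' @return A `data.frame` of class `linkage_map` with columns
#'   `chrom`, `marker`, `pos_cM`, ordered by chromosome and position.
#' @export
linkage_map <- function(chrom, marker, pos_cM) {
  map <- data.frame(chrom = as.character(chrom),
                    marker = as.character(marker),
                    pos_cM = as.numeric(pos_cM),
                    stringsAsFactors = FALSE)
  if (anyNA(map)) stop("linkage map fields must not contain NA")
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker name(s): ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  map <- map[order(map$chrom, map$pos_cM), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (p[1] < 0) stop("first marker position on chromosome ", ch,
                       " is negative")
    if (any(diff(p) <= 0)) {
      stop("marker positions on chromosome ", ch,
           " are not strictly increasing")
    }
  }
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' Genotype table constructor
#'
#' Store unordered allele pairs for individuals by markers.  Alleles are
#' opaque positive integer labels; missing genotypes are `NA` (never an
#' allele code).
#'
#' @param allele1,allele2 Integer matrices (individuals x markers) with
#'   identical dimnames; `NA` in either slot marks the genotype missing.
#' @return An integer array `individuals x markers x 2` of class
#'   `genotype_table`.
#' @export
genotype_table <- function(allele1, allele2) {
  if (!identical(dim(allele1), dim(allele2)))
    stop("allele matrices must have identical dimensions")
  if (is.null(rownames(allele1)) || is.null(colnames(allele1)))
    stop("allele matrices need individual row names and marker column names")
  a1 <- matrix(as.integer(allele1), nrow(allele1), dimnames = dimnames(allele1))
  a2 <- matrix(as.integer(allele2), nrow(allele2), dimnames = dimnames(allele1))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  if (any(c(a1, a2) <= 0L, na.rm = TRUE))
    stop("allele labels must be positive integers")
  g <- array(c(a1, a2), dim = c(nrow(a1), ncol(a1), 2L),
             dimnames = c(dimnames(a1), list(NULL)))
  class(g) <- "genotype_table"
  g
}

#' Bind an F2 cross dataset
#'
#' Combine a linkage map, three-generation pedigree, genotype table and
#' phenotype table into one cross-referenced dataset.
#'
#' @param map A [linkage_map()].
#' @param pedigree Data frame with columns `id`, `sire`, `dam`,
#'   `generation` (one of `"F0"`, `"F1"`, `"F2"`), `breed` (for F0:
#'   `"Duroc"` or `"Pietrain"`), `sex`, `litter`, `group`; `NA` where not
#'   applicable.
#' @param genotypes A [genotype_table()]; marker columns must appear in
#'   the map and individuals in the pedigree.
#' @param phenotypes Data frame with columns `id`, `sex`, `litter`, then
#'   numeric covariate/trait columns; every id must be an F2.
#' @return A list of class `f2_dataset` with elements `map`, `pedigree`,
#'   `genotypes`, `phenotypes`.
#' @export
f2_dataset <- function(map, pedigree, genotypes, phenotypes) {
  stopifnot(inherits(map, "linkage_map"))
  need <- c("id", "sire", "dam", "generation", "breed", "sex", "litter",
            "group")
  if (!all(need %in% names(pedigree)))
    stop("pedigree lacks column(s): ",
         paste(setdiff(need, names(pedigree)), collapse = ", "))
  pedigree <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  for (cc in need) pedigree[[cc]] <- as.character(pedigree[[cc]])
  if (anyDuplicated(pedigree$id)) stop("duplicated pedigree ids")
  bad <- setdiff(colnames(genotypes), map$marker)
  if (length(bad))
    stop("genotyped marker(s) not on the map: ", paste(bad, collapse = ", "))
  bad <- setdiff(rownames(genotypes), pedigree$id)
  if (length(bad))
    stop("genotyped individual(s) missing from pedigree: ",
         paste(bad, collapse = ", "))
  if (!all(c("id", "sex", "litter") %in% names(phenotypes)))
    stop("phenotypes need columns id, sex, litter")
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  phenotypes$id <- as.character(phenotypes$id)
  bad <- setdiff(phenotypes$id, pedigree$id[pedigree$generation == "F2"])
  if (length(bad))
    stop("phenotyped individual(s) that are not pedigree F2: ",
         paste(bad, collapse = ", "))
  structure(list(map = map, pedigree = pedigree, genotypes = genotypes,
                 phenotypes = phenotypes),
            class = "f2_dataset")
}

#' @export
print.f2_dataset <- function(x, ...) {
  nf2 <- sum(x$pedigree$generation == "F2")
  cat("F2 cross dataset\n")
  cat(sprintf("  markers: %d on %d chromosome(s), %.1f cM total\n",
              nrow(x$map), length(unique(x$map$chrom)),
              sum(tapply(x$map$pos_cM, x$map$chrom,
                         function(p) diff(range(p))))))
  cat(sprintf("  pedigree: %d individuals (%d F2)\n",
              nrow(x$pedigree), nf2))
  cat(sprintf("  phenotypes: %d records, trait/covariate columns: %s\n",
              nrow(x$phenotypes),
              paste(dataset_traits(x), collapse = ", ")))
  invisible(x)
}

#' Trait and covariate column names of a dataset
#'
#' @param dataset An `f2_dataset`.
#' @return Character vector of numeric phenotype column names (traits and
#'   covariates; the model specification decides the role of each).
#' @export
dataset_traits <- function(dataset) {
  ph <- dataset$phenotypes
  nm <- setdiff(names(ph), c("id", "sex", "litter"))
  nm[vapply(ph[nm], is.numeric, logical(1))]
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = ".", colClasses = "character",
                    check.names = FALSE, comment.char = "")
}

#' Read an F2 dataset from tab-separated files
#'
#' File dialects: `map` has columns `chrom`, `marker`, `pos_cM`;
#' `pedigree` has `id`, `sire`, `dam`, `generation`, `breed`, `sex`,
#' `litter`, `group` with `"."` for missing; `genotypes` is wide with
#' `id` then one `"a/b"` (or `"./."`) column per marker; `phenotypes`
#' has `id`, `sex`, `litter`, then numeric columns.
#'
#' @param map_file,pedigree_file,genotype_file,phenotype_file Paths.
#' @return An [f2_dataset()].
#' @export
read_dataset <- function(map_file, pedigree_file, genotype_file,
                         phenotype_file) {
  m <- .read_tsv(map_file)
  if (!all(c("chrom", "marker", "pos_cM") %in% names(m)))
    stop("map file ", map_file, " needs columns chrom, marker, pos_cM")
  map <- linkage_map(m$chrom, m$marker, as.numeric(m$pos_cM))

  ped <- .read_tsv(pedigree_file)

  g <- .read_tsv(genotype_file)
  if (names(g)[1] != "id") stop("genotype file ", genotype_file,
                                " must start with an 'id' column")
  mk <- names(g)[-1]
  bad <- setdiff(mk, map$marker)
  if (length(bad))
    stop("genotype file ", genotype_file,
         " has marker(s) not on the map: ", paste(bad, collapse = ", "))
  n <- nrow(g)
  a1 <- a2 <- matrix(NA_integer_, n, length(mk),
                     dimnames = list(g$id, mk))
  for (j in seq_along(mk)) {
    v <- g[[mk[j]]]
    ok <- !is.na(v) & v != "./."
    parts <- strsplit(v[ok], "/", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != 2L)) {
      i <- which(ok)[which(lens != 2L)[1]]
      stop("malformed genotype in ", genotype_file, ", line ", i + 1L,
           ", marker ", mk[j], ": '", v[i], "'")
    }
    al <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2,
                 byrow = TRUE)
    if (anyNA(al)) {
      i <- which(ok)[which(rowSums(is.na(al)) > 0)[1]]
      stop("malformed allele in ", genotype_file, ", line ", i + 1L,
           ", marker ", mk[j], ": '", v[i], "'")
    }
    a1[ok, j] <- al[, 1]
    a2[ok, j] <- al[, 2]
  }
  geno <- genotype_table(a1, a2)

  ph <- .read_tsv(phenotype_file)
  if (ncol(ph) >= 4) {
    for (cc in setdiff(names(ph), c("id", "sex", "litter")))
      ph[[cc]] <- as.numeric(ph[[cc]])
  }
  f2_dataset(map, ped, geno, ph)
}

#' Write an F2 dataset to tab-separated files
#'
#' Inverse of [read_dataset()]; writes `map.tsv`, `pedigree.tsv`,
#' `genotypes.tsv`, `phenotypes.tsv` under `dir` using `"."` for missing
#' values.
#'
#' @param dataset An `f2_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  wt(as.data.frame(unclass(dataset$map))[c("chrom", "marker", "pos_cM")],
     "map.tsv")
  wt(dataset$pedigree, "pedigree.tsv")
  g <- dataset$genotypes
  gs <- matrix("./.", nrow(g), ncol(g), dimnames = dimnames(g)[1:2])
  ok <- !is.na(g[, , 1])
  gs[ok] <- paste0(g[, , 1][ok], "/", g[, , 2][ok])
  wt(data.frame(id = rownames(g), gs, check.names = FALSE),
     "genotypes.tsv")
  wt(dataset$phenotypes, "phenotypes.tsv")
  invisible(file.path(dir, c("map.tsv", "pedigree.tsv", "genotypes.tsv",
                             "phenotypes.tsv")))
}

# TRUE where child's unordered pair is transmissible from its parents'
# genotypes; a missing parent or parent genotype is always compatible.
.mendel_ok <- function(c1, c2, s1, s2, d1, d2) {
  from <- function(x, p1, p2) is.na(p1) | x == p1 | x == p2
  (from(c1, s1, s2) & from(c2, d1, d2)) |
    (from(c2, s1, s2) & from(c1, d1, d2))
}

#' Validate an F2 dataset
#'
#' Runs Mendelian and structural consistency checks.  Hard errors:
#' pedigree-structure violations and any non-founder genotype with no
#' allele transmissible from its genotyped parents.  Warnings:
#' monomorphic markers and markers missing in more than half of the F2.
#'
#' @param dataset An `f2_dataset`.
#' @return A list of class `f2_validation` with character vectors
#'   `errors` and `warnings`.
#' @export
validate_dataset <- function(dataset) {
  ped <- dataset$pedigree
  g <- dataset$genotypes
  errors <- character()
  warnings <- character()
  rownames(ped) <- ped$id

  gen <- ped$generation
  for (i in which(gen == "F1")) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) || is.na(d) ||
        !s %in% ped$id || !d %in% ped$id ||
        ped[s, "generation"] != "F0" || ped[d, "generation"] != "F0" ||
        !identical(ped[s, "breed"], "Duroc") ||
        !identical(ped[d, "breed"], "Pietrain")) {
      errors <- c(errors, paste0("F1 ", ped$id[i],
                                 " lacks an F0 Duroc sire and F0 Pietrain dam"))
    }
  }
  for (i in which(gen == "F2")) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) || is.na(d) || !s %in% ped$id || !d %in% ped$id ||
        ped[s, "generation"] != "F1" || ped[d, "generation"] != "F1") {
      errors <- c(errors, paste0("F2 ", ped$id[i],
                                 " lacks F1 sire and F1 dam"))
    }
  }
  # ancestry cycles
  anc <- function(id) {
    seen <- character()
    stack <- c(ped[id, "sire"], ped[id, "dam"])
    while (length(stack)) {
      a <- stack[1]; stack <- stack[-1]
      if (is.na(a) || !a %in% ped$id || a %in% seen) next
      seen <- c(seen, a)
      stack <- c(stack, ped[a, "sire"], ped[a, "dam"])
    }
    seen
  }
  for (id in ped$id) {
    if (id %in% anc(id))
      errors <- c(errors, paste0(id, " is its own ancestor"))
  }

  ids <- rownames(g)
  has_geno <- ped$id %in% ids
  for (i in which(!is.na(ped$sire) & !is.na(ped$dam) & has_geno)) {
    id <- ped$id[i]; s <- ped$sire[i]; d <- ped$dam[i]
    if (!(s %in% ids) || !(d %in% ids)) next
    c1 <- g[id, , 1]; c2 <- g[id, , 2]
    ok <- .mendel_ok(c1, c2, g[s, , 1], g[s, , 2], g[d, , 1], g[d, , 2])
    bad <- which(!ok & !is.na(c1))
    for (m in colnames(g)[bad]) {
      errors <- c(errors, paste0("Mendelian inconsistency: ", id,
                                 " at marker ", m,
                                 " (genotype ", g[id, m, 1], "/",
                                 g[id, m, 2], ") incompatible with parents ",
                                 s, " and ", d))
    }
  }

  f0 <- ped$id[gen == "F0" & has_geno]
  ref <- if (length(f0)) f0 else intersect(ped$id, ids)
  f2g <- intersect(ped$id[gen == "F2"], ids)
  for (m in colnames(g)) {
    al <- unique(stats::na.omit(c(g[ref, m, 1], g[ref, m, 2])))
    if (length(al) <= 1L)
      warnings <- c(warnings, paste0("marker ", m,
                                     " is monomorphic in the founders"))
    if (length(f2g) &&
        mean(is.na(g[f2g, m, 1])) > 0.5)
      warnings <- c(warnings, paste0("marker ", m,
                                     " missing in >50% of F2"))
  }

  ph <- dataset$phenotypes
  for (cc in dataset_traits(dataset)) {
    if (any(!is.finite(ph[[cc]]) & !is.na(ph[[cc]])))
      errors <- c(errors, paste0("non-finite values in phenotype column ",
                                 cc))
  }

  structure(list(errors = errors, warnings = warnings),
            class = "f2_validation")
}

#' @export
print.f2_validation <- function(x, ...) {
  cat(length(x$errors), "hard error(s),", length(x$warnings),
      "warning(s)\n")
  if (length(x$errors)) cat(paste0("  E: ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat(paste0("  W: ", x$warnings, "\n"), sep = "")
  invisible(x)
}
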