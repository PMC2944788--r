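#' Write a population to PLINK-style and TSV files
#'
#' Writes `<prefix>.ped` / `<prefix>.map` (alleles coded 1/2, missing `0 0`,
#' 1-based bp positions, autosomes only), a dosage matrix
#' `<prefix>.dosage.tsv` (rows = individuals, header = SNP ids) and the
#' pedigree `<prefix>.pedigree.csv` (id, sire_id).
#'
#' @param pop a population.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_population <- function(pop, prefix) {
  g <- pop$genotypes
  map <- pop$snp_map
  write.table(data.frame(map$chrom, map$snp_id, map$pos_cm / 100, map$pos_bp),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  gr <- round(g)
  ped <- vapply(seq_len(nrow(g)), function(i) {
    al <- code[as.character(gr[i, ])]
    al[is.na(al)] <- "0 0"
    paste(c(pop$pedigree$sire[i], rownames(g)[i], "0", "0", "0", "-9", al),
          collapse = " ")
  }, character(1))
  writeLines(ped, paste0(prefix, ".ped"))
  dm <- as.data.frame(g)
  write.table(cbind(id = rownames(g), dm), paste0(prefix, ".dosage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = pop$pedigree$id, sire_id = pop$pedigree$sire),
              paste0(prefix, ".pedigree.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a dosage TSV written by [write_population()]
#'
#' @param path path to the `.dosage.tsv` file.
#' @return numeric matrix with individual ids as row names.
#' @export
read_dosage <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a trait table
#'
#' Phenotype TSV with columns `id`, `trait`, `split`.
#'
#' @param trait a [sim_trait()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trait <- function(trait, path) {
  write.table(data.frame(id = names(trait$phenotype), trait = trait$phenotype,
                         split = as.character(trait$split)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
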