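#' Read PLINK-style text genotype files
#'
#' Parses a `.ped` / `.map` pair into a [snp_panel()]. The `.ped` file has 6
#' leading columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele columns per SNP; the `.map` file has 4 columns
#' (chromosome, SNP name, genetic position, base-pair position). Alleles are
#' collapsed to the additive \{1, 0, -1\} code; an allele pair "0 0" is
#' treated as missing.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @param allele_coding either `"major"` (default: the more frequent allele
#'   of each SNP becomes the reference "A" allele, ties broken toward the
#'   lexicographically smaller allele) or a character vector of length p
#'   giving the reference allele of each SNP explicitly.
#' @return A [snp_panel()].
#' @export
read_plink_text <- function(ped_path, map_path, allele_coding = "major") {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad))
    stop("map parse error: line ", bad[1], " has ", lengths(map_tok)[bad[1]],
         " fields (expected 4)")
  map <- data.frame(chrom = as.integer(vapply(map_tok, `[`, "", 1L)),
                    name = vapply(map_tok, `[`, "", 2L),
                    gpos = as.numeric(vapply(map_tok, `[`, "", 3L)),
                    pos = as.numeric(vapply(map_tok, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  p <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  if (n == 0L) stop("ped parse error: no individuals in ", ped_path)
  a1 <- matrix("", n, p)
  a2 <- matrix("", n, p)
  ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * p)
      stop("ped parse error: line ", i, " has ", length(tok),
           " fields (expected ", 6L + 2L * p, ")")
    ids[i] <- tok[2L]
    al <- tok[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * p, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * p, by = 2L)]
  }

  geno <- matrix(NA_real_, n, p)
  ref <- character(p)
  explicit <- !identical(allele_coding, "major")
  if (explicit && length(allele_coding) != p)
    stop("allele_coding must be \"major\" or one reference allele per SNP")
  for (j in seq_len(p)) {
    m <- a1[, j] == "0" | a2[, j] == "0"
    obs <- c(a1[!m, j], a2[!m, j])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("parse error: SNP ", map$name[j], " has ", length(alleles),
           " distinct alleles (", paste(alleles, collapse = ", "), ")")
    if (explicit) {
      ref[j] <- allele_coding[j]
      if (length(obs) && !all(obs %in% c(ref[j], setdiff(alleles, ref[j]))))
        stop("unknown allele symbol for SNP ", map$name[j])
      if (length(alleles) && !ref[j] %in% alleles && length(alleles) == 2L)
        stop("reference allele ", ref[j], " not observed for SNP ", map$name[j])
    } else {
      if (!length(alleles)) { ref[j] <- NA_character_; next }
      cnt <- table(factor(obs, levels = alleles))
      top <- alleles[cnt == max(cnt)]
      ref[j] <- sort(top)[1L]   # major allele; lexicographic tie-break
    }
    code <- (a1[, j] == ref[j]) + (a2[, j] == ref[j]) - 1
    code[m] <- NA_real_
    geno[, j] <- code
  }
  panel <- snp_panel(geno, data.frame(name = map$name, chrom = map$chrom,
                                      pos = map$pos), ids)
  attr(panel, "ref_allele") <- ref
  panel
}

#' Write a SNP panel as PLINK-style text files
#'
#' Inverse of [read_plink_text()]: the +1 allele is written as "A" and the
#' -1 allele as "B" (missing as "0 0"), so that re-reading with
#' `allele_coding = rep("A", p)` reproduces the code matrix exactly.
#'
#' @param panel a [snp_panel()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(panel, ped_path, map_path) {
  map <- panel$snp_map
  writeLines(paste(map$chrom, map$name, 0, map$pos), map_path)
  g <- panel$genotypes
  n <- nrow(g)
  al1 <- matrix("A", n, ncol(g)); al2 <- matrix("B", n, ncol(g))
  al1[g == -1] <- "B"; al2[g == 1] <- "A"
  al1[is.na(g)] <- "0"; al2[is.na(g)] <- "0"
  rows <- vapply(seq_len(n), function(i) {
    paste(c(panel$individual_ids[i], panel$individual_ids[i], "0", "0",
            "0", "-9", as.vector(rbind(al1[i, ], al2[i, ]))), collapse = " ")
  }, "")
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a phenotype table
#'
#' Tab-separated file with a header and two columns: individual id and
#' trait value.
#'
#' @param path file path.
#' @return A [phenotype_vector()].
#' @export
read_phenotype_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("phenotype file must have columns: id, value")
  phenotype_vector(as.numeric(d[[2L]]), as.character(d[[1L]]))
}

#' Write a phenotype table
#' @param pheno a [phenotype_vector()].
#' @param path file path.
#' @param trait column name for the trait value.
#' @return Invisibly, `path`.
#' @export
write_phenotype_tsv <- function(pheno, path, trait = "value") {
  d <- data.frame(id = pheno$individual_ids, value = pheno$values)
  names(d)[2] <- trait
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Comma-separated file with a header and columns id, sire, dam; "0", "NA"
#' or empty denote an unknown parent.
#'
#' @param path file path.
#' @return A [pedigree_table()].
#' @export
read_pedigree_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (ncol(d) < 3L) stop("pedigree file must have columns: id, sire, dam")
  pedigree_table(d[[1L]], d[[2L]], d[[3L]])
}

#' Write a pedigree file
#' @param ped a [pedigree_table()].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_pedigree_csv <- function(ped, path) {
  d <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam)
  d$sire[is.na(d$sire)] <- "0"; d$dam[is.na(d$dam)] <- "0"
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an additive relationship matrix
#'
#' Whitespace-delimited square matrix with a header line of individual ids.
#'
#' @param A an [a_matrix()] result.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_a_matrix <- function(A, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(A$id_order, collapse = " "), con)
  utils::write.table(format(A$values, digits = 12, trim = TRUE), con,
                     col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(path)
}
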