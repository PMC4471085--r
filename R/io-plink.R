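#' Write genotypes as PLINK text files
#'
#' Emits space-delimited `.ped` / `.map` files. The family id column
#' carries the population label; missing genotypes are written as
#' `0 0`.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are created.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$dosages) == 0) stop("no loci to write")
  map <- data.frame(
    chrom = gm$loci$chrom, id = gm$loci$id, cm = 0, pos = gm$loci$pos
  )
  utils::write.table(map, paste0(prefix, ".map"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  n <- nrow(gm$dosages)
  m <- ncol(gm$dosages)
  ref <- gm$loci$ref
  alt <- gm$loci$alt
  # allele pair per genotype; dosage counts alt alleles
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  d <- gm$dosages
  for (code in 0:2) {
    idx <- which(!is.na(d) & d == code)
    cm <- ((idx - 1) %/% n) + 1  # column of each hit
    a1[idx] <- if (code == 0) ref[cm] else alt[cm]
    a2[idx] <- if (code == 2) alt[cm] else ref[cm]
  }
  geno <- matrix("", n, 2 * m)
  geno[, seq(1, 2 * m, 2)] <- a1
  geno[, seq(2, 2 * m, 2)] <- a2
  ped <- cbind(gm$samples$population, gm$samples$sample_id,
               "0", "0", "0", "-9", geno)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  writeLines(apply(ped, 1, paste, collapse = " "), con)
  invisible(prefix)
}

#' Read PLINK text genotypes
#'
#' Parses `<prefix>.ped` / `<prefix>.map`. Per locus, the observed
#' allele labels are ordered alphabetically: the first becomes the
#' reference and the second the alternate allele, and dosages count
#' alternate alleles. The `.ped` family id column is taken as the
#' population label.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (f in c(ped_path, map_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("integer", "character",
                                          "numeric", "integer"))
  lines <- readLines(ped_path)
  if (length(lines) == 0) stop("empty .ped file")
  m <- nrow(map)
  n <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  bad <- which(len != 6 + 2 * m)
  if (length(bad) > 0) {
    stop("malformed .ped line ", bad[1], ": expected ", 6 + 2 * m,
         " fields, found ", len[bad[1]])
  }
  fm <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = fm[, 2], population = fm[, 1])
  a1 <- fm[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- fm[, 6 + 2 * seq_len(m), drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2) {
      stop("locus ", map$id[j], " has >2 alleles in .ped")
    }
    if (length(obs) == 0) obs <- c("A", "B")
    if (length(obs) == 1) obs <- c(obs, "B")
    ref[j] <- obs[1]
    alt[j] <- obs[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dj <- (a1[, j] == obs[2]) + (a2[, j] == obs[2])
    dj[miss] <- NA_integer_
    dos[, j] <- dj
  }
  loci <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                     ref = ref, alt = alt)
  genotype_matrix(dos, loci, samples)
}
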