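#' Write genotypes as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with a GT-only FORMAT field; missing
#' calls are written as `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$dosages) == 0) stop("no loci to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lsblscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- t(gm$dosages)  # loci x samples
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  body <- paste(
    gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref, gm$loci$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}

#' Read a two-column population map
#'
#' @param path TSV with columns `sample_id` and `population` (a header
#'   line is detected and skipped).
#' @return Data frame with `sample_id` and `population`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "population"),
                          colClasses = "character")
  if (nrow(pm) > 0 && identical(tolower(pm$sample_id[1]), "sample_id")) {
    pm <- pm[-1, , drop = FALSE]
  }
  if (anyDuplicated(pm$sample_id)) stop("duplicate sample ids in popmap")
  rownames(pm) <- NULL
  pm
}

#' Read genotypes from a VCF
#'
#' Parses GT fields with \pkg{vcfR}. Multiallelic records are skipped
#' (with a message giving the count); every VCF sample must appear in
#' the population map.
#'
#' @param path VCF file (plain or bgzipped).
#' @param popmap Path to a TSV population map ([read_popmap()]).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) stop("file not found: ", path)
  pm <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- t(fm)  # single-record VCF drops to vector
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    message("skipping ", sum(multi), " multiallelic/invalid records")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  missing_ids <- setdiff(ids, pm$sample_id)
  if (length(missing_ids) > 0) {
    stop("samples absent from popmap: ",
         paste(missing_ids, collapse = ", "))
  }
  # dosage = count of '1' alleles in the GT string; any '.' -> missing
  clean <- gsub("\\|", "/", gt)
  dos_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- matrix(dos_map[clean], nrow(gt), ncol(gt))
  dos <- t(dos)  # samples x loci
  ids_na <- is.na(fix$ID) | fix$ID == "."
  locus_id <- ifelse(ids_na,
                     paste0(fix$CHROM, "_", fix$POS), fix$ID)
  loci <- data.frame(
    chrom = as.integer(fix$CHROM), pos = as.integer(fix$POS),
    id = locus_id, ref = fix$REF, alt = fix$ALT
  )
  samples <- data.frame(
    sample_id = ids, population = pm$population[match(ids, pm$sample_id)]
  )
  genotype_matrix(dos, loci, samples)
}
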