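#' Read gene intervals from BED or GFF3
#'
#' Standard-format parsing is delegated to \pkg{rtracklayer}; intervals
#' are returned with 1-based inclusive coordinates (BED's 0-based
#' half-open convention is converted on import). For GFF3, only records
#' of the requested feature type are kept and the gene name is taken
#' from the first available of the `Name`, `gene_id` or `ID`
#' attributes.
#'
#' @param path BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return Data frame with `chrom` (character), `start`, `end`
#'   (1-based inclusive), `strand`, `gene`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3"),
                                feature = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
      "bed"
    } else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e))
  )
  if (length(gr) == 0) {
    warning("no intervals in ", path)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene = character(0)))
  }
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    keep <- as.character(md$type) == feature
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    if (length(gr) == 0) {
      warning("no '", feature, "' records in ", path)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        gene = character(0)))
    }
    pick <- function(col) {
      if (col %in% names(md)) as.character(md[[col]]) else
        rep(NA_character_, length(gr))
    }
    gene <- pick("Name")
    for (alt in c("gene_id", "ID")) {
      miss <- is.na(gene)
      if (any(miss)) gene[miss] <- pick(alt)[miss]
    }
  } else {
    gene <- if ("name" %in% names(md)) as.character(md$name) else
      paste0("interval_", seq_along(gr))
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = gene
  )
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    gene = genes$gene
  )
}

# put two GRanges on a shared seqlevel universe so overlap queries do
# not warn when one object lacks a chromosome entirely
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

#' Genes overlapping candidate windows
#'
#' Lists every gene whose interval intersects a candidate window. When
#' merged candidate sets for several breeds are supplied, windows
#' present in two or more breeds' sets are excluded from the
#' breed-specific lists and reported separately (shared windows mark a
#' difference between two breeds rather than a breed-specific sweep).
#'
#' @param wt A [build_windows()] table.
#' @param genes Gene table from [read_gene_intervals()]; chromosome
#'   names must match the genotype chromosome codes (after any mapping
#'   applied by the caller).
#' @param merged Named list of merged window-index sets per breed.
#' @return List with `specific` (data frame: `breed`, `window`, `chrom`,
#'   `start`, `end`, `gene`) and `shared` (same columns with `breeds`
#'   instead of `breed`).
#' @export
genes_in_windows <- function(wt, genes, merged) {
  gg <- genes_to_granges(genes)
  ov <- cross_breed_overlap(merged)
  shared_w <- ov$windows$window
  hit_genes <- function(wins) {
    rows <- wt[match(wins, wt$window), , drop = FALSE]
    wr <- GenomicRanges::GRanges(
      seqnames = as.character(rows$chrom),
      ranges = IRanges::IRanges(rows$start, rows$end)
    )
    al <- align_seqlevels(wr, gg)
    h <- GenomicRanges::findOverlaps(al[[1]], al[[2]])
    data.frame(
      window = rows$window[S4Vectors::queryHits(h)],
      chrom = rows$chrom[S4Vectors::queryHits(h)],
      start = rows$start[S4Vectors::queryHits(h)],
      end = rows$end[S4Vectors::queryHits(h)],
      gene = gg$gene[S4Vectors::subjectHits(h)]
    )
  }
  specific <- do.call(rbind, lapply(names(merged), function(b) {
    wins <- setdiff(merged[[b]], shared_w)
    if (length(wins) == 0) return(NULL)
    out <- hit_genes(wins)
    if (nrow(out) == 0) return(NULL)
    cbind(breed = b, out)
  }))
  shared <- NULL
  if (length(shared_w) > 0) {
    shared <- hit_genes(shared_w)
    if (nrow(shared) > 0) {
      shared <- cbind(
        breeds = ov$windows$breeds[match(shared$window, ov$windows$window)],
        shared
      )
    }
  }
  empty <- data.frame(breed = character(0), window = integer(0),
                      chrom = integer(0), start = integer(0),
                      end = integer(0), gene = character(0))
  list(specific = if (is.null(specific)) empty else specific,
       shared = if (is.null(shared)) empty else shared)
}

#' Genes in or near each window's peak SNP
#'
#' For every candidate window of a breed, reports genes whose interval
#' contains the window's peak SNP or lies within `near_bp` of it -- the
#' second, stricter screen that narrows window-level gene lists to the
#' neighborhood of the strongest signal.
#'
#' @param wt A [build_windows()] table.
#' @param genes Gene table from [read_gene_intervals()].
#' @param merged Named list of merged window-index sets per breed.
#' @param scores The [breed_scores()] object (supplies peak SNP
#'   positions).
#' @param near_bp Neighborhood radius around the peak SNP in bp
#'   (default 50,000, about the chip's inter-SNP spacing).
#' @return Data frame: `breed`, `window`, `peak_snp`, `peak_pos`,
#'   `gene`, `distance` (0 when the gene contains the SNP).
#' @export
peak_snp_genes <- function(wt, genes, merged, scores, near_bp = 5e4) {
  gg <- genes_to_granges(genes)
  ov <- cross_breed_overlap(merged)
  shared_w <- ov$windows$window
  out <- lapply(names(merged), function(b) {
    wins <- setdiff(merged[[b]], shared_w)
    if (length(wins) == 0) return(NULL)
    rows <- wt[match(wins, wt$window), , drop = FALSE]
    peak_id <- rows[[paste0("peak_", b)]]
    ppos <- scores$loci$pos[match(peak_id, scores$loci$id)]
    pr <- GenomicRanges::GRanges(
      seqnames = as.character(rows$chrom),
      ranges = IRanges::IRanges(ppos, ppos)
    )
    al <- align_seqlevels(pr, gg)
    pr <- al[[1]]
    gga <- al[[2]]
    h <- GenomicRanges::findOverlaps(pr, gga, maxgap = near_bp)
    if (length(h) == 0) return(NULL)
    q <- S4Vectors::queryHits(h)
    s <- S4Vectors::subjectHits(h)
    dist <- GenomicRanges::distance(pr[q], gga[s])
    data.frame(
      breed = b, window = rows$window[q], peak_snp = peak_id[q],
      peak_pos = ppos[q], gene = gg$gene[s], distance = dist
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(breed = character(0), window = integer(0),
                      peak_snp = character(0), peak_pos = integer(0),
                      gene = character(0), distance = integer(0))
  }
  out
}
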