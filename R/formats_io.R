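## Readers and writers for the external formats: aligned multi-FASTA,
## metadata TSV, Rtab gene presence/absence, abundance TSV, VCF 4.2,
## Newick, BED. All internal coordinates are 1-based inclusive; BED's
## 0-based half-open convention is applied only at the writer/reader
## boundary.

#' Construct an aligned genome set
#'
#' @param mat Character matrix (strains x positions) over
#'   `A,C,G,T,N,-`, rownames are strain ids and must include `ref_id`.
#' @param ref_id Row name of the reference record.
#' @return An object of class `aligned_genomes`.
#' @export
aligned_genomes <- function(mat, ref_id) {
  if (!is.matrix(mat) || !is.character(mat))
    stop_param("mat must be a character matrix")
  if (is.null(rownames(mat)) || !ref_id %in% rownames(mat))
    stop_param("reference record '", ref_id, "' not found")
  refrow <- mat[ref_id, ]
  if (any(refrow %in% c("N", "-")))
    stop_format("reference record contains ambiguous bases or gaps")
  structure(list(mat = mat, ref_id = ref_id), class = "aligned_genomes")
}

#' @export
print.aligned_genomes <- function(x, ...) {
  cat("aligned_genomes:", nrow(x$mat) - 1L, "strains + reference '",
      x$ref_id, "', ", ncol(x$mat), "bp\n")
  invisible(x)
}

#' Strain identifiers of an aligned genome set (reference excluded)
#' @param genomes An `aligned_genomes` object.
#' @return Character vector.
#' @export
strain_ids <- function(genomes) {
  setdiff(rownames(genomes$mat), genomes$ref_id)
}

#' Subset an aligned genome set by strain
#'
#' Keeps the reference record and the requested strains.
#'
#' @param genomes An `aligned_genomes` object.
#' @param strains Strain ids to keep.
#' @return An `aligned_genomes` object.
#' @export
subset_genomes <- function(genomes, strains) {
  missing <- setdiff(strains, rownames(genomes$mat))
  if (length(missing) > 0L)
    stop_param("unknown strain(s): ", paste(missing, collapse = ", "))
  aligned_genomes(genomes$mat[unique(c(genomes$ref_id, strains)), ,
                              drop = FALSE],
                  ref_id = genomes$ref_id)
}

#' Read an aligned multi-FASTA into an `aligned_genomes` object
#'
#' All records must be equal length; bases are uppercased on read;
#' alphabet `A,C,G,T,N,-`.
#'
#' @param path FASTA file.
#' @param ref_id Record id of the reference; default the first record.
#' @return An `aligned_genomes` object.
#' @export
read_aligned_fasta <- function(path, ref_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_format("empty FASTA file: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    tab <- table(widths)
    cand <- as.integer(names(tab)[tab == max(tab)])
    modal <- if (widths[1L] %in% cand) widths[1L] else cand[1L]
    bad <- names(seqs)[widths != modal][1L]
    stop_format("records have unequal lengths; offending record: ", bad)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  mat <- matrix(unlist(strsplit(chars, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L)
    stop_format("invalid characters in alignment: ",
                paste(bad, collapse = ", "))
  aligned_genomes(mat, ref_id = ref_id %||% ids[1L])
}

#' Write an aligned genome set as multi-FASTA
#' @param genomes An `aligned_genomes` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(genomes, path) {
  seqs <- Biostrings::BStringSet(apply(genomes$mat, 1L, paste0, collapse = ""))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a Roary-style Rtab gene presence/absence matrix
#'
#' Tab-separated; first column gene ids, remaining columns one per strain,
#' cells strictly 0/1.
#'
#' @param path Rtab file.
#' @return Integer gene x strain matrix.
#' @export
read_rtab <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop_format("Rtab needs gene id + strain columns")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop_format("duplicate gene ids in Rtab")
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!m %in% c("0", "1"))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(m))
    stop_format("non-binary Rtab cell at gene '", genes[rc[1L]],
                "', strain '", colnames(m)[rc[2L]], "': '", m[bad[1L]], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a gene presence/absence matrix in Rtab dialect
#' @param genes Integer 0/1 gene x strain matrix with dimnames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rtab <- function(genes, path) {
  df <- data.frame(Gene = rownames(genes), genes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_columns <- c("strain_id", "sample_id", "country", "province",
                      "city", "community_id", "family_id", "host_species",
                      "age", "sex", "longevous_district")

#' Read strain metadata
#'
#' Tab-separated with header; missing cells (`NA` or empty) are preserved
#' as missing, never imputed. `age` must be non-negative where present;
#' `strain_id` must be unique.
#'
#' @param path Metadata TSV.
#' @return A data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (!"strain_id" %in% names(df)) stop_format("metadata lacks strain_id")
  if (anyDuplicated(df$strain_id))
    stop_format("duplicate strain_id: ",
                df$strain_id[duplicated(df$strain_id)][1L])
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    if (any(df$age < 0, na.rm = TRUE))
      stop_format("negative age in metadata")
  }
  if ("longevous_district" %in% names(df))
    df$longevous_district <- as.logical(toupper(df$longevous_district))
  df
}

#' Write strain metadata TSV
#' @param metadata A metadata data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample x taxon abundance TSV
#'
#' Tab-separated, first column sample ids, one column per taxon.
#'
#' @param path Abundance TSV.
#' @return Numeric sample x taxon matrix.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!is.numeric(m)) stop_format("non-numeric abundance cells")
  if (any(m < 0)) stop_format("negative abundance cells")
  m
}

#' Write a sample x taxon abundance TSV
#' @param abundance Numeric sample x taxon matrix with dimnames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(sample_id = rownames(abundance), abundance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SNP matrix as VCF 4.2 with haploid genotypes
#'
#' `CHROM` is the reference id, `POS` the 1-based reference coordinate,
#' genotypes `0`/`1`/`.` (missing).
#'
#' @param snps A `snp_matrix` (see [call_core_snps()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "snp_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", snps$ref_id,
                       snps$genome_length),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(snps$geno)), collapse = "\t")),
             con)
  if (length(snps$pos) > 0L) {
    gt <- ifelse(is.na(snps$geno), ".", as.character(snps$geno))
    body <- paste(snps$ref_id, snps$pos, ".", snps$ref, snps$alt, ".",
                  "PASS", ".", "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a haploid VCF written by [write_vcf()] back into a `snp_matrix`
#'
#' @param path VCF file.
#' @param genome_length Reference length; default taken from the contig
#'   header line.
#' @return A `snp_matrix`.
#' @export
read_vcf <- function(path, genome_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- t(apply(gt, 1L, function(r) suppressWarnings(as.integer(r))))
  if (nrow(fix) == 1L) geno <- matrix(geno, nrow = 1L)
  geno <- t(geno)
  dimnames(geno) <- list(colnames(gt), NULL)
  if (is.null(genome_length)) {
    ctg <- grep("^##contig", v@meta, value = TRUE)
    genome_length <- if (length(ctg) > 0L)
      as.integer(sub(".*length=(\\d+).*", "\\1", ctg[1L]))
    else max(as.integer(fix[, "POS"]))
  }
  new_snp_matrix(pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                 alt = fix[, "ALT"], geno = geno,
                 ref_id = fix[1L, "CHROM"], genome_length = genome_length)
}

#' Write a tree in Newick format
#' @param tree An `ape::phylo` tree.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write masked intervals as BED
#'
#' Internal intervals are 1-based inclusive; BED output is 0-based
#' half-open, so an interval covering reference bases 101-200 becomes
#' `chrom 100 200`.
#'
#' @param intervals Named list (one element per strain) of two-column
#'   matrices `[start, end]`, 1-based inclusive; or a single matrix.
#' @param chrom Chromosome (reference) id.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, chrom, path) {
  if (is.matrix(intervals)) intervals <- list(region = intervals)
  rows <- character(0)
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (is.null(iv) || nrow(iv) == 0L) next
    rows <- c(rows, sprintf("%s\t%d\t%d\t%s", chrom,
                            as.integer(iv[, 1L]) - 1L,
                            as.integer(iv[, 2L]), nm))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED file.
#' @return Named list (by the BED name column, or `region`) of two-column
#'   matrices, 1-based inclusive.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "region",
               character(1))
  st <- vapply(parts, function(p) as.integer(p[2L]), integer(1)) + 1L
  en <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
  out <- list()
  for (u in unique(nm))
    out[[u]] <- cbind(start = st[nm == u], end = en[nm == u])
  out
}
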