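# File interchange: VCF with per-sample allele depths, GFF3 gene models,
# phenotype CSV, marker/panel/hit TSV tables.

#' Write GBS read counts as a VCF with AD fields
#'
#' Emits one VCF record per site with `QD` in INFO and per-sample
#' `GT:AD:DP` fields; the genotype is left uncalled (`./.`) since
#' downstream scoring works from the allele depths. Coordinates are
#' 1-based inclusive.
#'
#' @param sites data.frame(site_id, chrom, pos_bp) aligned with the count
#'   matrices.
#' @param ref,alt sites x samples read-count matrices.
#' @param qd per-site QD values.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_gbs_vcf <- function(sites, ref, alt, qd, path) {
  samples <- colnames(ref)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- matrix(paste0("./.:", ref, ",", alt, ":", ref + alt),
               nrow(ref), ncol(ref))
  body <- apply(cbind(sites$chrom, sites$pos_bp, sites$site_id, "A", "G",
                      ".", "PASS", sprintf("QD=%.2f", qd), "GT:AD:DP", gt),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GBS VCF into sites and allele-depth matrices
#'
#' Parses a VCF (via vcfR) and extracts per-sample ref/alt read counts
#' from the AD field, QD from INFO, the number of ALT alleles, and the
#' pooled alt-read frequency per site -- the inputs [filter_sites()] and
#' [score_matrix()] need.
#'
#' @param path VCF file path.
#' @return list with `sites` (data.frame site_id, chrom, pos_bp,
#'   n_alleles, qd, pooled_alt_freq), `ref` and `alt` count matrices.
#' @export
read_gbs_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  ref <- apply(ad, 2, function(x)
    suppressWarnings(as.integer(sub(",.*", "", x))))
  alt1 <- apply(ad, 2, function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    suppressWarnings(vapply(parts, function(p)
      if (length(p) >= 2) as.integer(p[2]) else NA_integer_, integer(1)))
  })
  ref[is.na(ref)] <- 0L; alt1[is.na(alt1)] <- 0L
  qd <- suppressWarnings(as.numeric(sub(".*QD=([-0-9.eE]+).*", "\\1",
                                        fix$INFO)))
  qd[!grepl("QD=", fix$INFO)] <- NA_real_
  n_alleles <- 1L + vapply(strsplit(fix$ALT, ",", fixed = TRUE), length,
                           integer(1))
  tot <- rowSums(ref) + rowSums(alt1)
  sites <- data.frame(
    site_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
    n_alleles = n_alleles, qd = qd,
    pooled_alt_freq = ifelse(tot > 0, rowSums(alt1) / tot, 0),
    stringsAsFactors = FALSE)
  rownames(ref) <- rownames(alt1) <- sites$site_id
  list(sites = sites, ref = ref, alt = alt1)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame(gene_id, chrom, start, end, strand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\twaxmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features and their ID attribute; 1-based inclusive
#' coordinates are preserved.
#'
#' @param path GFF3 file path.
#' @return data.frame(gene_id, chrom, start, end, strand).
#' @export
read_gene_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) length(x) == 9 && x[3] == "gene",
                logical(1))]
  data.frame(
    gene_id = vapply(f, function(x)
      sub(".*ID=([^;]+).*", "\\1", x[9]), character(1)),
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 4)),
    end = as.integer(vapply(f, `[`, character(1), 5)),
    strand = vapply(f, `[`, character(1), 7),
    stringsAsFactors = FALSE)
}

#' Write / read a marker table as TSV
#'
#' Per-progeny scores are serialized as a string over `A B H C D -` so a
#' marker is one row regardless of population size.
#'
#' @param markers a `marker_table`.
#' @param path file path.
#' @return `path` (write) or a `marker_table` (read).
#' @export
write_marker_tsv <- function(markers, path) {
  df <- markers$info
  df$scores <- apply(markers$scores, 1, paste, collapse = "")
  write_tsv_plain(df, path)
}

#' @rdname write_marker_tsv
#' @param progeny_names optional progeny column names to restore.
#' @export
read_marker_tsv <- function(path, progeny_names = NULL) {
  df <- read_tsv_plain(path)
  sc <- do.call(rbind, strsplit(df$scores, ""))
  rownames(sc) <- df$marker_id
  if (!is.null(progeny_names)) colnames(sc) <- progeny_names
  df$scores <- NULL
  structure(list(info = df, scores = sc), class = "marker_table")
}

#' Write / read a phenotype CSV (sample, trait, value)
#'
#' @param pheno data.frame(sample, trait, value) or a named numeric
#'   vector (single trait).
#' @param path file path.
#' @param trait trait name used when `pheno` is a vector.
#' @return `path` (write) or a data.frame (read).
#' @export
write_phenotype_csv <- function(pheno, path, trait = "trait") {
  if (is.numeric(pheno))
    pheno <- data.frame(sample = names(pheno), trait = trait,
                        value = as.numeric(pheno))
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an accession panel as TSV
#'
#' Sites in rows, accessions in columns, genotype dosage 0/1/2 with `NA`
#' for missing calls; ecotype labels in a companion CSV.
#'
#' @param panel panel list (geno, ecotype, sites).
#' @param path genotype TSV path.
#' @param labels_path ecotype label CSV path.
#' @return `path` (write) or a panel list (read).
#' @export
write_panel_tsv <- function(panel, path, labels_path) {
  df <- cbind(panel$sites[, c("chrom", "pos_bp")],
              as.data.frame(panel$geno))
  df <- cbind(site_id = rownames(panel$geno), df)
  write_tsv_plain(df, path)
  utils::write.csv(data.frame(accession = colnames(panel$geno),
                              ecotype = as.character(panel$ecotype)),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path, labels_path) {
  df <- read_tsv_plain(path)
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, lab$accession, drop = FALSE])
  rownames(geno) <- df$site_id
  list(geno = geno, ecotype = factor(lab$ecotype),
       sites = df[, c("chrom", "pos_bp")])
}
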