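#' Write a cohort to VCF and TSV fixtures
#'
#' Emits three UTF-8, LF-terminated files into `out_dir`: `genotypes.vcf`
#' (VCF v4.2, one record per locus, haploid GT calls from the consensus and
#' a per-sample `AF` FORMAT field carrying the within-host derived-allele
#' frequency to four decimals), `samples.tsv` (the sample table), and
#' `loci.tsv` (locus annotations). Reading the files back with
#' [read_fixtures] reproduces the matrices (frequencies to 4 decimals).
#'
#' @param samples sample table as from [generate_cohort].
#' @param genotypes a [genotype_matrix].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_fixtures <- function(samples, genotypes, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", out_dir),
                  call. = FALSE)
  }
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    loci = file.path(out_dir, "loci.tsv")
  )
  write_tsv_lf(samples, paths[["samples"]])
  write_tsv_lf(genotypes$loci, paths[["loci"]])

  f <- genotypes$freq
  ids <- rownames(f)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=virus,length=155000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid consensus genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Within-host derived allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  records <- if (nrow(f) == 0L) character(0) else character(ncol(f))
  if (ncol(f) > 0 && nrow(f) > 0) {
    gt <- (f >= 0.5) + 0L
    for (j in seq_len(ncol(f))) {
      fields <- sprintf("%d:%.4f", gt[, j], f[, j])
      records[j] <- paste(c("virus", genotypes$loci$position[j],
                            genotypes$loci$locus_id[j], "A", "T", ".",
                            "PASS", ".", "GT:AF", fields), collapse = "\t")
    }
  }
  con <- file(paths[["vcf"]], open = "wb")
  writeLines(c(header, records), con, sep = "\n", useBytes = TRUE)
  close(con)
  paths
}

write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]])
  }
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Read cohort fixtures back
#'
#' Counterpart of [write_fixtures]: reads the VCF (via `vcfR`), sample TSV
#' and locus TSV and reconstructs the sample table and [genotype_matrix].
#'
#' @param dir directory containing `genotypes.vcf`, `samples.tsv`,
#'   `loci.tsv`.
#' @return List with `samples` and `genotypes`.
#' @export
read_fixtures <- function(dir) {
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  if ("collection_date" %in% names(samples)) {
    samples$collection_date <- as.Date(samples$collection_date)
  }
  if ("log10_titer" %in% names(samples)) {
    samples$log10_titer <- as.numeric(samples$log10_titer)
  }
  loci <- utils::read.delim(file.path(dir, "loci.tsv"),
                            stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  if (nrow(vcf@gt) == 0L || nrow(vcf@fix) == 0L) {
    freq <- matrix(numeric(0), nrow = 0, ncol = nrow(loci),
                   dimnames = list(NULL, loci$locus_id))
    return(list(samples = samples, genotypes = genotype_matrix(freq, loci)))
  }
  af <- vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE)
  # VCF rows are loci; our matrices are samples x loci
  freq <- t(af)
  ord <- match(loci$locus_id, vcf@fix[, "ID"])
  freq <- freq[, ord, drop = FALSE]
  colnames(freq) <- loci$locus_id
  list(samples = samples, genotypes = genotype_matrix(freq, loci))
}
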