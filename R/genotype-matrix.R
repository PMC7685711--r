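#' Genotype matrix of within-host allele frequencies
#'
#' Container pairing a numeric matrix of within-host derived-allele
#' frequencies (samples in rows, viral loci in columns) with per-locus
#' metadata. The consensus genotype of a sample at a locus is derived (1)
#' when its within-host frequency is at least 0.5, ancestral (0) otherwise,
#' mirroring consensus viral sequences called per infected host.
#'
#' @param freq numeric matrix in \[0, 1\]; rownames are sample ids and
#'   colnames are locus ids.
#' @param loci data.frame with one row per column of `freq`, columns
#'   `locus_id`, `position` (1-based bp, strictly increasing), `annotation`
#'   (one of upstream, downstream, intergenic, synonymous, nonsynonymous,
#'   nonsense), `gene`, `focal` (logical), `focal_order` (integer rank of the
#'   focal locus in the mutational order, `NA` for non-focal loci).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(freq, loci) {
  if (!is.matrix(freq) || !is.numeric(freq)) {
    stop_field("freq", "must be a numeric matrix")
  }
  if (nrow(loci) != ncol(freq)) {
    stop_field("loci", "must have one row per column of `freq`")
  }
  needed <- c("locus_id", "position", "annotation", "gene", "focal",
              "focal_order")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols)) {
    stop_field("loci", paste("missing column(s):",
                             paste(missing_cols, collapse = ", ")))
  }
  if (ncol(freq) > 0) {
    if (anyNA(freq) || any(freq < 0) || any(freq > 1)) {
      stop_field("freq", "frequencies must lie in [0, 1]")
    }
    if (any(diff(loci$position) <= 0)) {
      stop_field("loci", "positions must be strictly increasing")
    }
    colnames(freq) <- loci$locus_id
  }
  ann_ok <- c("upstream", "downstream", "intergenic", "synonymous",
              "nonsynonymous", "nonsense")
  if (ncol(freq) > 0 && !all(loci$annotation %in% ann_ok)) {
    stop_field("loci", paste("annotation must be one of:",
                             paste(ann_ok, collapse = ", ")))
  }
  structure(list(freq = freq, loci = as.data.frame(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d focal)\n",
              nrow(x$freq), ncol(x$freq), sum(x$loci$focal)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$freq)

#' Consensus haploid genotypes
#'
#' Collapses within-host allele frequencies to haploid 0/1 consensus calls
#' (derived when frequency >= 0.5).
#'
#' @param matrix a [genotype_matrix].
#' @return Integer matrix of 0/1 consensus calls, samples x loci.
#' @export
consensus_calls <- function(matrix) {
  g <- matrix$freq
  out <- (g >= 0.5) + 0L
  storage.mode(out) <- "integer"
  out
}

# Subset a genotype_matrix by sample and/or locus index.
subset_genotype_matrix <- function(matrix, samples = NULL, loci = NULL) {
  freq <- matrix$freq
  info <- matrix$loci
  if (!is.null(samples)) freq <- freq[samples, , drop = FALSE]
  if (!is.null(loci)) {
    freq <- freq[, loci, drop = FALSE]
    info <- info[loci, , drop = FALSE]
    rownames(info) <- NULL
  }
  genotype_matrix(freq, info)
}

# Resolve locus identifiers (character ids or indices) to column indices.
match_loci <- function(matrix, loci) {
  if (is.character(loci)) {
    idx <- match(loci, matrix$loci$locus_id)
    if (anyNA(idx)) {
      stop(sprintf("locus not found: %s",
                   paste(loci[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    idx
  } else {
    as.integer(loci)
  }
}
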