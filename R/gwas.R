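#' Minor-carrier filter and linkage clumping
#'
#' Reproduces the pre-association marker filtering: loci whose consensus
#' derived allele is carried by fewer than `min_carriers` infected samples
#' are dropped, then loci in near-perfect linkage (pairwise r2 at or above
#' `r2_threshold`) within `window` bp of a representative are greedily
#' merged into that representative. Representatives are chosen in ascending
#' position order, so the lowest position wins.
#'
#' @param matrix a [genotype_matrix] over infected samples.
#' @param min_carriers minimum number of consensus-derived carriers.
#' @param r2_threshold linkage threshold treated as "perfect".
#' @param window maximum distance in bp between a representative and a
#'   merged locus.
#' @return A [genotype_matrix] of representative loci, with attribute
#'   `merged` (named list: members merged into each representative) and
#'   `dropped` (locus ids failing the carrier filter).
#' @export
filter_and_clump <- function(matrix, min_carriers = 5L, r2_threshold = 0.99,
                             window = 10000) {
  if (ncol(matrix$freq) == 0L) stop("empty genotype matrix", call. = FALSE)
  g <- consensus_calls(matrix)
  carriers <- colSums(g == 1L)
  keep <- which(carriers >= min_carriers)
  dropped <- matrix$loci$locus_id[carriers < min_carriers]
  m <- subset_genotype_matrix(matrix, loci = keep)
  L <- ncol(m$freq)
  if (L == 0L) {
    out <- m
    attr(out, "merged") <- list()
    attr(out, "dropped") <- dropped
    return(out)
  }
  gk <- consensus_calls(m)
  pos <- m$loci$position
  assigned <- rep(NA_integer_, L)   # representative index per locus
  for (i in seq_len(L)) {
    if (!is.na(assigned[i])) next
    assigned[i] <- i
    j <- i + 1L
    while (j <= L && pos[j] - pos[i] <= window) {
      if (is.na(assigned[j]) &&
          !is.na(r2 <- r2_pair(gk[, i], gk[, j])) && r2 >= r2_threshold) {
        assigned[j] <- i
      }
      j <- j + 1L
    }
  }
  reps <- sort(unique(assigned))
  merged <- lapply(reps, function(r) m$loci$locus_id[assigned == r &
                                                       seq_len(L) != r])
  names(merged) <- m$loci$locus_id[reps]
  out <- subset_genotype_matrix(m, loci = reps)
  attr(out, "merged") <- merged
  attr(out, "dropped") <- dropped
  out
}

# r2 between two binary vectors; NA when either is monomorphic.
r2_pair <- function(a, b) {
  pa <- mean(a); pb <- mean(b)
  va <- pa * (1 - pa); vb <- pb * (1 - pb)
  if (va == 0 || vb == 0) return(NA_real_)
  (mean(a & b) - pa * pb)^2 / (va * vb)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values, preserving the input order.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return q values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# Prepare the shared parts of the titer association model for one cohort:
# align samples to matrix rows, restrict to infected samples with titer,
# expand covariates, and append the top eigenvectors of the centered
# genotype relationship matrix (fixed-covariate stand-in for a kinship term).
prepare_gwas <- function(matrix, samples,
                         covariates = c("sex", "population"),
                         n_relationship_components = 5L,
                         snp_interactions = "sex") {
  sid <- rownames(matrix$freq)
  idx <- match(sid, samples$sample_id)
  if (anyNA(idx)) stop("matrix contains samples absent from the table",
                       call. = FALSE)
  st <- samples[idx, , drop = FALSE]
  keep <- which(st$infected & !is.na(st$log10_titer))
  if (length(keep) < 10L) {
    stop("need >= 10 infected samples with non-missing titer", call. = FALSE)
  }
  st <- st[keep, , drop = FALSE]
  f <- matrix$freq[keep, , drop = FALSE]
  for (cv in covariates) {
    if (!cv %in% names(st)) {
      stop(sprintf("covariate not found in sample table: %s", cv),
           call. = FALSE)
    }
  }
  # drop covariates constant in the analysed subset (non-estimable)
  usable <- covariates[vapply(covariates,
                              function(cv) length(unique(st[[cv]])) > 1L,
                              logical(1))]
  Z <- matrix(1, nrow = nrow(st), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  inter <- NULL
  if (length(usable)) {
    df <- st[usable]
    df[] <- lapply(df, function(x) if (is.character(x) || is.logical(x))
      factor(x) else x)
    mm <- stats::model.matrix(~ ., data = df)
    Z <- mm
    snp_interactions <- intersect(snp_interactions, usable)
    if (length(snp_interactions)) {
      cols <- unlist(lapply(snp_interactions, function(cv) {
        grep(paste0("^", cv), colnames(mm), value = TRUE)
      }))
      inter <- mm[, cols, drop = FALSE]
    }
  }
  n_comp <- min(n_relationship_components, nrow(st) - 1L)
  if (n_comp > 0 && ncol(f) > 0) {
    gc <- scale(f, center = TRUE, scale = FALSE)
    ev <- eigen(tcrossprod(gc), symmetric = TRUE)
    pos <- which(ev$values > 1e-8 * max(ev$values, 1e-300))
    n_comp <- min(n_comp, length(pos))
    if (n_comp > 0) {
      U <- ev$vectors[, seq_len(n_comp), drop = FALSE]
      colnames(U) <- sprintf("PC%d", seq_len(n_comp))
      Z <- cbind(Z, U)
    }
  }
  list(freq = f, y = st$log10_titer, Z = Z, inter = inter, samples = st,
       loci = matrix$loci)
}

# Per-locus least-squares scaffold: QR of [Z, snp, snp x interactions] with
# the pieces needed to test the SNP main effect for many phenotype vectors.
locus_qr <- function(prep, j) {
  x <- prep$freq[, j]
  if (stats::var(x) == 0) return(list(skip = "zero variance"))
  X <- cbind(prep$Z, snp = x)
  if (!is.null(prep$inter)) {
    XI <- prep$inter * x
    colnames(XI) <- paste0("snp:", colnames(prep$inter))
    X <- cbind(X, XI)
  }
  qx <- qr(X)
  r <- qx$rank
  n <- nrow(X)
  if (n - r <= 0) return(list(skip = "no residual degrees of freedom"))
  snp_col <- which(colnames(X) == "snp")
  pos <- match(snp_col, qx$pivot[seq_len(r)])
  if (is.na(pos)) return(list(skip = "singular (SNP aliased)"))
  R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
  cjj <- chol2inv(R)[pos, pos]
  list(qx = qx, R = R, r = r, n = n, pos = pos, cjj = cjj)
}

# Test the SNP main effect for phenotype y given a locus_qr scaffold.
locus_test <- function(lq, y) {
  qty <- qr.qty(lq$qx, y)
  coef <- backsolve(lq$R, qty[seq_len(lq$r)])
  rss <- sum(qty[(lq$r + 1):lq$n]^2)
  df <- lq$n - lq$r
  se <- sqrt(rss / df * lq$cjj)
  est <- coef[lq$pos]
  tval <- est / se
  c(est = est, se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), df))
}

#' Per-SNP association of within-host allele frequency with log10 titer
#'
#' For each locus, fits ordinary least squares of log10 titer on the
#' within-host derived-allele frequency plus the requested covariates, a
#' SNP-by-sex interaction (when sex is among the covariates), and the top
#' eigenvectors of the centered genotype relationship matrix (adjusting for
#' strain relatedness and population structure). Reports the SNP
#' main-effect estimate, standard error, t statistic, p value, and BH
#' q value. Monomorphic or aliased loci are skipped with a recorded reason.
#'
#' @param matrix a [genotype_matrix] over infected samples.
#' @param samples sample table with `sample_id`, `infected`, `log10_titer`
#'   and the covariate columns.
#' @param covariates covariate column names (default sex and population).
#' @param n_relationship_components number of relationship-matrix
#'   eigenvectors included as fixed covariates.
#' @param snp_interactions covariates whose interaction with the SNP
#'   frequency is included (intersected with `covariates`).
#' @param consensus use 0/1 consensus coding of the SNP instead of the
#'   within-host frequency.
#' @return data.frame of class `titer_gwas` with columns locus_id, position,
#'   effect, se, t, p, q; attributes `skipped` (data.frame of locus_id and
#'   reason) and `n` (samples analysed).
#' @export
fit_titer_gwas <- function(matrix, samples,
                           covariates = c("sex", "population"),
                           n_relationship_components = 5L,
                           snp_interactions = "sex",
                           consensus = FALSE) {
  if (consensus) matrix$freq <- consensus_calls(matrix) + 0
  prep <- prepare_gwas(matrix, samples, covariates,
                       n_relationship_components, snp_interactions)
  gwas_from_prep(prep)
}

gwas_from_prep <- function(prep, y = prep$y) {
  L <- ncol(prep$freq)
  rows <- vector("list", L)
  skipped <- list()
  for (j in seq_len(L)) {
    lq <- locus_qr(prep, j)
    if (!is.null(lq$skip)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(locus_id = prep$loci$locus_id[j], reason = lq$skip)
      next
    }
    rows[[j]] <- c(j, locus_test(lq, y))
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    out <- data.frame(locus_id = character(0), position = integer(0),
                      effect = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), q = numeric(0))
  } else {
    j <- m[, 1]
    out <- data.frame(
      locus_id = prep$loci$locus_id[j],
      position = prep$loci$position[j],
      effect = m[, "est"], se = m[, "se"], t = m[, "t"], p = m[, "p"],
      q = bh_fdr(m[, "p"]),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(locus_id = character(0), reason = character(0))
  attr(out, "n") <- length(y)
  class(out) <- c("titer_gwas", "data.frame")
  out
}

#' @export
print.titer_gwas <- function(x, n = 10L, ...) {
  if (is.null(x$p)) return(NextMethod())   # column subsets print plainly
  sk <- attr(x, "skipped")
  cat(sprintf("titer GWAS: %d loci tested on %s samples (%d skipped)\n",
              nrow(x), format(attr(x, "n") %||% NA),
              if (is.null(sk)) 0L else nrow(sk)))
  ord <- order(x$p)
  print.data.frame(utils::head(x[ord, , drop = FALSE], n), digits = 4)
  invisible(x)
}

#' @export
summary.titer_gwas <- function(object, fdr = 0.01, ...) {
  sig <- sum(object$q < fdr)
  cat(sprintf("%d of %d loci significant at FDR < %g\n",
              sig, nrow(object), fdr))
  invisible(list(n_significant = sig, fdr = fdr))
}
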