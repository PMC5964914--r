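#' Single-marker association scan
#'
#' Least-squares regression of a binary trait on each marker dosage plus
#' covariates, on the observed 0/1 scale; two-sided p-values from the t
#' statistic. Monomorphic markers are flagged (`usable = FALSE`) and
#' excluded from top-marker selection. An optional conditioning covariate
#' (e.g. the current top marker's dosage) can be added to re-scan
#' conditionally.
#'
#' @param geno a [geno_matrix()] with complete dosages in the scanned region.
#' @param trait named binary vector, or a column name of `phe`.
#' @param phe optional [phenotype_table()] supplying the trait by name
#'   (`"pnp"` or `"hnh"`).
#' @param covariates optional matrix/data.frame of covariates (rows matching
#'   the scanned animals), e.g. a sex indicator.
#' @param chrom,start,end optional closed-interval region restriction.
#' @param condition_on optional marker id whose dosage is added as a
#'   covariate.
#' @return data.frame of class `gwas_result`: per marker `chrom`, `pos`,
#'   `beta`, `se`, `stat`, `p`, `neglog10p`, `usable`.
#' @export
gwas_scan <- function(geno, trait, phe = NULL, covariates = NULL,
                      chrom = NULL, start = NULL, end = NULL,
                      condition_on = NULL) {
  if (is.character(trait) && length(trait) == 1) {
    if (is.null(phe)) stop("supply phe when trait is given by name")
    y <- stats::setNames(phe[[trait]], phe$animal)
  } else {
    y <- trait
  }
  if (is.null(names(y))) stop("trait must be named by animal id")
  ids <- intersect(geno$animal_ids, names(y))
  if (length(ids) < 3) stop("fewer than 3 genotyped, phenotyped animals")
  g <- subset_geno(geno, chrom = chrom, start = start, end = end,
                   animals = ids)
  y <- as.numeric(y[ids])
  if (!all(y %in% c(0, 1))) stop("trait must be binary 0/1")
  D <- g$dosage
  storage.mode(D) <- "double"
  if (anyNA(D)) stop("missing dosages in scan region: impute or subset first")
  X0 <- matrix(1, length(ids), 1)
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  if (!is.null(condition_on)) {
    if (!condition_on %in% geno$markers$marker_id) {
      stop("conditioning marker not found: ", condition_on)
    }
    X0 <- cbind(X0, geno$dosage[ids, condition_on])
  }
  # residualise y and dosages on covariates, then per-marker simple LS
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RD <- qr.resid(qr0, D)
  sxx <- colSums(RD^2)
  usable <- sxx > 1e-12
  beta <- ifelse(usable, colSums(RD * ry) / sxx, NA)
  df <- length(y) - ncol(X0) - 1
  rss <- pmax(sum(ry^2) - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  stat <- beta / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  out <- data.frame(marker_id = g$markers$marker_id, chrom = g$markers$chrom,
                    pos = g$markers$pos, beta = beta, se = se, stat = stat,
                    p = p, neglog10p = -log10(p), usable = usable,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- if (is.character(trait)) trait else deparse(substitute(trait))
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Write a scan result as TSV
#'
#' Columns: marker, chromosome, position, effect, statistic, p,
#' -log10(p), usable flag.
#'
#' @param scan a [gwas_scan()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select the top markers of a scan
#'
#' The `k` smallest p-values among usable markers; ties are broken by
#' distance to `causal_pos` (nearer first), then by lower bp position.
#'
#' @param scan a [gwas_scan()] result.
#' @param k number of markers.
#' @param causal_pos reference position for tie-breaking (default the
#'   causal insertion position 29,456,047).
#' @return the selected rows, ordered by ascending p.
#' @export
top_markers <- function(scan, k, causal_pos = 29456047) {
  s <- scan[scan$usable & !is.na(scan$p), , drop = FALSE]
  if (nrow(s) == 0) stop("empty scan: no usable markers")
  if (k > nrow(s)) stop("k = ", k, " exceeds ", nrow(s), " usable markers")
  ord <- order(s$p, abs(s$pos - causal_pos), s$pos)
  s[ord[seq_len(k)], , drop = FALSE]
}

#' Genotype-by-phenotype tabulation
#'
#' Per sex and genotype class (0/1/2): counts of trait 0 and trait 1 and
#' the conditional probability of the "1" phenotype, i.e. the mean of the
#' binary trait in that genotype class. Probabilities are reported rounded
#' (default 2 decimals) with full precision retained in `prob_full`. Empty
#' genotype classes report a missing (`NA`) probability, not 0.
#'
#' @param genotype integer vector of dosages (0/1/2) or a marker id with
#'   `geno` supplied.
#' @param trait binary 0/1 vector.
#' @param sex character vector of sex labels.
#' @param geno optional [geno_matrix()] when `genotype` is a marker id.
#' @param digits rounding for the reported probability.
#' @return data.frame of class `geno_pheno_table` with columns `sex`,
#'   `genotype`, `n0`, `n1`, `prob`, `prob_full`.
#' @export
genotype_phenotype_table <- function(genotype, trait, sex, geno = NULL,
                                     digits = 2) {
  if (is.character(genotype) && length(genotype) == 1) {
    if (is.null(geno)) stop("supply geno when genotype is a marker id")
    genotype <- geno$dosage[, genotype]
  }
  trait <- as.numeric(trait)
  if (!all(trait %in% c(0, 1))) stop("trait must be binary 0/1")
  stopifnot(length(genotype) == length(trait), length(sex) == length(trait))
  out <- expand.grid(genotype = 0:2, sex = sort(unique(as.character(sex))),
                     stringsAsFactors = FALSE)[, c("sex", "genotype")]
  out$n0 <- out$n1 <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- sex == out$sex[r] & genotype == out$genotype[r] & !is.na(genotype)
    out$n0[r] <- sum(trait[sel] == 0)
    out$n1[r] <- sum(trait[sel] == 1)
  }
  tot <- out$n0 + out$n1
  out$prob_full <- ifelse(tot > 0, out$n1 / tot, NA)
  out$prob <- round(out$prob_full, digits)
  class(out) <- c("geno_pheno_table", "data.frame")
  out
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of dosages (composite LD, no phase needed).
#' When the object is phased, the haplotypic r2 (correlation across the 2n
#' chromosome copies) is attached as attribute `"r2_haplotypic"`.
#'
#' @param geno a [geno_matrix()].
#' @param marker_a,marker_b marker ids.
#' @return numeric r2 (with optional attribute `r2_haplotypic`).
#' @export
ld_r2 <- function(geno, marker_a, marker_b) {
  for (mk in c(marker_a, marker_b)) {
    if (!mk %in% geno$markers$marker_id) stop("marker not found: ", mk)
  }
  a <- geno$dosage[, marker_a]; b <- geno$dosage[, marker_b]
  ok <- !is.na(a) & !is.na(b)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    stop("monomorphic marker: r2 undefined")
  }
  r2 <- stats::cor(a[ok], b[ok])^2
  if (geno$phased) {
    ha <- c(geno$hap1[ok, marker_a], geno$hap2[ok, marker_a])
    hb <- c(geno$hap1[ok, marker_b], geno$hap2[ok, marker_b])
    if (stats::var(ha) > 0 && stats::var(hb) > 0) {
      attr(r2, "r2_haplotypic") <- stats::cor(ha, hb)^2
    }
  }
  r2
}
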