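#' Per-marker allele frequencies
#'
#' Frequency of the counted (alt) allele, `p = mean(dosage) / 2` over
#' non-missing calls.
#'
#' @param geno a [geno_matrix()] or a dosage matrix.
#' @return named numeric vector of alt-allele frequencies.
#' @export
allele_frequencies <- function(geno) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0)) {
    stop("all calls missing for marker(s): ",
         paste(colnames(d)[nobs == 0], collapse = ", "))
  }
  colMeans(d, na.rm = TRUE) / 2
}

# 1-df chi-square of observed genotype counts against Hardy-Weinberg
# proportions at the observed allele frequency.
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  o <- cbind(n0, n1, n2)
  e <- cbind(n * (1 - p)^2, n * 2 * p * (1 - p), n * p^2)
  chi <- rowSums((o - e)^2 / ifelse(e > 0, e, Inf))
  as.numeric(chi)
}

#' Marker quality control
#'
#' Applies the chip QC rules: drop a marker when its call rate is below
#' `call_rate_min`, when its genotype counts deviate strongly from
#' Hardy-Weinberg proportions (1-df chi-square above `hwe_chi2_max`), when
#' its minor allele frequency is below `maf_min`, or when it is not
#' autosomal (non-numeric chromosome label). A marker fails if at least one
#' rule fires; every removal is listed with the rule(s) that fired.
#'
#' @param geno a [geno_matrix()].
#' @param call_rate_min minimum call rate (default 0.90).
#' @param hwe_chi2_max maximum Hardy-Weinberg chi-square (default 600).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return list with `geno` (filtered [geno_matrix()]) and `report`
#'   (data.frame of class `qc_report`: one row per input marker with
#'   `call_rate`, `hwe_chi2`, `maf`, `pass`, `failed_rules`).
#' @export
qc_filter <- function(geno, call_rate_min = 0.90, hwe_chi2_max = 600,
                      maf_min = 0.01) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_chi2_max > 0, maf_min >= 0, maf_min < 0.5)
  d <- geno$dosage
  n <- nrow(d)
  call_rate <- colSums(!is.na(d)) / n
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  p <- ifelse(call_rate > 0, (2 * n2 + n1) / (2 * pmax(n0 + n1 + n2, 1)), NA)
  maf <- pmin(p, 1 - p)
  chi <- hwe_chisq(n0, n1, n2)
  chi[call_rate == 0] <- NA
  autosomal <- grepl("^[0-9]+$", geno$markers$chrom)
  rules <- cbind(call_rate = call_rate < call_rate_min,
                 hwe = !is.na(chi) & chi > hwe_chi2_max,
                 maf = !is.na(maf) & maf < maf_min,
                 non_autosomal = !autosomal)
  pass <- rowSums(rules, na.rm = TRUE) == 0
  failed <- apply(rules, 1, function(r) paste(colnames(rules)[which(r)], collapse = ","))
  report <- data.frame(marker_id = geno$markers$marker_id,
                       chrom = geno$markers$chrom, call_rate = call_rate,
                       hwe_chi2 = chi, maf = maf, pass = pass,
                       failed_rules = failed, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  if (!any(pass)) stop("no markers pass QC: nothing left to analyse")
  list(geno = subset_geno(geno, marker_ids = geno$markers$marker_id[pass]),
       report = report)
}
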