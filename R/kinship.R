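#' Relationship matrix container
#'
#' @param kind one of `"pedigree_A"`, `"genomic_G"`, `"dominance_D"`.
#' @param labels animal identifiers (unique), one per row/column.
#' @param values symmetric numeric matrix.
#' @param scale_c scale constant for genomic kinds
#'   (`2 * sum(p_j * (1 - p_j))` for G, `sum((2 p_j (1 - p_j))^2)` for D).
#' @param freq allele frequencies used (genomic kinds).
#' @return object of class `relmatrix`.
#' @export
relmatrix <- function(kind = c("pedigree_A", "genomic_G", "dominance_D"),
                      labels, values, scale_c = NA_real_, freq = NULL) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in relationship matrix")
  values <- as.matrix(values)
  if (nrow(values) != length(labels) || ncol(values) != length(labels)) {
    stop("matrix dimensions do not match labels")
  }
  if (max(abs(values - t(values))) > 1e-10) stop("matrix not symmetric")
  dimnames(values) <- list(labels, labels)
  structure(list(kind = kind, labels = labels, values = values,
                 scale_c = scale_c, freq = freq),
            class = "relmatrix")
}

#' @export
print.relmatrix <- function(x, ...) {
  cat(sprintf("relmatrix [%s]: %d animals, mean diagonal %.3f\n",
              x$kind, length(x$labels), mean(diag(x$values))))
  invisible(x)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Built from the Cholesky recursion `A = L L'` on the topologically sorted
#' pedigree (equivalent to the tabular method); founders are taken as
#' unrelated and non-inbred, and inbreeding accumulates through shared
#' ancestry, so the diagonal is `1 + F`.
#'
#' @param ped a [pedigree()].
#' @return A [relmatrix()] of kind `"pedigree_A"` over all pedigree members.
#' @export
build_nrm <- function(ped) {
  ldl <- ped_ldl(ped)
  n <- nrow(ped)
  ij <- lapply(seq_len(n), function(i) {
    r <- ldl$Lrows[[i]]
    cbind(i = i, j = as.integer(names(r)), x = as.numeric(r))
  })
  ij <- do.call(rbind, ij)
  L <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3], dims = c(n, n))
  A <- as.matrix(Matrix::tcrossprod(L))
  relmatrix("pedigree_A", ped$animal, A)
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding:
#' `A^-1 = (I - P)' D^-1 (I - P)` where `P` carries 0.5 on parent links and
#' `D` holds the Mendelian-sampling variances.
#'
#' @param ped a [pedigree()].
#' @return sparse symmetric Matrix with dimnames set to animal ids.
#' @export
nrm_inverse <- function(ped) {
  ldl <- ped_ldl(ped)
  n <- nrow(ped)
  ii <- rep(seq_len(n), 2)
  pp <- c(ldl$sire, ldl$dam)
  keep <- !is.na(pp)
  P <- Matrix::sparseMatrix(i = ii[keep], j = pp[keep], x = rep(0.5, sum(keep)),
                            dims = c(n, n))
  IP <- Matrix::Diagonal(n) - P
  Ainv <- Matrix::crossprod(IP, Matrix::Diagonal(x = 1 / ldl$d) %*% IP)
  Ainv <- Matrix::forceSymmetric(Ainv)
  dimnames(Ainv) <- list(ped$animal, ped$animal)
  Ainv
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / c` with `W` the column-centred dosage matrix
#' (`w_ij = x_ij - 2 p_j`) and `c = 2 * sum(p_j (1 - p_j))`. Monomorphic
#' markers (p of 0 or 1) are excluded with a message. Missing dosages must
#' be imputed first (see [mean_impute_dosage()]).
#'
#' @param geno a [geno_matrix()] or complete numeric dosage matrix with
#'   column names.
#' @param freq optional externally supplied alt-allele frequencies (named or
#'   in marker order); default uses observed frequencies.
#' @return A [relmatrix()] of kind `"genomic_G"`.
#' @export
build_grm <- function(geno, freq = NULL) {
  d <- grm_dosage(geno)
  p <- grm_freq(d, freq)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic: GRM scale constant is zero")
  if (any(!keep)) message("excluding ", sum(!keep), " monomorphic marker(s) from GRM")
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(d, 2, 2 * p)
  cc <- 2 * sum(p * (1 - p))
  relmatrix("genomic_G", rownames(d), tcrossprod(W) / cc, scale_c = cc, freq = p)
}

#' Dominance genomic relationship matrix
#'
#' Classical (GCTA-compatible) parameterisation of dominance deviations:
#' genotype 0 is coded `-2 p^2`, genotype 1 `2 p (1 - p)` and genotype 2
#' `-2 (1 - p)^2`; `D = H H' / sum((2 p_j (1 - p_j))^2)`.
#'
#' @inheritParams build_grm
#' @return A [relmatrix()] of kind `"dominance_D"`.
#' @export
build_drm <- function(geno, freq = NULL) {
  d <- grm_dosage(geno)
  p <- grm_freq(d, freq)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic: DRM scale constant is zero")
  if (any(!keep)) message("excluding ", sum(!keep), " monomorphic marker(s) from DRM")
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  H <- dominance_code(d, p)
  cc <- sum((2 * p * (1 - p))^2)
  relmatrix("dominance_D", rownames(d), tcrossprod(H) / cc, scale_c = cc, freq = p)
}

# Dominance coding per marker: 0 -> -2p^2, 1 -> 2p(1-p), 2 -> -2(1-p)^2.
# Non-integer (imputed) dosages are rounded to the nearest genotype class.
dominance_code <- function(d, p) {
  g <- round(d)
  H <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    codes <- c(-2 * p[j]^2, 2 * p[j] * (1 - p[j]), -2 * (1 - p[j])^2)
    H[, j] <- codes[g[, j] + 1]
  }
  H
}

grm_dosage <- function(geno) {
  d <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  storage.mode(d) <- "double"
  if (anyNA(d)) stop("missing dosages: impute first (mean_impute_dosage)")
  if (is.null(rownames(d))) rownames(d) <- seq_len(nrow(d))
  d
}

grm_freq <- function(d, freq) {
  if (is.null(freq)) return(colMeans(d) / 2)
  if (!is.null(names(freq)) && !is.null(colnames(d))) {
    miss <- setdiff(colnames(d), names(freq))
    if (length(miss)) stop("no frequency supplied for marker(s): ",
                           paste(miss[1:min(3, length(miss))], collapse = ", "))
    freq <- freq[colnames(d)]
  }
  if (length(freq) != ncol(d)) stop("frequency vector length mismatch")
  as.numeric(freq)
}

#' Add a diagonal ridge to a relationship matrix
#'
#' A small ridge (default 1e-6) is added to the diagonal before inversion in
#' model fitting to guarantee positive definiteness; callers that need the
#' inverse should always go through this.
#'
#' @param K a [relmatrix()] or plain symmetric matrix.
#' @param ridge ridge magnitude.
#' @return matrix with ridge added.
#' @export
add_ridge <- function(K, ridge = 1e-6) {
  V <- if (inherits(K, "relmatrix")) K$values else as.matrix(K)
  V + diag(ridge, nrow(V))
}

#' Write / read a relationship matrix as labelled lower-triangle text
#'
#' GCTA-GRM-like plain-text exchange format: a `.grm` file with columns
#' `i j value` (1-based indices, lower triangle including the diagonal) and
#' a `.id` file with one animal id per line.
#'
#' @param rm_obj a [relmatrix()].
#' @param prefix output path prefix (writes `<prefix>.grm` and `<prefix>.id`).
#' @return `prefix`, invisibly.
#' @export
write_relmatrix <- function(rm_obj, prefix) {
  idx <- which(lower.tri(rm_obj$values, diag = TRUE), arr.ind = TRUE)
  utils::write.table(
    data.frame(i = idx[, 1], j = idx[, 2],
               value = rm_obj$values[idx]),
    paste0(prefix, ".grm"), row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(rm_obj$labels, paste0(prefix, ".id"))
  invisible(prefix)
}

#' @rdname write_relmatrix
#' @param kind matrix kind for the reconstructed object.
#' @export
read_relmatrix <- function(prefix, kind = "genomic_G") {
  ids <- readLines(paste0(prefix, ".id"))
  tri <- utils::read.table(paste0(prefix, ".grm"), header = FALSE,
                           col.names = c("i", "j", "value"))
  n <- length(ids)
  V <- matrix(0, n, n)
  V[cbind(tri$i, tri$j)] <- tri$value
  V[cbind(tri$j, tri$i)] <- tri$value
  relmatrix(kind, ids, V)
}
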