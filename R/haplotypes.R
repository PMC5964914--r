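#' Build multi-marker haplotype alleles from phased genotypes
#'
#' Reads each animal's two haplotype alleles (bit-strings over the chosen
#' markers) off the phased matrices and tabulates per-allele population
#' frequencies and per-animal copy counts (0/1/2 per allele, summing to 2).
#'
#' @param geno a phased [geno_matrix()].
#' @param marker_ids markers forming the haplotype (typically the top 3, 5
#'   or 10 scan hits, or all markers within a window; see
#'   [select_haplotype_markers()]).
#' @param animals optional animal subset.
#' @return object of class `hap_set`: `alleles` (bit-strings), `freq`,
#'   `copies` (animals x alleles count matrix), `marker_ids`, `pooled`
#'   (logical per allele, all `FALSE` here).
#' @export
build_haplotypes <- function(geno, marker_ids, animals = NULL) {
  if (!geno$phased) {
    stop("haplotypes require phased genotypes; supply phased data ",
         "(the simulator always emits phase)")
  }
  miss <- setdiff(marker_ids, geno$markers$marker_id)
  if (length(miss)) stop("unknown markers: ", paste(miss, collapse = ", "))
  rows <- if (is.null(animals)) geno$animal_ids else as.character(animals)
  h1 <- geno$hap1[rows, marker_ids, drop = FALSE]
  h2 <- geno$hap2[rows, marker_ids, drop = FALSE]
  a1 <- apply(h1, 1, paste, collapse = "")
  a2 <- apply(h2, 1, paste, collapse = "")
  alleles <- sort(unique(c(a1, a2)))
  copies <- matrix(0L, length(rows), length(alleles),
                   dimnames = list(rows, alleles))
  copies[cbind(seq_along(a1), match(a1, alleles))] <-
    copies[cbind(seq_along(a1), match(a1, alleles))] + 1L
  copies[cbind(seq_along(a2), match(a2, alleles))] <-
    copies[cbind(seq_along(a2), match(a2, alleles))] + 1L
  freq <- colSums(copies) / (2 * length(rows))
  structure(list(alleles = alleles, freq = freq, copies = copies,
                 marker_ids = marker_ids,
                 pooled = stats::setNames(rep(FALSE, length(alleles)), alleles)),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("hap_set: %d markers, %d allele classes (%s)\n",
              length(x$marker_ids), length(x$alleles),
              if (any(x$pooled)) "rare pooled" else "unpooled"))
  invisible(x)
}

#' Pool rare haplotype alleles into one residual class
#'
#' All alleles with copy frequency below `freq_threshold` are merged into a
#' single residual class (`"residual"`); copy counts are re-aggregated.
#' Idempotent: pooling an already pooled set changes nothing.
#'
#' @param set a [build_haplotypes()] set.
#' @param freq_threshold frequency below which an allele is pooled
#'   (default 0.02).
#' @return A pooled `hap_set`.
#' @export
pool_rare_haplotypes <- function(set, freq_threshold = 0.02) {
  stopifnot(freq_threshold > 0, freq_threshold < 0.5)
  if (is.null(names(set$freq))) names(set$freq) <- set$alleles
  rare <- set$freq < freq_threshold & names(set$freq) != "residual"
  if (all(set$freq[names(set$freq) != "residual"] < freq_threshold)) {
    stop("all haplotype alleles are rare: nothing left to contrast")
  }
  if (!any(rare)) return(set)
  keep <- !rare
  copies <- cbind(set$copies[, keep, drop = FALSE],
                  residual = rowSums(set$copies[, rare, drop = FALSE]))
  if ("residual" %in% colnames(set$copies)[keep]) {
    # merge into the existing residual column
    res_cols <- colnames(copies) == "residual"
    res <- rowSums(copies[, res_cols, drop = FALSE])
    copies <- cbind(copies[, !res_cols, drop = FALSE], residual = res)
  }
  freq <- colSums(copies) / (2 * nrow(copies))
  pooled <- stats::setNames(colnames(copies) == "residual", colnames(copies))
  structure(list(alleles = colnames(copies), freq = freq, copies = copies,
                 marker_ids = set$marker_ids, pooled = pooled),
            class = "hap_set")
}

#' Random-effect design from a haplotype set
#'
#' Copy-count design matrix (animals x haplotype classes) for fitting the
#' haplotype effects as one random term with a shared variance component.
#' Every row sums to 2.
#'
#' @param set a (pooled) `hap_set`.
#' @param label term label.
#' @return An [mm_random()] term.
#' @export
haplotype_design <- function(set, label = "haplotype") {
  if (ncol(set$copies) < 2) {
    stop("single haplotype class: design confounded with the intercept")
  }
  mm_random(label, set$copies)
}

#' Write a haplotype set as TSV
#'
#' One row per allele class: bit-string, copy frequency, pooled flag.
#'
#' @param set a `hap_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hap_set <- function(set, path) {
  utils::write.table(
    data.frame(allele = set$alleles,
               frequency = as.numeric(set$freq[set$alleles]),
               pooled = as.logical(set$pooled[set$alleles])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Choose markers for haplotype construction
#'
#' Two selectors: the top-k most significant scan hits (`k`), or all
#' markers within a +/- `window_kb` window of a position.
#'
#' @param scan a [gwas_scan()] result (needed for `k`).
#' @param geno a [geno_matrix()] (needed for `window_kb`).
#' @param k number of top markers.
#' @param window_kb half-window in kb around `center_pos`.
#' @param center_pos window centre (default the causal insertion position).
#' @return character vector of marker ids in map order.
#' @export
select_haplotype_markers <- function(scan = NULL, geno = NULL, k = NULL,
                                     window_kb = NULL,
                                     center_pos = 29456047) {
  if (!is.null(k)) {
    if (is.null(scan)) stop("top-k selection needs a scan")
    ids <- top_markers(scan, k, causal_pos = center_pos)$marker_id
    ord <- match(ids, scan$marker_id)
    return(ids[order(scan$pos[ord])])
  }
  if (!is.null(window_kb)) {
    if (is.null(geno)) stop("window selection needs genotypes")
    sel <- abs(geno$markers$pos - center_pos) <= window_kb * 1000
    if (!any(sel)) stop("no markers within the window")
    return(geno$markers$marker_id[sel])
  }
  stop("supply k or window_kb")
}
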