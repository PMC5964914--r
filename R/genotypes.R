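#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes of a set of animals: allele dosages
#' (count of the alternate allele as written in the source, 0/1/2, `NA` for
#' missing) plus, when the source is phased, the two underlying binary
#' haplotype matrices. Coordinates are 1-based base pairs, and positions must
#' be strictly increasing within each chromosome.
#'
#' @param animal_ids character vector of animal identifiers (unique).
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `ref`, `alt`; one row per marker, `marker_id` unique, `pos` strictly
#'   increasing within `chrom`.
#' @param dosage integer matrix (animals x markers) with entries 0, 1, 2 or
#'   `NA`.
#' @param hap1,hap2 optional binary matrices of the same shape whose sum
#'   equals `dosage` at every non-missing cell; supplying both marks the
#'   object as phased.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(animal_ids, markers, dosage, hap1 = NULL, hap2 = NULL) {
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids)) stop("duplicate animal ids")
  req <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(markers))) {
    stop("markers must have columns: ", paste(req, collapse = ", "))
  }
  markers <- as.data.frame(markers)[, req]
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (anyDuplicated(markers$marker_id)) stop("duplicate marker ids")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(animal_ids) || ncol(dosage) != nrow(markers)) {
    stop("dosage dimensions do not match animals x markers")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(animal_ids, markers$marker_id)
  phased <- !is.null(hap1) && !is.null(hap2)
  if (phased) {
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    if (!identical(dim(hap1), dim(dosage)) || !identical(dim(hap2), dim(dosage))) {
      stop("haplotype matrices must match dosage dimensions")
    }
    s <- hap1 + hap2
    ok <- is.na(dosage) | (s == dosage)
    if (!all(ok, na.rm = TRUE)) stop("hap1 + hap2 != dosage at some cells")
    dimnames(hap1) <- dimnames(hap2) <- dimnames(dosage)
  } else {
    hap1 <- hap2 <- NULL
  }
  structure(list(animal_ids = animal_ids, markers = markers, dosage = dosage,
                 phased = phased, hap1 = hap1, hap2 = hap2),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d markers (%s), chrom: %s\n",
              length(x$animal_ids), nrow(x$markers),
              if (x$phased) "phased" else "unphased",
              paste(unique(x$markers$chrom), collapse = ",")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset markers of a genotype matrix
#'
#' @param geno a `geno_matrix`.
#' @param marker_ids marker identifiers to keep, or `NULL`.
#' @param chrom optional chromosome label; with `start`/`end` (1-based,
#'   closed interval) restricts to a region.
#' @param start,end optional closed interval bounds in bp.
#' @param animals optional animal identifiers to keep.
#' @return A `geno_matrix` restricted to the selection (marker order of the
#'   original is preserved for region/chromosome selections; `marker_ids`
#'   order is preserved only if consistent with position order).
#' @export
subset_geno <- function(geno, marker_ids = NULL, chrom = NULL,
                        start = NULL, end = NULL, animals = NULL) {
  keep <- rep(TRUE, nrow(geno$markers))
  if (!is.null(marker_ids)) {
    miss <- setdiff(marker_ids, geno$markers$marker_id)
    if (length(miss)) stop("unknown markers: ", paste(miss, collapse = ", "))
    keep <- keep & geno$markers$marker_id %in% marker_ids
  }
  if (!is.null(chrom)) keep <- keep & geno$markers$chrom %in% as.character(chrom)
  if (!is.null(start)) keep <- keep & geno$markers$pos >= start
  if (!is.null(end)) keep <- keep & geno$markers$pos <= end
  rows <- seq_along(geno$animal_ids)
  if (!is.null(animals)) {
    rows <- match(as.character(animals), geno$animal_ids)
    if (anyNA(rows)) stop("unknown animals requested")
  }
  geno_matrix(geno$animal_ids[rows], geno$markers[keep, , drop = FALSE],
              geno$dosage[rows, keep, drop = FALSE],
              if (geno$phased) geno$hap1[rows, keep, drop = FALSE],
              if (geno$phased) geno$hap2[rows, keep, drop = FALSE])
}

#' Read genotypes from VCF or PLINK-style text
#'
#' VCF parsing is delegated to \pkg{vcfR}; phase is taken from the `|`
#' separator in the GT field (the object is marked phased only when every
#' non-missing genotype is phased). Only biallelic SNP records are accepted.
#' The PLINK reader expects a `.ped`/`.map` text pair (pass the `.ped` path);
#' `.ped` alleles are recoded against the first-listed allele per marker.
#'
#' @param path path to a `.vcf` (optionally gzipped) or `.ped` file.
#' @param format `"vcf"` or `"plink_text"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_plink(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic record(s): ",
         paste(stats::na.omit(fix[multi, "ID"])[1:min(3, sum(multi))], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(fix[, "ID"], names(gt)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  core <- gsub("[|/]", "", gt)                 # e.g. "01", "11", ".."
  bad <- !is.na(core) & !core %in% c("00", "01", "10", "11")
  if (any(bad)) stop("unsupported GT value(s): ", paste(unique(gt[bad])[1:3], collapse = ", "))
  a1 <- ifelse(is.na(core), NA_integer_, as.integer(substr(core, 1, 1)))
  a2 <- ifelse(is.na(core), NA_integer_, as.integer(substr(core, 2, 2)))
  phased_all <- all(grepl("\\|", gt[!is.na(gt)]))
  dim(a1) <- dim(a2) <- dim(gt)
  markers <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = alt,
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  a1 <- t(a1[ord, , drop = FALSE]); a2 <- t(a2[ord, , drop = FALSE])
  geno_matrix(colnames(gt), markers, a1 + a2,
              if (phased_all) a1, if (phased_all) a2)
}

read_genotypes_plink <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path) || !file.exists(map_path)) {
    stop("matching .map file not found for ", ped_path)
  }
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map: expected 4 columns")
  names(map)[1:4] <- c("chrom", "marker_id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop("malformed .ped: expected ", 6 + 2 * m, " columns, found ", ncol(ped))
  }
  al1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  al2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  dosage <- matrix(NA_integer_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    # .ped carries no ref/alt orientation: orient alphabetically (dosage
    # orientation never changes downstream results)
    lv <- sort(setdiff(unique(obs), "0"))
    if (length(lv) > 2) stop("multi-allelic marker in .ped: ", map$marker_id[j])
    ref[j] <- lv[1]
    alt[j] <- if (length(lv) == 2) lv[2] else "."
    d <- (al1[, j] == alt[j]) + (al2[, j] == alt[j])
    d[al1[, j] == "0" | al2[, j] == "0"] <- NA
    dosage[, j] <- as.integer(d)
  }
  markers <- data.frame(marker_id = map$marker_id, chrom = as.character(map$chrom),
                        pos = as.integer(map$pos), ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  geno_matrix(as.character(ped[, 2]), markers[ord, , drop = FALSE],
              dosage[, ord, drop = FALSE])
}

#' Write genotypes to VCF or PLINK-style text
#'
#' Writes plain (uncompressed) text. Phase is encoded with `|` separators
#' when the object is phased; unphased genotypes use `/` with heterozygotes
#' written as `0/1`.
#'
#' @param geno a [geno_matrix()].
#' @param path output path (`.vcf`, or `.ped`; the `.map` is written beside it).
#' @param format `"vcf"` or `"plink_text"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (format == "vcf") write_genotypes_vcf(geno, path) else write_genotypes_plink(geno, path)
  invisible(path)
}

write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$animal_ids), collapse = "\t")), con)
  sep <- if (geno$phased) "|" else "/"
  for (j in seq_len(nrow(geno$markers))) {
    if (geno$phased) {
      g <- paste(geno$hap1[, j], geno$hap2[, j], sep = sep)
    } else {
      g <- c("0/0", "0/1", "1/1")[geno$dosage[, j] + 1L]
    }
    g[is.na(geno$dosage[, j])] <- paste(".", ".", sep = sep)
    m <- geno$markers[j, ]
    writeLines(paste(c(m$chrom, m$pos, m$marker_id, m$ref, m$alt, ".", "PASS",
                       ".", "GT", g), collapse = "\t"), con)
  }
}

write_genotypes_plink <- function(geno, path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  utils::write.table(
    data.frame(geno$markers$chrom, geno$markers$marker_id, 0, geno$markers$pos),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- length(geno$animal_ids)
  al <- matrix("0", n, 2 * nrow(geno$markers))
  for (j in seq_len(nrow(geno$markers))) {
    d <- geno$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d == 2, geno$markers$alt[j], geno$markers$ref[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d >= 1, geno$markers$alt[j], geno$markers$ref[j]))
    al[, 2 * j - 1] <- a1; al[, 2 * j] <- a2
  }
  out <- cbind("FAM", geno$animal_ids, "0", "0", "0", "-9", al)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
}

#' Mean-impute missing dosages
#'
#' Replaces missing dosages by the per-marker mean dosage (a real number, so
#' the result is a plain numeric matrix, not a `geno_matrix`). Model-fitting
#' code requires complete data; imputation is an explicit, logged step.
#'
#' @param geno a [geno_matrix()].
#' @param quiet suppress the imputation message.
#' @return numeric matrix of dosages with no missing values.
#' @export
mean_impute_dosage <- function(geno, quiet = FALSE) {
  d <- geno$dosage
  storage.mode(d) <- "double"
  nmiss <- sum(is.na(d))
  if (nmiss > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
    if (!quiet) message("mean-imputed ", nmiss, " missing dosage cells")
  }
  d
}
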