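#' Mode-of-inheritance model specification
#'
#' The five single-locus models for a binary horn trait, all of the form
#' `y = 1 mu + sex + Z u + (marker terms) + e` with the marker effects
#' fitted as random:
#' \describe{
#'   \item{1}{additive only: one allele-substitution term (dosage 0/1/2).}
#'   \item{2}{additive + dominance: adds a heterozygosity-indicator term.}
#'   \item{3}{sex-dependent additive: one additive term per sex.}
#'   \item{4}{additive + sex-dependent dominance.}
#'   \item{5}{sex-dependent additive + sex-dependent dominance.}
#' }
#' Each sex-specific term carries its own variance component. Sex enters
#' as a fixed main effect in every model so that the marker terms are not
#' confounded with the sex difference. The polygenic term uses either the
#' pedigree relationship matrix or a genomic one. Incomplete penetrance is
#' deliberately not modelled.
#'
#' @param model_id 1-5.
#' @param trait `"pnp"` or `"hnh"`.
#' @param marker marker id.
#' @param polygenic `"pedigree_A"`, `"genomic_G"` or `"none"`.
#' @return object of class `moi_spec`.
#' @export
moi_spec <- function(model_id, trait = c("pnp", "hnh"), marker,
                     polygenic = c("pedigree_A", "genomic_G", "none")) {
  stopifnot(model_id %in% 1:5)
  structure(list(model_id = as.integer(model_id), trait = match.arg(trait),
                 marker = marker, polygenic = match.arg(polygenic)),
            class = "moi_spec")
}

# Marker design columns for a mode-of-inheritance model: additive dosage
# Lambda (0/1/2), heterozygosity indicator Delta (0/1), split by sex for the
# sex-interaction models. Returns a list of mm_random terms.
moi_marker_terms <- function(model_id, dosage, sexf) {
  lam <- as.numeric(dosage)
  del <- as.numeric(dosage == 1)
  fm <- cbind(F = as.numeric(sexf), M = as.numeric(!sexf))
  per_sex <- function(v, what) {
    cols <- fm * v
    if (any(colSums(cols != 0) == 0)) {
      empty <- colnames(fm)[colSums(cols != 0) == 0]
      stop("no ", what, " observations for sex ", paste(empty, collapse = ","),
           ": per-sex term cannot be fitted")
    }
    list(mm_random(paste0(what, "_F"), cols[, 1, drop = FALSE]),
         mm_random(paste0(what, "_M"), cols[, 2, drop = FALSE]))
  }
  switch(model_id,
    list(mm_random("alpha", cbind(lam))),
    list(mm_random("alpha", cbind(lam)), mm_random("delta", cbind(del))),
    per_sex(lam, "alpha"),
    c(list(mm_random("alpha", cbind(lam))), per_sex(del, "delta")),
    c(per_sex(lam, "alpha"), per_sex(del, "delta")))
}

#' Build the mixed-model design for a mode-of-inheritance model
#'
#' @param spec a [moi_spec()].
#' @param study a `synthetic_study` or a list with elements `geno`, `ped`,
#'   `phe`.
#' @param animals optional subset of phenotyped animals to use (e.g. a
#'   training fold); default all phenotyped animals.
#' @param G optional precomputed [relmatrix()] when
#'   `polygenic = "genomic_G"`.
#' @param Ainv optional precomputed sparse pedigree precision from
#'   [nrm_inverse()] (recomputed otherwise).
#' @param ridge ridge for covariance inversion.
#' @return An [mm_spec()]; the polygenic term (if any) is labelled
#'   `"polygenic"` and spans all pedigree members (pedigree kind) or the
#'   animals covered by `G`.
#' @export
build_moi_design <- function(spec, study, animals = NULL, G = NULL,
                             Ainv = NULL, ridge = 1e-6) {
  phe <- study$phe
  if (!is.null(animals)) phe <- phe[phe$animal %in% animals, , drop = FALSE]
  ids <- phe$animal
  y <- phe[[spec$trait]]
  if (!spec$marker %in% study$geno$markers$marker_id) {
    stop("marker not found: ", spec$marker)
  }
  dos <- study$geno$dosage[ids, spec$marker]
  if (anyNA(dos)) stop("marker genotypes incomplete for phenotyped animals")
  sex <- study$ped$sex[match(ids, study$ped$animal)]
  sexf <- sex == "female"
  X <- cbind("(Intercept)" = 1, sexF = as.numeric(sexf))
  terms <- moi_marker_terms(spec$model_id, dos, sexf)
  if (spec$polygenic == "pedigree_A") {
    if (is.null(Ainv)) Ainv <- nrm_inverse(study$ped)
    Zp <- Matrix::sparseMatrix(i = seq_along(ids),
                               j = match(ids, study$ped$animal),
                               x = 1, dims = c(length(ids), nrow(study$ped)))
    terms <- c(list(mm_random("polygenic", Zp, Kinv = Ainv)), terms)
  } else if (spec$polygenic == "genomic_G") {
    if (is.null(G)) G <- build_grm(mean_impute_dosage(study$geno, quiet = TRUE))
    gl <- G$labels
    Zp <- Matrix::sparseMatrix(i = seq_along(ids), j = match(ids, gl),
                               x = 1, dims = c(length(ids), length(gl)))
    terms <- c(list(mm_random("polygenic", Zp, K = G, ridge = ridge)), terms)
  }
  mm_spec(y, X, terms)
}

#' Fit a mode-of-inheritance model
#'
#' Delegates to [fit_variance_components()] with ML (so that AIC values are
#' comparable across the five models) and records the model id.
#'
#' @inheritParams build_moi_design
#' @return An `mm_fit` with extra fields `model_id`, `trait`, `marker`
#'   (class `moi_fit`).
#' @export
fit_moi <- function(spec, study, animals = NULL, G = NULL, Ainv = NULL) {
  design <- build_moi_design(spec, study, animals = animals, G = G,
                             Ainv = Ainv)
  fit <- fit_variance_components(design, method = "ML")
  fit$model_id <- spec$model_id
  fit$trait <- spec$trait
  fit$marker <- spec$marker
  fit$moi_spec <- spec
  class(fit) <- c("moi_fit", class(fit))
  fit
}

#' Select the best mode of inheritance by AIC
#'
#' Fits all five models and ranks them by AIC (ML), reporting the
#' improvement over the additive null (model 1). The lowest AIC wins; ties
#' go to the lower model id. Failed fits are annotated and excluded from
#' the ranking.
#'
#' @param study a `synthetic_study` (or compatible list).
#' @param trait `"pnp"` or `"hnh"`.
#' @param marker marker id.
#' @param polygenic polygenic covariance kind (see [moi_spec()]).
#' @param G optional precomputed [relmatrix()].
#' @return list with `table` (model, AIC, dAIC, n_parameters, error rows in
#'   model order), `best` (the winning [moi_spec()]) and `fits`.
#' @export
select_mode_of_inheritance <- function(study, trait, marker,
                                       polygenic = "pedigree_A", G = NULL) {
  fits <- vector("list", 5)
  errors <- rep(NA_character_, 5)
  Ainv <- if (polygenic == "pedigree_A") nrm_inverse(study$ped)
  for (mid in 1:5) {
    fits[[mid]] <- tryCatch(
      fit_moi(moi_spec(mid, trait, marker, polygenic), study, G = G,
              Ainv = Ainv),
      error = function(e) {
        errors[mid] <<- conditionMessage(e)
        NULL
      })
  }
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$AIC, 0)
  npar <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n_parameters, 0)
  tab <- data.frame(model = 1:5, AIC = aic, dAIC = aic[1] - aic,
                    n_parameters = npar, error = errors,
                    stringsAsFactors = FALSE)
  ok <- which(!is.na(aic))
  if (!length(ok)) stop("all five model fits failed")
  best_id <- ok[which.min(aic[ok])]   # which.min takes the first = lowest id on ties
  list(table = tab, best = moi_spec(best_id, trait, marker, polygenic),
       fits = fits)
}

#' Degree of dominance from genotype-class means
#'
#' From the three genotype-class means of a binary trait: additive scale
#' `a = |m2 - m0| / 2` (orientation chosen so the allele that lowers the
#' trait is counted, making `a >= 0`), dominance deviation
#' `d = m1 - (m0 + m2) / 2`, and degree `d / a` (|d/a| of 1 is complete
#' dominance, 0 pure additivity).
#'
#' @param m0,m1,m2 genotype-class means.
#' @return list `a`, `d`, `degree`, `flipped` (whether genotype labels were
#'   swapped to fix orientation).
#' @export
dominance_from_means <- function(m0, m1, m2) {
  flipped <- m2 > m0
  if (flipped) { tmp <- m0; m0 <- m2; m2 <- tmp }
  a <- (m0 - m2) / 2
  d <- m1 - (m0 + m2) / 2
  list(a = a, d = d, degree = if (a > 0) d / a else NA_real_,
       flipped = flipped)
}

#' Degree of dominance per sex at a marker
#'
#' Genotype-class means of the binary trait per sex, with the dominance
#' summary of [dominance_from_means()]. A sex with an empty genotype class
#' is reported as unavailable.
#'
#' @param genotype dosage vector (0/1/2) or marker id with `geno`.
#' @param trait binary vector.
#' @param sex sex labels.
#' @param geno optional [geno_matrix()].
#' @return data.frame of class `dominance_summary`: per sex `m0`, `m1`,
#'   `m2`, `a`, `d`, `degree`, `available`.
#' @export
degree_of_dominance <- function(genotype, trait, sex, geno = NULL) {
  if (is.character(genotype) && length(genotype) == 1) {
    if (is.null(geno)) stop("supply geno when genotype is a marker id")
    genotype <- geno$dosage[, genotype]
  }
  trait <- as.numeric(trait)
  sexes <- sort(unique(as.character(sex)))
  rows <- lapply(sexes, function(s) {
    m <- vapply(0:2, function(g) {
      sel <- sex == s & genotype == g
      if (any(sel)) mean(trait[sel]) else NA_real_
    }, 0)
    if (anyNA(m)) {
      data.frame(sex = s, m0 = m[1], m1 = m[2], m2 = m[3], a = NA_real_,
                 d = NA_real_, degree = NA_real_, available = FALSE)
    } else {
      dd <- dominance_from_means(m[1], m[2], m[3])
      data.frame(sex = s, m0 = m[1], m1 = m[2], m2 = m[3], a = dd$a,
                 d = dd$d, degree = dd$degree, available = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dominance_summary", "data.frame")
  out
}
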