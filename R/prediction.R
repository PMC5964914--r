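#' Per-sex Pearson prediction accuracy
#'
#' Pearson correlation between predicted and observed phenotype, overall
#' and per sex. Cells with fewer than 3 pairs or zero variance in either
#' vector are reported as `NA`.
#'
#' @param predicted,observed numeric vectors.
#' @param sex optional sex labels for per-sex rows.
#' @return data.frame with `group`, `n`, `r`.
#' @export
accuracy <- function(predicted, observed, sex = NULL) {
  stopifnot(length(predicted) == length(observed))
  one <- function(idx, label) {
    p <- predicted[idx]; o <- observed[idx]
    r <- if (length(p) < 3 || stats::sd(p) == 0 || stats::sd(o) == 0) {
      NA_real_
    } else {
      stats::cor(p, o)
    }
    data.frame(group = label, n = length(p), r = r, stringsAsFactors = FALSE)
  }
  out <- one(seq_along(predicted), "pooled")
  if (!is.null(sex)) {
    for (s in sort(unique(as.character(sex)))) {
      out <- rbind(out, one(which(sex == s), s))
    }
  }
  out
}

#' Predict a binary trait from a single-marker or haplotype model
#'
#' Fits the chosen model on the training animals only (phenotypes of the
#' validation animals never enter the fit) and predicts the validation
#' animals as intercept + sex effect + marker/haplotype solutions applied
#' to their genotypes + (when a relationship-based polygenic term is in the
#' model) the BLUP of their polygenic value through its covariance with the
#' training animals. The causal insertion is predicted the same way by
#' passing its marker id.
#'
#' @param study a `synthetic_study` (or list with `geno`, `ped`, `phe`).
#' @param model a [moi_spec()] (single marker, mode of inheritance chosen
#'   by [select_mode_of_inheritance()]) or a `hap_set` built over at least
#'   the training and validation animals.
#' @param train,test character vectors of animal ids (disjoint).
#' @param trait trait name when `model` is a `hap_set` (`"pnp"`/`"hnh"`).
#' @param polygenic polygenic covariance for a `hap_set` model
#'   (`"none"`, `"pedigree_A"`, `"genomic_G"`); a [moi_spec()] carries its
#'   own.
#' @param G optional precomputed [relmatrix()] for genomic polygenic terms.
#' @param method variance-component method.
#' @param genotype_error optional probability with which each validation
#'   animal's marker genotype is replaced by a random draw from the
#'   training genotype distribution (emulates imputation error for the
#'   insertion-based predictor); 0 disables.
#' @param seed seed used when `genotype_error > 0`.
#' @return object of class `prediction_result`: data.frame `predictions`
#'   (`animal`, `sex`, `observed`, `predicted` and the `fixed`, `marker`,
#'   `polygenic` components), plus `fit` and `model_tag`.
#' @export
predict_marker_model <- function(study, model, train, test,
                                 trait = NULL, polygenic = "none", G = NULL,
                                 method = "REML", genotype_error = 0,
                                 seed = 1) {
  if (length(intersect(train, test))) stop("train and test overlap")
  phe <- study$phe
  if (!all(train %in% phe$animal)) stop("training animals without phenotypes")
  ped_ids <- study$ped$animal
  sex_all <- stats::setNames(study$ped$sex, ped_ids)
  is_moi <- inherits(model, "moi_spec")
  trait <- if (is_moi) model$trait else match.arg(trait, c("pnp", "hnh"))
  poly_kind <- if (is_moi) model$polygenic else polygenic
  ytr <- phe[[trait]][match(train, phe$animal)]
  sexf_tr <- sex_all[train] == "female"
  X <- cbind("(Intercept)" = 1, sexF = as.numeric(sexf_tr))

  if (is_moi) {
    dos_all <- study$geno$dosage[, model$marker]
    if (genotype_error > 0) {
      set.seed(seed)
      hit <- stats::runif(length(test)) < genotype_error
      if (any(hit)) {
        dos_all[test[hit]] <- sample(dos_all[train], sum(hit), replace = TRUE)
      }
    }
    tag <- paste0("single_snp_model", model$model_id)
  } else {
    if (!all(c(train, test) %in% rownames(model$copies))) {
      stop("hap_set does not cover all train/test animals")
    }
    if (ncol(model$copies) < 2) {
      stop("single haplotype class: design confounded with the intercept")
    }
    tag <- paste0("hap", length(model$marker_ids))
  }

  if (poly_kind == "pedigree_A") {
    Ainv <- nrm_inverse(study$ped)
    Zp <- Matrix::sparseMatrix(i = seq_along(train),
                               j = match(train, ped_ids),
                               x = 1, dims = c(length(train), length(ped_ids)))
    poly_term <- mm_random("polygenic", Zp, Kinv = Ainv)
    poly_labels <- ped_ids
  } else if (poly_kind == "genomic_G") {
    if (is.null(G)) G <- build_grm(mean_impute_dosage(study$geno, quiet = TRUE))
    if (!all(c(train, test) %in% G$labels)) {
      stop("validation animal absent from the genomic relationship matrix")
    }
    Zp <- Matrix::sparseMatrix(i = seq_along(train),
                               j = match(train, G$labels),
                               x = 1, dims = c(length(train), length(G$labels)))
    poly_term <- mm_random("polygenic", Zp, K = G)
    poly_labels <- G$labels
  } else {
    poly_term <- NULL
  }
  train_terms <- if (is_moi) {
    moi_marker_terms(model$model_id, dos_all[train], sexf_tr)
  } else {
    list(mm_random("haplotype", model$copies[train, , drop = FALSE]))
  }
  spec_tr <- mm_spec(ytr, X, c(if (!is.null(poly_term)) list(poly_term),
                               train_terms))
  fit <- fit_variance_components(spec_tr, method = method)

  # validation predictions
  sexf_te <- sex_all[test] == "female"
  fixed <- fit$b["(Intercept)"] + fit$b["sexF"] * as.numeric(sexf_te)
  if (is_moi) {
    te_terms <- moi_marker_terms_design(model$model_id, dos_all[test], sexf_te)
    mk <- numeric(length(test))
    for (lab in names(te_terms)) mk <- mk + te_terms[[lab]] * fit$u[[lab]]
  } else {
    mk <- as.numeric(model$copies[test, , drop = FALSE] %*% fit$u[["haplotype"]])
  }
  pg <- if (!is.null(poly_term)) {
    fit$u[["polygenic"]][match(test, poly_labels)]
  } else {
    rep(0, length(test))
  }
  obs <- phe[[trait]][match(test, phe$animal)]
  pred <- data.frame(animal = test, sex = unname(sex_all[test]),
                     observed = obs, predicted = fixed + mk + pg,
                     fixed = fixed, marker = mk, polygenic = pg,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(predictions = pred, fit = fit,
                 model_tag = paste0(tag, "_poly_", poly_kind)),
            class = "prediction_result")
}

# Test-design columns for the marker terms of a mode-of-inheritance model,
# as a named list of numeric vectors (one per random term label).
moi_marker_terms_design <- function(model_id, dosage, sexf) {
  lam <- as.numeric(dosage)
  del <- as.numeric(dosage == 1)
  f <- as.numeric(sexf); m <- as.numeric(!sexf)
  switch(model_id,
    list(alpha = lam),
    list(alpha = lam, delta = del),
    list(alpha_F = lam * f, alpha_M = lam * m),
    list(alpha = lam, delta_F = del * f, delta_M = del * m),
    list(alpha_F = lam * f, alpha_M = lam * m,
         delta_F = del * f, delta_M = del * m))
}

#' Polygenic-only (BLUP) prediction
#'
#' Fits `y = mu + sex + u + e` on the training animals with a pedigree or
#' genomic covariance and predicts validation animals purely from their
#' relationship with the training set — the family-information baseline
#' against which marker models are contrasted in the family-validation
#' designs.
#'
#' @param study a `synthetic_study` (or compatible list).
#' @param trait `"pnp"` or `"hnh"`.
#' @param train,test animal id vectors (disjoint).
#' @param polygenic `"pedigree_A"` or `"genomic_G"`.
#' @param G optional precomputed [relmatrix()].
#' @param method variance-component method.
#' @return A `prediction_result` with components `fixed` and `polygenic`.
#' @export
predict_polygenic <- function(study, trait, train, test,
                              polygenic = c("pedigree_A", "genomic_G"),
                              G = NULL, method = "REML") {
  polygenic <- match.arg(polygenic)
  if (length(intersect(train, test))) stop("train and test overlap")
  phe <- study$phe
  ytr <- phe[[trait]][match(train, phe$animal)]
  sex_all <- stats::setNames(study$ped$sex, study$ped$animal)
  sexf_tr <- sex_all[train] == "female"
  X <- cbind("(Intercept)" = 1, sexF = as.numeric(sexf_tr))
  if (polygenic == "pedigree_A") {
    labels <- study$ped$animal
    Zp <- Matrix::sparseMatrix(i = seq_along(train), j = match(train, labels),
                               x = 1, dims = c(length(train), length(labels)))
    term <- mm_random("polygenic", Zp, Kinv = nrm_inverse(study$ped))
  } else {
    if (is.null(G)) G <- build_grm(mean_impute_dosage(study$geno, quiet = TRUE))
    labels <- G$labels
    if (!all(c(train, test) %in% labels)) {
      stop("validation animal absent from the genomic relationship matrix")
    }
    Zp <- Matrix::sparseMatrix(i = seq_along(train), j = match(train, labels),
                               x = 1, dims = c(length(train), length(labels)))
    term <- mm_random("polygenic", Zp, K = G)
  }
  fit <- fit_variance_components(mm_spec(ytr, X, list(term)), method = method)
  sexf_te <- sex_all[test] == "female"
  fixed <- fit$b["(Intercept)"] + fit$b["sexF"] * as.numeric(sexf_te)
  pg <- fit$u[["polygenic"]][match(test, labels)]
  obs <- phe[[trait]][match(test, phe$animal)]
  pred <- data.frame(animal = test, sex = unname(sex_all[test]),
                     observed = obs, predicted = fixed + pg,
                     fixed = fixed, polygenic = pg,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(predictions = pred, fit = fit,
                 model_tag = paste0("polygenic_only_", polygenic)),
            class = "prediction_result")
}

#' GBLUP prediction with additive and dominance genomic values
#'
#' Fits `y = mu + sex + g + d + e` on the training animals with
#' `g ~ N(0, G sigma2_g)` and optionally `d ~ N(0, D sigma2_d)`, variance
#' components estimated on the training subset, then predicts validation
#' animals either directly through the covariance blocks of G (and D), or
#' by back-solving per-marker additive (and dominance) effects from the
#' training genomic values and applying them to the validation genotypes.
#' The two routes are algebraically identical.
#'
#' @param study a `synthetic_study` (or compatible list).
#' @param trait `"pnp"` or `"hnh"`.
#' @param train,test animal id vectors.
#' @param G additive [relmatrix()] covering train and test.
#' @param D optional dominance [relmatrix()].
#' @param route `"covariance"` or `"backsolve"`.
#' @param geno genotype source for the backsolve route (defaults to
#'   `study$geno`); must be the matrix G/D were built from.
#' @param method variance-component method.
#' @return A `prediction_result` with components `fixed`, `additive`,
#'   `dominance` and attribute `marker_effects` (backsolve route).
#' @export
gblup_predict <- function(study, trait, train, test, G, D = NULL,
                          route = c("covariance", "backsolve"), geno = NULL,
                          method = "REML") {
  route <- match.arg(route)
  if (length(intersect(train, test))) stop("train and test overlap")
  if (!all(c(train, test) %in% G$labels)) {
    stop("G does not cover all train and test animals")
  }
  phe <- study$phe
  ytr <- phe[[trait]][match(train, phe$animal)]
  sex_all <- stats::setNames(study$ped$sex, study$ped$animal)
  sexf_tr <- sex_all[train] == "female"
  X <- cbind("(Intercept)" = 1, sexF = as.numeric(sexf_tr))
  Zg <- Matrix::sparseMatrix(i = seq_along(train), j = match(train, G$labels),
                             x = 1, dims = c(length(train), length(G$labels)))
  terms <- list(mm_random("additive", Zg, K = G))
  if (!is.null(D)) {
    if (!identical(D$labels, G$labels)) stop("G and D label mismatch")
    terms <- c(terms, list(mm_random("dominance", Zg, K = D)))
  }
  fit <- fit_variance_components(mm_spec(ytr, X, terms), method = method)
  sexf_te <- sex_all[test] == "female"
  fixed <- fit$b["(Intercept)"] + fit$b["sexF"] * as.numeric(sexf_te)
  gv_tr <- fit$u[["additive"]][match(train, G$labels)]
  dv_tr <- if (!is.null(D)) fit$u[["dominance"]][match(train, G$labels)] else NULL
  marker_effects <- NULL
  if (route == "covariance") {
    add <- fit$u[["additive"]][match(test, G$labels)]
    dom <- if (!is.null(D)) fit$u[["dominance"]][match(test, G$labels)] else rep(0, length(test))
  } else {
    if (is.null(geno)) geno <- study$geno
    dos <- mean_impute_dosage(subset_geno(geno, animals = c(train, test)),
                              quiet = TRUE)
    p <- G$freq
    dos <- dos[, names(p), drop = FALSE]
    W <- sweep(dos, 2, 2 * p)
    alpha <- backsolve_marker_effects(gv_tr, W[train, , drop = FALSE],
                                      G, G$scale_c, subset = train)
    add <- as.numeric(W[test, , drop = FALSE] %*% alpha) / G$scale_c
    marker_effects <- list(additive = alpha)
    dom <- rep(0, length(test))
    if (!is.null(D)) {
      H <- dominance_code(dos, p)
      delta <- backsolve_marker_effects(dv_tr, H[train, , drop = FALSE],
                                        D, D$scale_c, subset = train)
      dom <- as.numeric(H[test, , drop = FALSE] %*% delta) / D$scale_c
      marker_effects$dominance <- delta
    }
  }
  obs <- phe[[trait]][match(test, phe$animal)]
  pred <- data.frame(animal = test, sex = unname(sex_all[test]),
                     observed = obs, predicted = fixed + add + dom,
                     fixed = fixed, additive = add, dominance = dom,
                     stringsAsFactors = FALSE, row.names = NULL)
  out <- structure(list(predictions = pred, fit = fit,
                        model_tag = paste0("gblup_", route,
                                           if (!is.null(D)) "_GD" else "_G")),
                   class = "prediction_result")
  attr(out, "marker_effects") <- marker_effects
  out
}

#' Back-solve per-marker effects from genomic values
#'
#' `alpha = W' (G_tt + ridge I)^-1 g_hat` (the `1/c` scaling is applied
#' when effects are turned back into genetic values, so that
#' `W alpha / c` reconstructs `g_hat` up to ridge-level error). Checks that
#' W and G share provenance (`W W' / c` must reproduce the training block
#' of G).
#'
#' @param gebv genomic values of the training animals.
#' @param W centred genotype design of the training animals (rows in the
#'   same order as `gebv`).
#' @param G the [relmatrix()] W was used to build.
#' @param scale_c the scale constant `c` of G.
#' @param subset training animal ids (rows of G to use); default all.
#' @param ridge diagonal ridge.
#' @return numeric vector of per-marker effects (in `W' G^-1 g` units).
#' @export
backsolve_marker_effects <- function(gebv, W, G, scale_c, subset = NULL,
                                     ridge = 1e-6) {
  Gtt <- if (is.null(subset)) G$values else G$values[subset, subset]
  if (nrow(W) != nrow(Gtt) || length(gebv) != nrow(Gtt)) {
    stop("dimensions of gebv, W and G do not agree")
  }
  if (max(abs(tcrossprod(W) / scale_c - Gtt)) > 1e-8) {
    stop("mismatched W/G provenance: W W' / c does not reproduce G")
  }
  sol <- solve(Gtt + diag(ridge, nrow(Gtt)), gebv)
  as.numeric(crossprod(W, sol))
}

#' k-fold cross-validation of a predictor
#'
#' Random animal-level partition into `k` folds, repeated `repeats` times.
#' The supplied predictor is refitted per fold on the training ids only and
#' per-fold, per-sex Pearson accuracies are aggregated as mean and standard
#' error (`sd / sqrt(#contributing folds)`) per sex; fold cells with a
#' constant observed trait are excluded from the mean with a warning.
#'
#' @param predict_fn function(train_ids, test_ids) returning a numeric
#'   vector of predictions named by (or ordered as) `test_ids`.
#' @param ids animal ids to partition.
#' @param observed named binary vector over `ids`.
#' @param sex named sex labels over `ids`.
#' @param k folds (>= 2).
#' @param repeats repetitions.
#' @param seed partition seed.
#' @return object of class `validation_report`.
#' @export
kfold_cv <- function(predict_fn, ids, observed, sex, k = 5, repeats = 5,
                     seed = 1) {
  stopifnot(k >= 2)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- sample(rep_len(seq_len(k), length(ids)))
    for (fold in seq_len(k)) {
      test <- ids[fold_of == fold]
      train <- ids[fold_of != fold]
      pred <- predict_fn(train, test)
      if (!is.null(names(pred))) pred <- pred[test]
      acc <- accuracy(pred, observed[test], sex[test])
      acc$rep_i <- rep_i; acc$fold <- fold
      rows[[length(rows) + 1]] <- acc
    }
  }
  folds <- do.call(rbind, rows)
  validation_report("cv5x5", folds)
}

#' Within- and across-family validation splits
#'
#' Restricts to offspring of sires with more than `min_offspring` offspring
#' among `ids`, then builds `n_folds` randomised train/test splits:
#' `within` halves every eligible half-sib family (odd counts resolved
#' toward training), so each sire appears on both sides; `across` assigns
#' approximately half of the families wholly to training, so no sire spans
#' the split.
#'
#' @param ped a [pedigree()].
#' @param ids phenotyped animal ids to split.
#' @param mode `"within"` or `"across"`.
#' @param min_offspring eligibility threshold (strictly more than this).
#' @param n_folds number of randomised splits.
#' @param seed seed.
#' @return list of `n_folds` lists with `train` and `test` id vectors, with
#'   attribute `eligible` (animals used) and `n_families`.
#' @export
family_split <- function(ped, ids, mode = c("within", "across"),
                         min_offspring = 13, n_folds = 5, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  sire_of <- stats::setNames(ped$sire, ped$animal)[ids]
  ids <- ids[!is.na(sire_of)]
  sire_of <- sire_of[!is.na(sire_of)]
  fam_size <- table(sire_of)
  eligible_sires <- names(fam_size)[fam_size > min_offspring]
  if (!length(eligible_sires)) stop("no sires with more than ", min_offspring,
                                    " offspring")
  keep <- sire_of %in% eligible_sires
  ids <- ids[keep]; sire_of <- sire_of[keep]
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    if (mode == "within") {
      train <- character(0); test <- character(0)
      for (s in eligible_sires) {
        fam <- sample(ids[sire_of == s])
        n_tr <- ceiling(length(fam) / 2)    # odd counts toward training
        train <- c(train, fam[seq_len(n_tr)])
        test <- c(test, fam[-seq_len(n_tr)])
      }
    } else {
      fams <- sample(eligible_sires)
      n_tr <- ceiling(length(fams) / 2)
      train <- ids[sire_of %in% fams[seq_len(n_tr)]]
      test <- ids[sire_of %in% fams[-seq_len(n_tr)]]
    }
    folds[[f]] <- list(train = train, test = test)
  }
  attr(folds, "eligible") <- ids
  attr(folds, "n_families") <- length(eligible_sires)
  folds
}

#' Run a predictor over prebuilt validation folds
#'
#' @param predict_fn as in [kfold_cv()].
#' @param folds list of `list(train, test)` splits (see [family_split()]).
#' @param observed,sex named vectors over all involved ids.
#' @param scheme label for the report.
#' @return A `validation_report`.
#' @export
run_validation <- function(predict_fn, folds, observed, sex,
                           scheme = "family") {
  rows <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]$test
    pred <- predict_fn(folds[[f]]$train, test)
    if (!is.null(names(pred))) pred <- pred[test]
    acc <- accuracy(pred, observed[test], sex[test])
    acc$rep_i <- 1L; acc$fold <- f
    rows[[length(rows) + 1]] <- acc
  }
  validation_report(scheme, do.call(rbind, rows))
}

validation_report <- function(scheme, folds) {
  if (anyNA(folds$r)) {
    warning(sum(is.na(folds$r)),
            " fold cell(s) with undefined accuracy excluded from the mean")
  }
  groups <- unique(folds$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    r <- folds$r[folds$group == g]
    r <- r[!is.na(r)]
    data.frame(group = g, folds = length(r), mean = mean(r),
               se = stats::sd(r) / sqrt(length(r)), stringsAsFactors = FALSE)
  }))
  structure(list(scheme = scheme, folds = folds, summary = summ),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report [", x$scheme, "]\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
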