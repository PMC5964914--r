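test_that("accuracy reproduces hand-computed correlations and edge cases", {
  p <- c(0.2, 0.8, 0.4, 0.9, 0.1)
  o <- c(0, 1, 1, 1, 0)
  hand <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(accuracy(p, o)$r[1], hand, tolerance = 1e-12)
  expect_equal(accuracy(o, o)$r[1], 1.0)
  expect_equal(accuracy(1 - o, o)$r[1], -1.0)
  expect_true(is.na(accuracy(rep(0.5, 5), o)$r[1]))
  bysex <- accuracy(p, o, c("f", "f", "f", "m", "m"))
  expect_equal(nrow(bysex), 3)
})

test_that("back-solved marker effects reconstruct the genomic values", {
  set.seed(55)
  dos <- matrix(rbinom(80 * 40, 2, 0.4), 80, 40,
                dimnames = list(paste0("a", 1:80), paste0("m", 1:40)))
  G <- build_grm(dos)
  p <- G$freq
  W <- sweep(dos[, names(p)], 2, 2 * p)
  ghat <- as.numeric(G$values %*% rnorm(80)) # a plausible GEBV vector
  alpha <- backsolve_marker_effects(ghat, W, G, G$scale_c)
  recon <- as.numeric(W %*% alpha) / G$scale_c
  expect_lt(sqrt(sum((recon - ghat)^2)) / sqrt(sum(ghat^2)), 1e-4)
  # null GEBVs give null effects
  expect_equal(backsolve_marker_effects(rep(0, 80), W, G, G$scale_c),
               rep(0, 40))
  # provenance check fires on a mismatched W
  expect_error(backsolve_marker_effects(ghat, W * 2, G, G$scale_c),
               "provenance")
})

test_that("one-marker back-solving equals the single-SNP random-effect solution", {
  set.seed(66)
  n <- 60
  dos <- matrix(rbinom(n, 2, 0.4), n, 1,
                dimnames = list(paste0("a", 1:n), "m1"))
  y <- 0.3 * dos[, 1] + rnorm(n)
  G <- build_grm(dos)
  s2g <- 0.25; s2e <- 0.9
  Zg <- diag(n)
  fit_g <- solve_mme(mm_spec(y, NULL, list(mm_random("g", Zg, K = G, ridge = 1e-6))),
                     c(g = s2g), s2e)
  # equivalent SNP-BLUP: u_snp ~ N(0, s2g / c), y = mu + W u + e
  p <- G$freq
  W <- sweep(dos, 2, 2 * p)
  fit_s <- solve_mme(mm_spec(y, NULL, list(mm_random("snp", W))),
                     c(snp = s2g / G$scale_c), s2e)
  alpha <- backsolve_marker_effects(fit_g$u$g, W, G, G$scale_c) / G$scale_c
  expect_equal(as.numeric(alpha), as.numeric(fit_s$u$snp), tolerance = 1e-4)
})

test_that("GBLUP covariance and back-solve routes agree", {
  st <- medium_study()
  off <- st$phe$animal
  dos <- mean_impute_dosage(st$geno, quiet = TRUE)[off, ]
  G <- build_grm(dos)
  D <- build_drm(dos)
  set.seed(1)
  te <- sample(off, 60); tr <- setdiff(off, te)
  pa <- gblup_predict(st, "hnh", tr, te, G, D, route = "covariance")
  pb <- gblup_predict(st, "hnh", tr, te, G, D, route = "backsolve")
  expect_lt(max(abs(pa$predictions$predicted - pb$predictions$predicted)), 1e-6)
  # dropping the dominance matrix reduces to additive-only GBLUP
  pg <- gblup_predict(st, "hnh", tr, te, G, route = "covariance")
  expect_true(all(pg$predictions$dominance == 0))
})

test_that("a fully penetrant locus is predicted perfectly without polygenics", {
  cfg <- sim_config(n_sires = 20, offspring_range = c(8, 12), n_markers = 8,
                    sigma2_a = 0,
                    penetrance = penetrance_model(
                      female = rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)),
                      male = rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))),
                    seed = 91)
  st <- simulate_study(cfg)
  off <- st$phe$animal
  set.seed(2)
  te <- sample(off, 40); tr <- setdiff(off, te)
  pr <- predict_marker_model(st, moi_spec(2, "hnh", st$causal_marker, "none"),
                             tr, te)
  acc <- accuracy(pr$predictions$predicted, pr$predictions$observed)
  expect_gt(acc$r[1], 0.999)
})

test_that("unrelated validation animals receive a zero pedigree polygenic component", {
  st <- medium_study()
  off <- st$phe$animal
  sires <- unique(st$ped$sire[match(off, st$ped$animal)])
  te_sires <- sires[1:5]
  sire_of <- st$ped$sire[match(off, st$ped$animal)]
  te <- off[sire_of %in% te_sires]
  tr <- setdiff(off, te)
  # break all dam-sharing links by restricting to a block-diagonal pedigree:
  # test families and training families share no parents by construction
  dams_te <- unique(st$ped$dam[match(te, st$ped$animal)])
  dams_tr <- unique(st$ped$dam[match(tr, st$ped$animal)])
  expect_length(intersect(dams_te, dams_tr), 0)
  pr <- predict_marker_model(st, moi_spec(1, "hnh", st$causal_marker,
                                          "pedigree_A"), tr, te)
  expect_lt(max(abs(pr$predictions$polygenic)), 1e-10)
})

test_that("predictions decompose into their declared components", {
  st <- medium_study()
  off <- st$phe$animal
  set.seed(3)
  te <- sample(off, 50); tr <- setdiff(off, te)
  pr <- predict_marker_model(st, moi_spec(4, "hnh", st$causal_marker,
                                          "pedigree_A"), tr, te)
  with(pr$predictions,
       expect_equal(predicted, fixed + marker + polygenic, tolerance = 1e-12))
})

test_that("no phenotype leakage: test responses never affect predictions", {
  st <- medium_study()
  off <- st$phe$animal
  set.seed(4)
  te <- sample(off, 50); tr <- setdiff(off, te)
  pr1 <- predict_marker_model(st, moi_spec(2, "hnh", st$causal_marker,
                                           "pedigree_A"), tr, te)
  st2 <- st
  st2$phe$hnh[st2$phe$animal %in% te] <-
    1L - st2$phe$hnh[st2$phe$animal %in% te]
  pr2 <- predict_marker_model(st2, moi_spec(2, "hnh", st$causal_marker,
                                            "pedigree_A"), tr, te)
  expect_identical(pr1$predictions$predicted, pr2$predictions$predicted)
})

test_that("family splits satisfy their defining properties", {
  st <- medium_study()
  off <- st$phe$animal
  sire_of <- stats::setNames(st$ped$sire, st$ped$animal)
  ac <- family_split(st$ped, off, "across", min_offspring = 13, seed = 9)
  for (f in ac) {
    expect_length(intersect(sire_of[f$train], sire_of[f$test]), 0)
  }
  wi <- family_split(st$ped, off, "within", min_offspring = 13, seed = 9)
  for (f in wi[1:2]) {
    expect_setequal(unique(sire_of[f$train]), unique(sire_of[f$test]))
    # per-family balance within one animal
    for (s in unique(sire_of[f$train])) {
      ntr <- sum(sire_of[f$train] == s); nte <- sum(sire_of[f$test] == s)
      expect_lte(abs(ntr - nte), 1)
    }
  }
  # eligibility: a sire with exactly min_offspring offspring is excluded
  fam_sizes <- table(sire_of[off])
  thr <- as.numeric(stats::quantile(fam_sizes, 0.5))
  sp <- family_split(st$ped, off, "across", min_offspring = thr, seed = 1)
  used_sires <- unique(sire_of[attr(sp, "eligible")])
  expect_true(all(fam_sizes[used_sires] > thr))
  expect_error(family_split(st$ped, off, "across", min_offspring = 1e6),
               "no sires")
})

test_that("cross-validation partitions are balanced and aggregate correctly", {
  set.seed(10)
  ids <- paste0("a", 1:103)
  obs <- stats::setNames(rbinom(103, 1, 0.4), ids)
  sex <- stats::setNames(sample(c("female", "wether"), 103, TRUE), ids)
  sizes <- integer(0)
  rec <- kfold_cv(function(tr, te) {
    sizes <<- c(sizes, length(te))
    stats::setNames(obs[te], te)        # perfect predictor
  }, ids, obs, sex, k = 5, repeats = 2, seed = 3)
  expect_true(all(abs(sizes - 103 / 5) <= 1))
  pooled <- rec$summary[rec$summary$group == "pooled", ]
  expect_equal(pooled$mean, 1.0)
  expect_equal(pooled$se, 0)
})

test_that("a null predictor scores within two standard errors of zero", {
  set.seed(11)
  ids <- paste0("a", 1:400)
  obs <- stats::setNames(rbinom(400, 1, 0.4), ids)
  sex <- stats::setNames(sample(c("female", "wether"), 400, TRUE), ids)
  rec <- kfold_cv(function(tr, te) stats::setNames(stats::rnorm(length(te)), te),
                  ids, obs, sex, k = 5, repeats = 5, seed = 12)
  pooled <- rec$summary[rec$summary$group == "pooled", ]
  expect_lt(abs(pooled$mean), 2 * pooled$se + 1e-12)
})

test_that("insertion-based prediction degrades under genotype error", {
  st <- medium_study()
  off <- st$phe$animal
  set.seed(13)
  te <- sample(off, 80); tr <- setdiff(off, te)
  spec <- moi_spec(2, "hnh", st$causal_marker, "none")
  clean <- predict_marker_model(st, spec, tr, te)
  noisy <- predict_marker_model(st, spec, tr, te, genotype_error = 0.5,
                                seed = 14)
  r_clean <- accuracy(clean$predictions$predicted, clean$predictions$observed)$r[1]
  r_noisy <- accuracy(noisy$predictions$predicted, noisy$predictions$observed)$r[1]
  expect_lt(r_noisy, r_clean)
})

test_that("family designs separate linkage from LD information", {
  st <- medium_study()
  off <- st$phe$animal
  obs <- stats::setNames(st$phe$hnh, off)
  sex <- stats::setNames(st$ped$sex[match(off, st$ped$animal)], off)
  spec <- moi_spec(2, "hnh", st$causal_marker, "pedigree_A")
  score <- function(folds) {
    rs <- vapply(folds, function(f) {
      pr <- predict_marker_model(st, spec, f$train, f$test)
      accuracy(pr$predictions$predicted, pr$predictions$observed)$r[1]
    }, 0)
    c(mean = mean(rs), se = stats::sd(rs) / sqrt(length(rs)))
  }
  wi <- score(family_split(st$ped, off, "within", min_offspring = 13, seed = 5))
  ac <- score(family_split(st$ped, off, "across", min_offspring = 13, seed = 5))
  # a strong causal marker predicts through LD alone: the two designs agree
  pooled_se <- sqrt(wi["se"]^2 + ac["se"]^2)
  expect_lt(abs(wi["mean"] - ac["mean"]), 2 * pooled_se + 0.02)

  # pure family information (no marker fitted): within-family prediction
  # keeps its edge over across-family prediction
  score_pol <- function(folds) {
    mean(vapply(folds, function(f) {
      pr <- predict_polygenic(st, "hnh", f$train, f$test, "pedigree_A")
      accuracy(pr$predictions$predicted, pr$predictions$observed)$r[1]
    }, 0))
  }
  wi_pol <- score_pol(family_split(st$ped, off, "within", min_offspring = 13,
                                   seed = 6))
  ac_pol <- score_pol(family_split(st$ped, off, "across", min_offspring = 13,
                                   seed = 6))
  expect_gt(wi_pol, ac_pol)
})
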