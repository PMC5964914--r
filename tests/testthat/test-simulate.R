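test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_sires = 8, offspring_range = c(2, 6), n_markers = 6,
                    sigma2_a = 0.2, seed = 31)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$phe, b$phe)
  expect_identical(a$polygenic, b$polygenic)
})

test_that("phase always sums to dosage after gene drop", {
  st <- medium_study()
  expect_true(all(st$geno$hap1 + st$geno$hap2 == st$geno$dosage))
})

test_that("founder pool hits the configured tag r2 and frequencies", {
  cfg <- sim_config(n_founder_haplotypes = 10000, tag_r2 = 0.985, seed = 5)
  pool <- simulate_founder_haplotypes(cfg)
  ci <- pool$causal_index
  tag_j <- setdiff(order(abs(pool$markers$pos - cfg$causal_pos)), ci)[1]
  r2 <- cor(pool$haps[, ci], pool$haps[, tag_j])^2
  expect_lt(abs(r2 - 0.985), 0.01)
  expect_lt(abs(mean(pool$haps[, ci]) - cfg$causal_freq), 0.02)
})

test_that("zero switch rate makes every marker a perfect causal proxy", {
  cfg <- sim_config(switch_rate = 0, tag_r2 = numeric(0), n_markers = 6,
                    n_founder_haplotypes = 2000, seed = 6)
  pool <- simulate_founder_haplotypes(cfg)
  r2 <- cor(pool$haps[, pool$causal_index], pool$haps)^2
  expect_true(all(r2 > 1 - 1e-12))
})

test_that("high switch rate decorrelates markers away from the causal locus", {
  cfg <- sim_config(switch_rate = 0.5, tag_r2 = numeric(0), n_markers = 12,
                    n_founder_haplotypes = 10000, seed = 8)
  pool <- simulate_founder_haplotypes(cfg)
  ci <- pool$causal_index
  far <- which(seq_len(ncol(pool$haps)) != ci &
                 abs(seq_len(ncol(pool$haps)) - ci) > 2)
  r2 <- cor(pool$haps[, ci], pool$haps[, far])^2
  expect_lt(max(r2), 0.02)
})

test_that("unreachable LD targets fail with the Hill-Robertson bound cited", {
  cfg <- sim_config(marker_freq = 0.05, tag_r2 = 0.985, seed = 7)
  expect_error(simulate_founder_haplotypes(cfg), "Hill-Robertson")
})

test_that("increasing the r2 target never decreases realized LD", {
  targets <- c(0.2, 0.5, 0.8, 0.985)
  mean_r2 <- vapply(targets, function(tg) {
    r2s <- vapply(1:10, function(s) {
      cfg <- sim_config(tag_r2 = tg, n_founder_haplotypes = 3000, seed = 100 + s)
      pool <- simulate_founder_haplotypes(cfg)
      ci <- pool$causal_index
      tag_j <- setdiff(order(abs(pool$markers$pos - cfg$causal_pos)), ci)[1]
      cor(pool$haps[, ci], pool$haps[, tag_j])^2
    }, 0)
    mean(r2s)
  }, 0)
  expect_true(all(diff(mean_r2) > 0))
})

test_that("half-sib pedigree matches the configured family structure", {
  cfg <- sim_config(seed = 17)
  ped <- simulate_pedigree(cfg)
  off <- ped[!is.na(ped$sire), ]
  fam <- table(off$sire)
  expect_equal(length(fam), 182)
  expect_true(all(fam >= 1 & fam <= 51))
  expect_lt(abs(nrow(off) - 182 * 26), 4 * sqrt(182 * var(1:51)))
  # dams average ~1.5 offspring
  expect_lt(abs(mean(table(off$dam)) - 1.5), 0.15)
  # sex ratio near half at n ~ 4700
  expect_lt(abs(mean(off$sex == "female") - 0.5), 0.05)
})

test_that("single-sire pedigrees contain only half- and full-sibs", {
  cfg <- sim_config(n_sires = 1, offspring_range = c(10, 10), seed = 23)
  ped <- simulate_pedigree(cfg)
  off <- ped[!is.na(ped$sire), ]
  expect_equal(unique(off$sire), "S1")
  A <- build_nrm(ped)$values
  rel <- A[off$animal, off$animal]
  expect_true(all(rel[upper.tri(rel)] >= 0.25 - 1e-12))
})

test_that("gene drop without recombination copies parental haplotypes", {
  cfg <- sim_config(n_sires = 6, offspring_range = c(3, 6), n_markers = 8,
                    recomb_rate = 0, seed = 41)
  ped <- simulate_pedigree(cfg)
  pool <- simulate_founder_haplotypes(cfg, seed = 42)
  g <- gene_drop(ped, pool, recomb_rate = 0, seed = 43)
  off_idx <- which(!is.na(ped$sire))
  for (i in off_idx[1:10]) {
    s <- match(ped$sire[i], ped$animal)
    matches_sire <- identical(g$hap1[i, ], g$hap1[s, ]) ||
      identical(g$hap1[i, ], g$hap2[s, ])
    expect_true(matches_sire)
  }
  # homozygous parents force the offspring genotype
  both_hom <- which(vapply(off_idx, function(i) {
    s <- match(ped$sire[i], ped$animal); d <- match(ped$dam[i], ped$animal)
    all(g$dosage[s, ] %in% c(0, 2)) && all(g$dosage[d, ] %in% c(0, 2))
  }, TRUE))
  for (i in off_idx[both_hom]) {
    s <- match(ped$sire[i], ped$animal); d <- match(ped$dam[i], ped$animal)
    expect_equal(g$dosage[i, ], (g$dosage[s, ] + g$dosage[d, ]) / 2)
  }
})

test_that("founder genotypes sit within Hardy-Weinberg sampling bounds", {
  viol <- 0; total <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_sires = 50, offspring_range = c(1, 2), n_markers = 30,
                      switch_rate = 0.5, tag_r2 = numeric(0), seed = 300 + s)
    ped <- simulate_pedigree(cfg)
    pool <- simulate_founder_haplotypes(cfg)
    g <- gene_drop(ped, pool, cfg$recomb_rate, seed = cfg$seed + 2)
    founders <- attr(ped, "founders")
    d <- g$dosage[founders, ]
    chi <- hornpred:::hwe_chisq(colSums(d == 0), colSums(d == 1),
                                colSums(d == 2))
    total <- total + length(chi)
    viol <- viol + sum(chi > qchisq(0.999, 1))
  }
  expect_lt(viol / total, 0.01)
})

test_that("penetrance draws reproduce the sex-specific genotype-conditional rates", {
  pen <- default_penetrance()
  n_per <- 700
  geno <- rep(0:2, each = n_per)
  phe_m <- assign_phenotypes(geno, rep("wether", 3 * n_per),
                             penetrance = pen, seed = 51)
  # male P(horned | g): 0.67, 0.01, 0.00
  for (g in 0:2) {
    ph <- mean(phe_m$hnh[geno == g])
    expected <- pen$male[g + 1, "horned"]
    expect_lt(abs(ph - expected), 3 * sqrt(max(expected * (1 - expected), 1e-4) / n_per))
  }
  # male P(polled | g): 0.04, 0.53, 0.78
  for (g in 0:2) {
    pp <- mean(1 - phe_m$pnp[geno == g])
    expected <- pen$male[g + 1, "polled"]
    expect_lt(abs(pp - expected), 3 * sqrt(expected * (1 - expected) / n_per))
  }
})

test_that("degenerate penetrance and zero polygenic variance behave as stated", {
  all_polled <- penetrance_model(
    female = cbind(rep(1, 3), 0, 0), male = cbind(rep(1, 3), 0, 0))
  phe <- assign_phenotypes(rep(0:2, 20), rep(c("female", "wether"), 30),
                           penetrance = all_polled, seed = 61)
  expect_true(all(phe$horn_score == "polled"))
  expect_equal(var(phe$pnp), 0)

  cfg <- sim_config(n_sires = 5, offspring_range = c(2, 4), n_markers = 5,
                    sigma2_a = 0, seed = 63)
  st <- simulate_study(cfg)
  expect_true(all(st$polygenic == 0))
})

test_that("simulated class frequencies by sex track the emulated population margins", {
  cfg <- sim_config(seed = 71, sigma2_a = 0)
  st <- simulate_study(cfg)
  sex <- st$ped$sex[match(st$phe$animal, st$ped$animal)]
  f <- st$phe[sex == "female", ]; m <- st$phe[sex == "wether", ]
  # emulated margins: females 1123/1237/88 of 2448; males 511/561/481 of 1553
  expect_lt(abs(mean(f$horn_score == "polled") - 1123 / 2448), 0.05)
  expect_lt(abs(mean(f$hnh) - 88 / 2448), 0.03)
  expect_lt(abs(mean(m$horn_score == "polled") - 511 / 1553), 0.05)
  expect_lt(abs(mean(m$hnh) - 481 / 1553), 0.05)
})

test_that("penetrance matrices are validated", {
  expect_error(penetrance_model(female = cbind(c(0.5, 0.5, 0.5), 0.6, 0),
                                male = diag(3)), "sum to 1")
  expect_error(penetrance_model(female = cbind(c(1.2, 1, 1), c(-0.2, 0, 0), 0),
                                male = diag(3)), "outside")
})
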