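#' Sex-by-genotype penetrance model
#'
#' Probability vectors over the three phenotype classes
#' (polled, knobs/scurs, horned) for each sex x causal-genotype cell.
#' Genotype is the count (0/1/2) of the polled-associated allele.
#'
#' @param female,male 3 x 3 numeric matrices (rows = genotype 0/1/2,
#'   columns = polled, knobs_scurs, horned); each row must sum to 1.
#' @return object of class `penetrance_model`.
#' @export
penetrance_model <- function(female, male) {
  check <- function(m, sex) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(3, 3))) stop(sex, " matrix must be 3 x 3")
    if (any(m < 0) || any(m > 1)) stop(sex, " probabilities outside [0, 1]")
    if (any(abs(rowSums(m) - 1) > 1e-12)) stop(sex, " rows must sum to 1")
    dimnames(m) <- list(genotype = 0:2,
                        class = c("polled", "knobs_scurs", "horned"))
    m
  }
  structure(list(female = check(female, "female"), male = check(male, "male")),
            class = "penetrance_model")
}

#' Default penetrance calibrated to the observed Merino genotype-conditional
#' probabilities
#'
#' Per sex and causal genotype (0 = no copies of the polled-associated
#' allele), P(polled) and P(horned) follow the genotype-conditional
#' probabilities observed in Australian Merino data (males: P(horned) = 0.67/0.01/0.00
#' and P(polled) = 0.04/0.53/0.78 for genotypes 0/1/2; females:
#' P(horned) = 0.07/0.01/0.01, P(polled) = 0.14/0.77/0.85); knobs/scurs
#' take the remaining mass.
#'
#' @return A [penetrance_model()].
#' @export
default_penetrance <- function() {
  f_polled <- c(0.14, 0.77, 0.85); f_horned <- c(0.07, 0.01, 0.01)
  m_polled <- c(0.04, 0.53, 0.78); m_horned <- c(0.67, 0.01, 0.00)
  penetrance_model(
    female = cbind(f_polled, 1 - f_polled - f_horned, f_horned),
    male = cbind(m_polled, 1 - m_polled - m_horned, m_horned))
}

#' Additive (no-dominance, no-sex-difference) penetrance for null scenarios
#'
#' P(horned) declines linearly in the polled-allele count and is identical
#' in both sexes, so the causal locus acts purely additively on both binary
#' traits.
#'
#' @param p_horned length-3 P(horned) by genotype (default 0.6, 0.35, 0.1).
#' @param p_polled length-3 P(polled) by genotype (default 0.1, 0.35, 0.6).
#' @return A [penetrance_model()].
#' @export
additive_penetrance <- function(p_horned = c(0.6, 0.35, 0.1),
                                p_polled = c(0.1, 0.35, 0.6)) {
  m <- cbind(p_polled, 1 - p_polled - p_horned, p_horned)
  penetrance_model(female = m, male = m)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the simulator: a two-generation
#' half-sib population (default 182 sires with 1-51 offspring each, dams
#' reused so that a dam averages 1.5 offspring), an OAR10-like chromosome
#' segment with a biallelic causal insertion locus at 29,456,047 bp tagged
#' by SNPs in strong LD (default target r2 = 0.985), and sex-dependent
#' four-class penetrance at the causal locus.
#'
#' @param n_sires number of sires.
#' @param offspring_range integer range of offspring per sire (uniform).
#' @param mean_offspring_per_dam dam-reuse calibration target.
#' @param female_prop probability an offspring is female (vs wether).
#' @param n_markers number of non-causal markers.
#' @param chrom chromosome label.
#' @param chrom_start,chrom_end segment bounds in bp.
#' @param causal_pos causal-locus position in bp.
#' @param causal_freq founder frequency of the polled-associated allele.
#' @param marker_freq founder alt-allele frequency for non-causal markers
#'   (recycled).
#' @param tag_r2 named numeric vector: target r2 between the causal locus
#'   and designated tag markers (names are tag indices into the non-causal
#'   markers, or `NULL` names to tag the markers nearest the causal locus).
#' @param switch_rate per-marker lineage-break probability of the founder
#'   mosaic (controls background LD decay away from the causal locus).
#' @param recomb_rate recombination rate in Morgan per bp.
#' @param sigma2_a polygenic liability variance on the logit scale of the
#'   horned-class probability; the default 0.2 leaves a residual polygenic
#'   liability heritability of roughly `0.2 / (0.2 + pi^2/3) ~ 0.06` once
#'   the causal locus is accounted for.
#' @param penetrance a [penetrance_model()].
#' @param n_founder_haplotypes size of the founder haplotype pool.
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 182, offspring_range = c(1, 51),
                       mean_offspring_per_dam = 1.5, female_prop = 0.5,
                       n_markers = 20, chrom = "10",
                       chrom_start = 29.2e6, chrom_end = 29.8e6,
                       causal_pos = 29456047, causal_freq = 0.3,
                       marker_freq = 0.3, tag_r2 = c(0.985),
                       switch_rate = 0.05, recomb_rate = 1e-8,
                       sigma2_a = 0.2, penetrance = default_penetrance(),
                       n_founder_haplotypes = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sires >= 1, offspring_range[1] >= 1,
            offspring_range[2] >= offspring_range[1],
            mean_offspring_per_dam >= 1, female_prop > 0, female_prop < 1,
            n_markers >= 2, causal_freq > 0, causal_freq < 1,
            all(tag_r2 >= 0), all(tag_r2 <= 1), switch_rate >= 0,
            switch_rate <= 1, recomb_rate >= 0, sigma2_a >= 0,
            causal_pos > chrom_start, causal_pos < chrom_end)
  structure(as.list(environment()), class = "sim_config")
}

# Hill-Robertson upper bound on r2 for allele frequencies p and q.
r2_max <- function(p, q) {
  dmax <- max(min(p * (1 - q), q * (1 - p)), min(p * q, (1 - p) * (1 - q)))
  dmax^2 / (p * (1 - p) * q * (1 - q))
}

#' Simulate a founder haplotype pool
#'
#' Mosaic copying scheme around the causal locus: each haplotype draws a
#' causal allele, then walks outward marker by marker carrying a latent
#' "linked" state that breaks with probability `switch_rate` per marker;
#' linked markers copy the causal allele, broken markers draw independently
#' at their configured frequency. Designated tag markers instead copy the
#' causal allele with the probability required to hit their target r2
#' exactly in expectation, which requires the target to be feasible under
#' the Hill-Robertson bound for the two allele frequencies.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `haps` (pool x markers binary matrix including the
#'   causal column), `markers` (marker table), `causal_index` (column of the
#'   causal locus).
#' @export
simulate_founder_haplotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  m <- config$n_markers
  pos <- sort(sample(seq(config$chrom_start, config$chrom_end),
                     m, replace = FALSE))
  pos <- pos[abs(pos - config$causal_pos) > 100]   # keep causal position free
  m <- length(pos)
  freq <- rep_len(config$marker_freq, m)
  # designate tags: nearest markers to the causal position, unless named
  tag_idx <- if (!is.null(names(config$tag_r2)) && all(names(config$tag_r2) != "")) {
    as.integer(names(config$tag_r2))
  } else {
    order(abs(pos - config$causal_pos))[seq_along(config$tag_r2)]
  }
  q <- config$causal_freq
  tag_copy <- numeric(0)
  for (i in seq_along(config$tag_r2)) {
    p <- freq[tag_idx[i]]
    if (config$tag_r2[i] > r2_max(p, q) + 1e-12) {
      stop(sprintf(
        "target r2 %.3f unreachable for frequencies %.2f/%.2f (Hill-Robertson r2max = %.3f)",
        config$tag_r2[i], p, q, r2_max(p, q)))
    }
    tag_copy[i] <- sqrt(config$tag_r2[i]) * sqrt(p * (1 - p) / (q * (1 - q)))
  }
  nh <- config$n_founder_haplotypes
  causal <- stats::rbinom(nh, 1, q)
  haps <- matrix(0L, nh, m)
  # walk outward from the causal position on each side
  left <- rev(which(pos < config$causal_pos))
  right <- which(pos > config$causal_pos)
  for (side in list(left, right)) {
    linked <- rep(TRUE, nh)
    for (j in side) {
      linked <- linked & (stats::runif(nh) > config$switch_rate)
      draw <- stats::rbinom(nh, 1, freq[j])
      haps[, j] <- ifelse(linked, causal, draw)
    }
  }
  # tags override the walk with calibrated copying
  for (i in seq_along(tag_idx)) {
    j <- tag_idx[i]; p <- freq[j]; t_c <- tag_copy[i]
    p_indep <- (p - t_c * q) / (1 - t_c)
    p_indep <- min(max(p_indep, 0), 1)
    copy <- stats::runif(nh) < t_c
    haps[, j] <- ifelse(copy, causal, stats::rbinom(nh, 1, p_indep))
  }
  markers <- data.frame(
    marker_id = paste0("OAR", config$chrom, "_", pos),
    chrom = config$chrom, pos = pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  ins <- data.frame(marker_id = "RXFP2_ins1780", chrom = config$chrom,
                    pos = config$causal_pos, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
  all_markers <- rbind(markers[pos < config$causal_pos, ], ins,
                       markers[pos > config$causal_pos, ])
  causal_index <- sum(pos < config$causal_pos) + 1L
  haps_all <- cbind(haps[, pos < config$causal_pos, drop = FALSE], causal,
                    haps[, pos > config$causal_pos, drop = FALSE])
  colnames(haps_all) <- all_markers$marker_id
  list(haps = haps_all, markers = all_markers, causal_index = causal_index)
}

#' Simulate a half-sib pedigree
#'
#' Each sire receives a uniform number of offspring in `offspring_range`;
#' offspring within a sire family are distributed over
#' `ceiling(n_k / mean_offspring_per_dam)` dams so that dams average the
#' configured litter contribution. Offspring sexes are independent
#' Bernoulli draws (female vs wether).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A [pedigree()]; founders are the sires and dams.
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  set.seed(seed)
  n_off_per_sire <- sample(seq(config$offspring_range[1],
                               config$offspring_range[2]),
                           config$n_sires, replace = TRUE)
  animal <- sire <- dam <- sex <- character(0)
  dam_counter <- 0
  for (s in seq_len(config$n_sires)) {
    n_k <- n_off_per_sire[s]
    n_dams <- max(1L, ceiling(n_k / config$mean_offspring_per_dam))
    dams_k <- paste0("D", dam_counter + seq_len(n_dams))
    dam_counter <- dam_counter + n_dams
    animal <- c(animal, paste0("S", s, "_", seq_len(n_k)))
    sire <- c(sire, rep(paste0("S", s), n_k))
    dam <- c(dam, sample(rep_len(dams_k, n_k)))
  }
  sex <- ifelse(stats::runif(length(animal)) < config$female_prop,
                "female", "wether")
  founders <- data.frame(
    animal = c(paste0("S", seq_len(config$n_sires)),
               paste0("D", seq_len(dam_counter))),
    sire = NA, dam = NA, sex = NA, stringsAsFactors = FALSE)
  pedigree(c(founders$animal, animal), c(founders$sire, sire),
           c(founders$dam, dam),
           c(founders$sex, sex),
           flock = NA, birth_year = NA)
}

#' Gene-drop phased genotypes through a pedigree
#'
#' Founders draw haplotype pairs from the pool; each non-founder inherits
#' one recombinant gamete per parent, with crossovers placed by a Poisson
#' process along the physical map (`recomb_rate` Morgan per bp) and the
#' starting parental strand chosen at random. Phase is retained.
#'
#' @param ped a [pedigree()] (topologically sorted, as constructed).
#' @param pool founder haplotype pool from [simulate_founder_haplotypes()].
#' @param recomb_rate Morgan per bp.
#' @param seed integer seed.
#' @return A phased [geno_matrix()] over all pedigree members.
#' @export
gene_drop <- function(ped, pool, recomb_rate, seed) {
  set.seed(seed)
  n <- nrow(ped)
  m <- nrow(pool$markers)
  pos <- pool$markers$pos
  total_morgan <- recomb_rate * (max(pos) - min(pos))
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  gamete <- function(h_a, h_b) {
    k <- stats::rpois(1, total_morgan)
    if (k == 0) {
      if (stats::runif(1) < 0.5) h_a else h_b
    } else {
      cx <- sort(stats::runif(k, min(pos), max(pos)))
      strand <- (findInterval(pos, cx) + stats::rbinom(1, 1, 0.5)) %% 2
      ifelse(strand == 0L, h_a, h_b)
    }
  }
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      pick <- sample.int(nrow(pool$haps), 2, replace = TRUE)
      hap1[i, ] <- pool$haps[pick[1], ]
      hap2[i, ] <- pool$haps[pick[2], ]
    } else {
      if (is.na(si[i]) || is.na(di[i])) {
        stop("non-founder with a single known parent: ", ped$animal[i])
      }
      hap1[i, ] <- gamete(hap1[si[i], ], hap2[si[i], ])
      hap2[i, ] <- gamete(hap1[di[i], ], hap2[di[i], ])
    }
  }
  geno_matrix(ped$animal, pool$markers, hap1 + hap2, hap1, hap2)
}

#' Assign four-class horn phenotypes
#'
#' Draws each animal's horn score from its sex x causal-genotype probability
#' vector. A non-zero polygenic value shifts the horned-class probability on
#' the logit scale (probabilities of exactly 0 or 1 are left untouched); the
#' remaining mass is redistributed proportionally over the other classes.
#'
#' @param causal_geno integer vector (0/1/2), copies of the
#'   polled-associated allele.
#' @param sex character vector (`"female"`/`"wether"`).
#' @param polygenic numeric vector of liability shifts (logit scale).
#' @param penetrance a [penetrance_model()].
#' @param seed integer seed.
#' @param animal optional animal ids.
#' @return A [phenotype_table()].
#' @export
assign_phenotypes <- function(causal_geno, sex, polygenic = 0,
                              penetrance = default_penetrance(), seed,
                              animal = NULL) {
  set.seed(seed)
  n <- length(causal_geno)
  polygenic <- rep_len(polygenic, n)
  if (is.null(animal)) animal <- paste0("A", seq_len(n))
  classes <- c("polled", "knobs", "horned")   # knobs_scurs drawn as knobs/scurs below
  score <- character(n)
  for (i in seq_len(n)) {
    tab <- if (sex[i] == "female") penetrance$female else penetrance$male
    pr <- tab[causal_geno[i] + 1, ]
    ph <- pr["horned"]
    if (polygenic[i] != 0 && ph > 0 && ph < 1) {
      ph2 <- stats::plogis(stats::qlogis(ph) + polygenic[i])
      rest <- pr[c("polled", "knobs_scurs")]
      pr <- c(rest / sum(rest) * (1 - ph2), horned = ph2)
      names(pr) <- c("polled", "knobs_scurs", "horned")
    }
    cls <- sample(c("polled", "knobs_scurs", "horned"), 1, prob = pr)
    score[i] <- if (cls == "knobs_scurs") {
      if (stats::runif(1) < 0.5) "knobs" else "scurs"
    } else cls
  }
  phenotype_table(animal, score)
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_pedigree()], [simulate_founder_haplotypes()],
#' [gene_drop()] and [assign_phenotypes()] into a reproducible synthetic
#' study: phased genotypes (causal insertion included as an ordinary
#' biallelic marker), pedigree, phenotypes for the offspring generation,
#' true polygenic values and the true causal genotype.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: list with `geno` (phased
#'   [geno_matrix()], all pedigree members), `ped`, `phe` (offspring only),
#'   `polygenic` (named true polygenic liability values), `causal_geno`
#'   (named 0/1/2 vector), `causal_marker` (its marker id), `config`.
#' @export
simulate_study <- function(config) {
  ped <- simulate_pedigree(config, seed = config$seed)
  pool <- simulate_founder_haplotypes(config, seed = config$seed + 1L)
  geno <- gene_drop(ped, pool, config$recomb_rate, seed = config$seed + 2L)
  causal_id <- pool$markers$marker_id[pool$causal_index]
  causal <- geno$dosage[, causal_id]
  # polygenic liability: founders N(0, sigma2_a), offspring mid-parent +
  # Mendelian-sampling deviation
  set.seed(config$seed + 3L)
  n <- nrow(ped)
  u <- numeric(n)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  if (config$sigma2_a > 0) {
    for (i in seq_len(n)) {
      u[i] <- if (is.na(si[i])) {
        stats::rnorm(1, 0, sqrt(config$sigma2_a))
      } else {
        0.5 * (u[si[i]] + u[di[i]]) + stats::rnorm(1, 0, sqrt(0.5 * config$sigma2_a))
      }
    }
  }
  names(u) <- ped$animal
  off <- ped$animal[!is.na(ped$sire)]
  phe <- assign_phenotypes(causal[off], ped$sex[match(off, ped$animal)],
                           u[off], config$penetrance,
                           seed = config$seed + 4L, animal = off)
  structure(list(geno = geno, ped = ped, phe = phe, polygenic = u,
                 causal_geno = causal, causal_marker = causal_id,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d pedigree members, %d phenotyped offspring, %d markers (causal: %s)\n",
              nrow(x$ped), nrow(x$phe), nrow(x$geno$markers), x$causal_marker))
  invisible(x)
}
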