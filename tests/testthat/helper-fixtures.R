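# Shared fixtures, memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

# Medium half-sib study used across module tests: ~600 phenotyped offspring,
# Table-2/3-calibrated penetrance, moderate polygenic background.
medium_study <- function() {
  if (is.null(.fixture_env$medium)) {
    cfg <- sim_config(n_sires = 40, offspring_range = c(10, 20),
                      n_markers = 15, sigma2_a = 0.3, seed = 2024)
    .fixture_env$medium <- simulate_study(cfg)
  }
  .fixture_env$medium
}

# Tiny unphased genotype fixture with known dosages.
tiny_geno <- function() {
  markers <- data.frame(marker_id = c("m1", "m2", "m3"), chrom = "10",
                        pos = c(100L, 200L, 300L), ref = "A",
                        alt = c("G", "T", "C"))
  dosage <- rbind(a1 = c(0L, 2L, 1L), a2 = c(1L, 2L, 1L), a3 = c(2L, 1L, 1L),
                  a4 = c(1L, 0L, 2L), a5 = c(0L, 0L, 0L))
  geno_matrix(rownames(dosage), markers, dosage)
}

# Independent brute-force additive-relationship oracle: the classic
# recursion a(i,i) = 1 + 0.5 a(s,d); a(i,j) = 0.5 (a(s_i,j) + a(d_i,j))
# for i below j in pedigree order, memoised on demand.
nrm_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  memo <- matrix(NA_real_, n, n)
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == j) {
      1 + 0.5 * a(ifelse(is.na(si[i]), 0, si[i]), ifelse(is.na(di[i]), 0, di[i]))
    } else {
      # j is the later-born: climb through j's parents
      0.5 * (a(ifelse(is.na(si[j]), 0, si[j]), i) +
               a(ifelse(is.na(di[j]), 0, di[j]), i))
    }
    memo[i, j] <<- v
    v
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) out[i, j] <- out[j, i] <- a(i, j)
  dimnames(out) <- list(ped$animal, ped$animal)
  out
}

# A random multi-generation pedigree for oracle comparisons.
random_pedigree <- function(n_founders = 20, n_later = 60, seed = 99) {
  set.seed(seed)
  animal <- paste0("p", seq_len(n_founders + n_later))
  sire <- dam <- rep(NA_character_, n_founders + n_later)
  for (i in (n_founders + 1):(n_founders + n_later)) {
    pick <- sample(i - 1, 2)
    sire[i] <- animal[pick[1]]
    dam[i] <- animal[pick[2]]
  }
  pedigree(animal, sire, dam)
}
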