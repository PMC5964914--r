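#' Construct a pedigree
#'
#' Validated pedigree records. Parents referenced but absent as records are
#' added as founder rows (unknown sex allowed for such implied founders).
#' The pedigree must be acyclic; the two admitted sex labels for phenotyped
#' animals are `"female"` and `"wether"` (all male lambs in the emulated design
#' are castrated before horn scoring).
#'
#' @param animal,sire,dam identifier vectors; `NA` (or `"0"`) for unknown
#'   parents.
#' @param sex character vector, `"female"` or `"wether"` (`NA` allowed for
#'   founders only implied as parents).
#' @param flock,birth_year optional labels carried along.
#' @return data.frame of class `pedigree`, topologically sorted so that
#'   parents precede offspring, with attribute `founders`.
#' @export
pedigree <- function(animal, sire = NA, dam = NA, sex = NA,
                     flock = NA, birth_year = NA) {
  norm_id <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", ".", "NA")] <- NA
    x
  }
  animal <- norm_id(animal)
  if (anyNA(animal)) stop("missing animal id")
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  n <- length(animal)
  ped <- data.frame(animal = animal, sire = rep_len(norm_id(sire), n),
                    dam = rep_len(norm_id(dam), n),
                    sex = rep_len(as.character(sex), n),
                    flock = rep_len(as.character(flock), n),
                    birth_year = rep_len(as.integer(birth_year), n),
                    stringsAsFactors = FALSE)
  bad_sex <- !is.na(ped$sex) & !ped$sex %in% c("female", "wether")
  if (any(bad_sex)) {
    stop("unknown sex label(s): ", paste(unique(ped$sex[bad_sex]), collapse = ", "),
         "; allowed labels are \"female\", \"wether\"")
  }
  implied <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(implied)) {
    ped <- rbind(data.frame(animal = implied, sire = NA_character_,
                            dam = NA_character_, sex = NA_character_,
                            flock = NA_character_, birth_year = NA_integer_,
                            stringsAsFactors = FALSE), ped)
  }
  ord <- ped_topo_sort(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  attr(ped, "founders") <- ped$animal[is.na(ped$sire) & is.na(ped$dam)]
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors naming a cycle member if one exists.
ped_topo_sort <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving: ",
         paste(ped$animal[cyc][1:min(5, length(cyc))], collapse = ", "))
  }
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals (%d founders), %d sires, %d dams\n",
              nrow(x), length(attr(x, "founders")),
              length(unique(stats::na.omit(x$sire))),
              length(unique(stats::na.omit(x$dam)))))
  invisible(x)
}

#' Read a pedigree from delimited text
#'
#' Expects a header with columns `animal,sire,dam,sex` and optionally
#' `flock,year` (CSV or TSV, sniffed from the header line).
#'
#' @param path file path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("animal", "sire", "dam", "sex")
  if (!all(req %in% names(d))) {
    stop("pedigree file must have columns: ", paste(req, collapse = ", "))
  }
  pedigree(d$animal, d$sire, d$dam, d$sex,
           if ("flock" %in% names(d)) d$flock else NA,
           if ("year" %in% names(d)) d$year else NA)
}

#' Write a pedigree to CSV
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  d <- as.data.frame(ped)
  names(d)[names(d) == "birth_year"] <- "year"
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen-Luo style recursion on the Cholesky decomposition
#' `A = T D T'` of the numerator relationship matrix: processing animals in
#' topological order, `F_i = 0.5 * a(sire, dam)` with pairwise relationships
#' obtained by recursive path tracing with memoisation.
#'
#' @param ped a [pedigree()].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  stats::setNames(ped_ldl(ped)$F, ped$animal)
}

# Cholesky recursion A = L L' on a topologically sorted pedigree.
# Returns parent indices, Mendelian-sampling variances d, inbreeding F and
# the sparse rows of L (named numeric vectors keyed by ancestor index).
ped_ldl <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  Fcoef <- numeric(n)
  Lrows <- vector("list", n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; dd <- di[i]
    if (is.na(s) && is.na(dd)) {
      d[i] <- 1
    } else if (is.na(s) || is.na(dd)) {
      Fp <- if (is.na(s)) Fcoef[dd] else Fcoef[s]
      d[i] <- 0.75 - 0.25 * Fp
    } else {
      d[i] <- 0.5 - 0.25 * (Fcoef[s] + Fcoef[dd])
    }
    row <- stats::setNames(sqrt(d[i]), i)
    for (p in c(s, dd)) {
      if (!is.na(p)) row <- c(row, Lrows[[p]] * 0.5)
    }
    row <- tapply(row, names(row), sum)       # collapse shared ancestors
    Lrows[[i]] <- row
    Fcoef[i] <- sum(row^2) - 1
  }
  list(sire = si, dam = di, d = d, F = pmax(Fcoef, 0), Lrows = Lrows)
}
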